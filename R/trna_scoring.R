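# Normalized nine-criterion disease score for mt-tRNA variants, and VUS
# flagging when no functional-study evidence exists in the literature.

#' Names of the nine tRNA scoring criteria
#'
#' In canonical row order: pathogenicity reports, PhastCons and PhyloP
#' conservation, heteroplasmy evidence, then the five functional-study
#' criteria (disease segregation, histochemistry, OXPHOS biochemical defect,
#' cybrid / mt-tRNA steady-state studies, single-fiber segregation).
#'
#' @return Character vector of length 9.
#' @export
trna_criteria <- function() {
  c("multiple_pathogenic_reports",
    "phastcons_conserved",
    "phylop_conserved",
    "heteroplasmy_evidence",
    "disease_segregation",
    "histochemical_evidence",
    "oxphos_biochemical_defect",
    "cybrid_or_steady_state_evidence",
    "single_fiber_segregation")
}

# the five criteria that require a functional study
functional_criteria <- function() trna_criteria()[5:9]

#' Default raw criterion weights
#'
#' Yarham-style point weights in criterion order; the strongest evidence
#' (cybrid / steady-state studies) carries 5 of the 20 total points.
#'
#' @return Named numeric vector of length 9.
#' @export
default_trna_weights <- function() {
  stats::setNames(c(2, 1, 1, 2, 2, 2, 2, 5, 3), trna_criteria())
}

#' Normalize criterion weights to the 0-1 range
#'
#' Each weight is divided by the total, so the normalized weights sum to 1
#' and a fully supported profile scores exactly 1. Weights are defined up to
#' scale: multiplying all raw weights by a constant leaves the result
#' unchanged.
#'
#' @param raw_weights Non-negative numeric vector with positive sum.
#' @return Numeric vector of the same length and names, summing to 1.
#' @export
normalize_weights <- function(raw_weights) {
  raw_weights <- as.numeric(raw_weights) |> stats::setNames(names(raw_weights))
  if (any(is.na(raw_weights) | raw_weights < 0))
    abort("raw weights must be non-negative", "mitotier_domain_error")
  s <- sum(raw_weights)
  if (s <= 0)
    abort("all-zero weights cannot be normalized",
          "mitotier_degenerate_weights")
  raw_weights / s
}

check_normalized <- function(weights) {
  if (abs(sum(weights) - 1) > 1e-8)
    abort("weights must be normalized (sum to 1); see normalize_weights()",
          "mitotier_domain_error")
  weights
}

#' tRNA disease score of an evidence profile
#'
#' The sum of the normalized weights of the satisfied criteria. Criteria
#' recorded as unknown (`NA`) contribute nothing; the score is therefore
#' monotone in the evidence and lies in \[0, 1\].
#'
#' @param profile Logical vector over the nine criteria (`TRUE` satisfied,
#'   `FALSE` not satisfied, `NA` unknown). If named, names are matched
#'   against the weights; otherwise positional order is used.
#' @param weights Normalized weights (default:
#'   `normalize_weights(default_trna_weights())`).
#' @return Disease score in \[0, 1\].
#' @export
trna_disease_score <- function(profile,
                               weights =
                                 normalize_weights(default_trna_weights())) {
  check_normalized(weights)
  if (length(profile) != length(weights))
    abort("profile and weights lengths differ", "mitotier_domain_error")
  if (!is.null(names(profile)) && !is.null(names(weights))) {
    if (!setequal(names(profile), names(weights)))
      abort("profile and weights names differ", "mitotier_domain_error")
    profile <- profile[names(weights)]
  }
  sum(weights[which(profile)])
}

#' Flag a tRNA variant as VUS
#'
#' A tRNA variant with no functional evidence available from the literature
#' is a Variant of Undefined Significance regardless of its disease score
#' (conservation or report criteria may still make DS > 0). A VUS flag
#' overrides tier assignment downstream.
#'
#' @param functional_evidence_available Logical; `NA` is treated as
#'   unavailable.
#' @return Logical VUS flag.
#' @export
flag_vus <- function(functional_evidence_available) {
  !isTRUE(functional_evidence_available)
}

#' Read a tRNA evidence table
#'
#' Strictly validated TSV: key columns `position`, `ref`, `alt`, one column
#' per criterion (values `yes`/`no`/`unknown`) and `evidence_available`
#' (`yes`/`no`). When `evidence_available` is `no`, the five
#' functional-study criteria must be `unknown` — an unavailable study
#' cannot assert a negative result.
#'
#' @param path Path to the TSV file.
#' @return Data frame with logical criterion columns (`NA` = unknown) and a
#'   logical `evidence_available` column.
#' @export
read_trna_evidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("position", "ref", "alt", trna_criteria(), "evidence_available")
  if (!identical(sort(names(df)), sort(need)))
    abort(paste0("evidence table header must be exactly: ",
                 paste(need, collapse = ", ")),
          "mitotier_evidence_error")
  df <- df[, need]
  df$position <- as.integer(df$position)
  to_logical <- function(x) {
    if (any(!x %in% c("yes", "no", "unknown")))
      abort("criterion values must be yes/no/unknown",
            "mitotier_evidence_error")
    ifelse(x == "yes", TRUE, ifelse(x == "no", FALSE, NA))
  }
  for (cr in trna_criteria()) df[[cr]] <- to_logical(df[[cr]])
  if (any(!df$evidence_available %in% c("yes", "no")))
    abort("evidence_available must be yes/no", "mitotier_evidence_error")
  df$evidence_available <- df$evidence_available == "yes"
  unavailable <- !df$evidence_available
  if (any(unavailable)) {
    fc <- as.matrix(df[unavailable, functional_criteria(), drop = FALSE])
    if (any(!is.na(fc)))
      abort(paste0("functional criteria must be unknown when ",
                   "evidence_available is no"),
            "mitotier_evidence_error")
  }
  df
}
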