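# Consensus disease score for non-synonymous variants: a weighted mean over
# pathogenicity-predictor probabilities. The predictor set and weighting are
# pluggable; the default is an unweighted mean over whatever predictors are
# supplied (see the methods vignette for the scope of this choice).

#' Consensus disease score from predictor probabilities
#'
#' The weighted mean of the available predictor probabilities, with weights
#' renormalized over the non-missing entries. The result is bounded by the
#' minimum and maximum available probability and is invariant under
#' duplicating a predictor with its weight split.
#'
#' @param panel Numeric vector of predictor probabilities in \[0, 1\];
#'   `NA` marks a predictor with no call for this variant.
#' @param weights Optional non-negative weights, recycled to the panel
#'   length; default uniform.
#' @return Disease score in \[0, 1\], or `NA` (unassigned) when no
#'   predictor reports a probability.
#' @export
nonsyn_disease_score <- function(panel, weights = NULL) {
  panel <- as.numeric(panel)
  if (any(panel < 0 | panel > 1, na.rm = TRUE))
    abort("predictor probabilities must lie in [0, 1]",
          "mitotier_domain_error")
  if (is.null(weights)) weights <- rep(1, length(panel))
  weights <- rep_len(as.numeric(weights), length(panel))
  if (any(is.na(weights) | weights < 0))
    abort("predictor weights must be non-negative", "mitotier_domain_error")
  ok <- !is.na(panel) & weights > 0
  if (!any(ok)) return(NA_real_)
  sum(panel[ok] * weights[ok]) / sum(weights[ok])
}

#' Disease-score eligibility of a functional class
#'
#' Only non-synonymous CDS variants receive the predictor-consensus score.
#' Stop-gain, stop-loss and frameshift records (the latter only importable
#' from external callers; substitutions cannot create them) have no
#' available disease score; synonymous, rRNA, regulatory and intergenic
#' variants are annotation-only under the current scoring scope. tRNA
#' variants are scored by the criterion-based scheme instead
#' ([trna_disease_score()]).
#'
#' @param functional_class Character vector of functional classes.
#' @return Character vector, `"eligible"` or `"ineligible"`.
#' @export
score_eligibility <- function(functional_class) {
  ifelse(functional_class == "non-synonymous", "eligible", "ineligible")
}

#' Read a predictor probability table
#'
#' TSV with key columns `position`, `ref`, `alt` and one numeric column per
#' predictor; missing calls are encoded as `.`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with numeric predictor columns (`NA` = missing).
#' @export
read_predictor_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("position", "ref", "alt")
  if (!all(need %in% names(df)) || ncol(df) <= length(need))
    abort("predictor table needs position, ref, alt and predictor columns",
          "mitotier_predictor_error")
  df$position <- as.integer(df$position)
  for (cl in setdiff(names(df), need)) {
    x <- df[[cl]]
    x[x == "."] <- NA
    df[[cl]] <- as.numeric(x)
    if (any(df[[cl]] < 0 | df[[cl]] > 1, na.rm = TRUE))
      abort("predictor probabilities must lie in [0, 1]",
            "mitotier_domain_error")
  }
  df
}
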