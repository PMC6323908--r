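# Exhaustive enumeration of the potential substitution space and the
# observed/potential discrimination by allele frequency.

#' Enumerate every possible substitution over selected locus types
#'
#' For each reference position whose primary locus type is requested, the
#' three non-reference alleles are emitted, so a full enumeration of an
#' L-base reference yields exactly 3L substitutions (49,707 for the
#' 16,569 bp human mitochondrial reference). Each variant is annotated with
#' its primary locus and functional class; all start as `potential`.
#'
#' @param reference An [mt_reference()] with a locus map.
#' @param locus_types Locus types to cover: any subset of
#'   `c("CDS", "tRNA", "rRNA", "regulatory", "intergenic")`. Default: all.
#' @return A data frame of class `mt_catalogue` with columns `position`,
#'   `ref`, `alt`, `locus_name`, `locus_type`, `functional_class`, `status`,
#'   sorted by position then alt (A < C < G < T).
#' @export
enumerate_potential <- function(reference,
                                locus_types = c("CDS", "tRNA", "rRNA",
                                                "regulatory", "intergenic")) {
  if (length(locus_types) == 0L)
    abort("locus_types must be non-empty", "mitotier_config_error")
  allowed <- c(LOCUS_TYPES, "intergenic")
  if (any(!locus_types %in% allowed))
    abort(paste0("unknown locus type; allowed: ",
                 paste(allowed, collapse = ", ")),
          "mitotier_config_error")
  li <- locus_index(reference)
  type <- ifelse(is.na(li), "intergenic", reference$loci$type[li])
  keep <- which(type %in% locus_types & reference$bases %in% BASES)
  position <- rep(keep, each = 3L)
  refb <- reference$bases[position]
  # the three non-reference alleles, already in A < C < G < T order
  alt <- unlist(lapply(reference$bases[keep],
                       function(b) BASES[BASES != b]), use.names = FALSE)
  cat <- data.frame(
    position = position,
    ref = refb,
    alt = alt,
    locus_name = ifelse(is.na(li[position]), "intergenic",
                        reference$loci$name[li[position]]),
    locus_type = type[position],
    functional_class = classify_substitution(reference, position, alt),
    status = "potential",
    stringsAsFactors = FALSE
  )
  class(cat) <- c("mt_catalogue", "data.frame")
  cat
}

variant_key <- function(position, ref, alt) {
  paste(position, ref, alt, sep = ":")
}

#' Mark observed variants in a catalogue
#'
#' A variant is `observed` when the frequency of the allele causing it is
#' greater than 0 in the cohort, `potential` otherwise. Variants absent from
#' the supplied statistics are treated as frequency 0.
#'
#' @param catalogue A catalogue from [enumerate_potential()].
#' @param stats Either a numeric vector of allele frequencies aligned with
#'   the catalogue rows, or a data frame with columns `position`, `ref`,
#'   `alt`, `af_total` (e.g. from [cohort_stats()]).
#' @return The catalogue with `status` updated.
#' @export
mark_observed <- function(catalogue, stats) {
  if (is.data.frame(stats)) {
    af <- stats$af_total[match(
      variant_key(catalogue$position, catalogue$ref, catalogue$alt),
      variant_key(stats$position, stats$ref, stats$alt))]
  } else {
    af <- rep_len(as.numeric(stats), nrow(catalogue))
  }
  af[is.na(af)] <- 0
  if (any(af < 0 | af > 1))
    abort("allele frequency outside [0, 1]", "mitotier_domain_error")
  catalogue$status <- ifelse(af > 0, "observed", "potential")
  catalogue
}

#' Catalogue coverage of the potential substitution space
#'
#' @param n_annotated Number of variants hosted in a catalogue.
#' @param n_potential Size of the full potential space (3L).
#' @param digits Decimal places (half-up rounding); default 2.
#' @return Percentage covered.
#' @export
coverage_percent <- function(n_annotated, n_potential, digits = 2) {
  if (n_potential <= 0)
    abort("potential space must be positive", "mitotier_domain_error")
  round_half_up(100 * n_annotated / n_potential, digits)
}

#' @export
print.mt_catalogue <- function(x, ...) {
  cat("<mt_catalogue> ", nrow(x), " substitutions (",
      sum(x$status == "observed"), " observed, ",
      sum(x$status == "potential"), " potential)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}
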