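# Cohort summaries: functional-class and tier breakdowns with the
# half-up rounding convention used for reporting.

#' Round half-up
#'
#' Plain decimal rounding where `.5` always rounds away from zero (unlike
#' base `round()`'s round-half-even), matching how percentages are reported.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage of a count, half-up rounded
#'
#' @param count,total Counts.
#' @param digits Decimal places (use 0 for integer-percent rendering).
#' @return Percentage.
#' @export
percent_of <- function(count, total, digits = 1) {
  round_half_up(100 * count / total, digits)
}

#' Render a percentage for display
#'
#' One-decimal rendering that drops a trailing `.0` (so 7.0 prints as
#' `"7%"`, 59.7 as `"59.7%"`), mirroring mixed-precision report styles.
#'
#' @param pct Numeric percentages.
#' @return Character vector.
#' @export
format_percent <- function(pct) {
  out <- sprintf("%.1f", pct)
  out <- sub("\\.0$", "", out)
  paste0(out, "%")
}

#' Functional-class breakdown of a variant set
#'
#' @param functional_class Character vector of classes (one per variant).
#' @param digits Decimal places for percentages (default 1).
#' @return Data frame with columns `functional_class`, `n`, `pct`, `label`;
#'   the attribute `total` carries the variant count. Empty input yields an
#'   empty summary with total 0.
#' @export
class_breakdown <- function(functional_class, digits = 1) {
  total <- length(functional_class)
  tab <- table(functional_class)
  out <- data.frame(functional_class = names(tab),
                    n = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$pct <- if (total > 0) percent_of(out$n, total, digits) else numeric(0)
  out$label <- if (nrow(out) > 0) format_percent(out$pct) else character(0)
  attr(out, "total") <- total
  out
}

#' Tier breakdown and healthy-absence fraction
#'
#' Counts variants per tier and, among Pathogenic-tier variants, the
#' fraction never observed in healthy genomes (healthy-stratum allele
#' frequency 0) — the signature expected of truly deleterious variants.
#'
#' @param tier Character vector of tier labels.
#' @param af_healthy Healthy-stratum allele frequency per variant, or
#'   `NULL` when health strata are unavailable.
#' @param digits Decimal places for percentages.
#' @return Data frame with columns `tier`, `n`, `pct`; attributes `total`
#'   and `pathogenic_absent_healthy_pct` (NA when there are no
#'   Pathogenic-tier variants or no strata).
#' @export
tier_breakdown <- function(tier, af_healthy = NULL, digits = 1) {
  total <- length(tier)
  lev <- c(TIER_LEVELS[TIER_LEVELS %in% tier], setdiff(unique(tier), TIER_LEVELS))
  tab <- table(factor(tier, levels = lev))
  out <- data.frame(tier = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$pct <- if (total > 0) percent_of(out$n, total, digits) else numeric(0)
  frac <- NA_real_
  if (!is.null(af_healthy)) {
    stopifnot(length(af_healthy) == total)
    path <- tier == "Pathogenic" & !is.na(af_healthy)
    if (any(path))
      frac <- percent_of(sum(af_healthy[path] == 0), sum(path), digits)
  }
  attr(out, "total") <- total
  attr(out, "pathogenic_absent_healthy_pct") <- frac
  out
}

#' Per-genome mutation counts
#'
#' Counts, for every genome in the cohort, the called positions that differ
#' from the reference base — the per-patient substitution burden.
#'
#' @param cohort An [mt_cohort()].
#' @param reference The matching [mt_reference()].
#' @return Data frame with `genome_id`, `status`, `n_mutations`; attribute
#'   `mean_mutations` is the cohort average (half-up, one decimal).
#' @export
patient_mutation_table <- function(cohort, reference) {
  stopifnot(cohort$length == reference$length)
  ref <- matrix(reference$bases, nrow = cohort$n_total,
                ncol = cohort$length, byrow = TRUE)
  diff <- cohort$alleles != ref & cohort$alleles %in% CALLED
  out <- data.frame(genome_id = cohort$genome_ids,
                    status = cohort$status,
                    n_mutations = as.integer(rowSums(diff)),
                    stringsAsFactors = FALSE)
  attr(out, "mean_mutations") <- round_half_up(mean(out$n_mutations), 1)
  out
}
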