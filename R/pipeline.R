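# End-to-end annotation: catalogue enumeration, cohort statistics, disease
# scoring and tier assignment, bundled into a classed result object.

#' Annotate a cohort against a reference
#'
#' Runs the full pipeline: enumerates the potential substitution space over
#' the requested locus types, computes per-variant allele frequencies
#' (overall and per health stratum) and per-site variability from the
#' cohort, marks observed variants, scores tRNA variants from the evidence
#' table and non-synonymous variants from the predictor table, flags VUS,
#' and assigns pathogenicity tiers. Variants outside the scored classes
#' (synonymous, stop-gain/-loss, rRNA, regulatory, intergenic) are
#' annotation-only and tiered `Unclassified`.
#'
#' @param reference An [mt_reference()] with a locus map.
#' @param cohort An [mt_cohort()] aligned to the reference.
#' @param trna_evidence tRNA evidence data frame (see
#'   [read_trna_evidence()]) or `NULL`; tRNA variants without a row are
#'   flagged VUS.
#' @param predictors Predictor probability data frame (see
#'   [read_predictor_table()]) or `NULL`; non-synonymous variants without a
#'   usable probability stay unassigned.
#' @param thresholds A [threshold_config()].
#' @param trna_weights Raw tRNA criterion weights (normalized internally).
#' @param locus_types Locus types to enumerate (default all).
#' @return An object of class `mt_annotation`: a list with the annotation
#'   `table`, the `thresholds`, the reference name and cohort counts.
#' @export
annotate_cohort <- function(reference, cohort, trna_evidence = NULL,
                            predictors = NULL,
                            thresholds = threshold_config(),
                            trna_weights = default_trna_weights(),
                            locus_types = c("CDS", "tRNA", "rRNA",
                                            "regulatory", "intergenic")) {
  stopifnot(cohort$length == reference$length)
  catalogue <- enumerate_potential(reference, locus_types)
  stats <- cohort_stats(cohort, catalogue, reference)
  catalogue <- mark_observed(catalogue, stats)

  n <- nrow(catalogue)
  ds <- rep(NA_real_, n)
  vus <- rep(FALSE, n)
  key <- variant_key(catalogue$position, catalogue$ref, catalogue$alt)

  is_trna <- catalogue$functional_class == "tRNA"
  if (any(is_trna)) {
    vus[is_trna] <- TRUE  # no evidence row means no functional evidence
    if (!is.null(trna_evidence)) {
      w <- normalize_weights(trna_weights)
      ek <- variant_key(trna_evidence$position, trna_evidence$ref,
                        trna_evidence$alt)
      hit <- match(key, ek)
      for (i in which(is_trna & !is.na(hit))) {
        row <- trna_evidence[hit[i], ]
        profile <- unlist(row[trna_criteria()])
        ds[i] <- trna_disease_score(profile, w)
        vus[i] <- flag_vus(row$evidence_available)
      }
    }
  }

  eligible <- score_eligibility(catalogue$functional_class) == "eligible"
  if (any(eligible) && !is.null(predictors)) {
    pcols <- setdiff(names(predictors), c("position", "ref", "alt"))
    pk <- variant_key(predictors$position, predictors$ref, predictors$alt)
    hit <- match(key, pk)
    for (i in which(eligible & !is.na(hit)))
      ds[i] <- nonsyn_disease_score(unlist(predictors[hit[i], pcols]))
  }

  tier <- rep("Unclassified", n)
  scored <- catalogue$functional_class %in% c("non-synonymous", "tRNA")
  tier[scored] <- assign_tier(ds[scored], stats$af_total[scored],
                              catalogue$functional_class[scored],
                              vus[scored], thresholds)

  tab <- cbind(catalogue,
               stats[, c("af_total", "af_healthy", "af_pathologic",
                         "nt_var", "aa_var")],
               data.frame(ds = ds, vus = vus, tier = tier,
                          stringsAsFactors = FALSE))
  class(tab) <- "data.frame"
  structure(
    list(table = tab, thresholds = thresholds,
         reference_name = reference$name,
         n_total = cohort$n_total, n_healthy = cohort$n_healthy,
         n_pathologic = cohort$n_pathologic),
    class = "mt_annotation"
  )
}

#' @export
print.mt_annotation <- function(x, ...) {
  cat("<mt_annotation> ", nrow(x$table), " substitutions on ",
      x$reference_name, "\n", sep = "")
  cat("  cohort: ", x$n_total, " genomes (", x$n_healthy, " healthy, ",
      x$n_pathologic, " pathologic)\n", sep = "")
  cat("  observed: ", sum(x$table$status == "observed"), "; scored: ",
      sum(!is.na(x$table$ds)), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.mt_annotation <- function(x, ...) x$table

#' Summarize an annotation
#'
#' Functional-class and tier breakdowns plus the fraction of
#' Pathogenic-tier variants never observed in healthy genomes.
#'
#' @param object An `mt_annotation`.
#' @param observed_only Restrict the class breakdown to observed variants.
#' @param ... Unused.
#' @return A list of class `summary.mt_annotation` with elements `classes`,
#'   `tiers` and `pathogenic_absent_healthy_pct`.
#' @export
summary.mt_annotation <- function(object, observed_only = FALSE, ...) {
  tab <- object$table
  cls_tab <- if (observed_only) tab[tab$status == "observed", ] else tab
  classes <- class_breakdown(cls_tab$functional_class)
  scored <- tab[tab$tier != "Unclassified", ]
  tiers <- tier_breakdown(scored$tier, scored$af_healthy)
  structure(
    list(classes = classes, tiers = tiers,
         pathogenic_absent_healthy_pct =
           attr(tiers, "pathogenic_absent_healthy_pct"),
         n_variants = nrow(tab)),
    class = "summary.mt_annotation"
  )
}

#' @export
print.summary.mt_annotation <- function(x, ...) {
  cat("Functional classes (", attr(x$classes, "total"), " variants):\n",
      sep = "")
  print.data.frame(x$classes, row.names = FALSE)
  cat("\nTiers (", attr(x$tiers, "total"), " classified variants):\n",
      sep = "")
  print.data.frame(x$tiers, row.names = FALSE)
  if (!is.na(x$pathogenic_absent_healthy_pct))
    cat("\nPathogenic-tier variants absent from healthy genomes: ",
        format_percent(x$pathogenic_absent_healthy_pct), "\n", sep = "")
  invisible(x)
}
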