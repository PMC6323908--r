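# Pathogenicity tier assignment from joint disease-score / allele-frequency
# thresholds, and empirical re-estimation of the allele-frequency threshold.

#' Threshold configuration for tier assignment
#'
#' The shipped defaults are the published operating points: disease-score
#' thresholds 0.43 (non-synonymous) and 0.35 (tRNA), allele-frequency
#' thresholds 0.003264 (non-synonymous) and 0.005020 (tRNA). `af_quantile`
#' is used only when re-estimating an AF threshold from data with
#' [estimate_af_threshold()].
#'
#' @param ds_t_nonsyn,ds_t_trna Disease-score thresholds in \[0, 1\].
#' @param af_t_nonsyn,af_t_trna Allele-frequency thresholds in \[0, 1\].
#' @param af_quantile Empirical quantile for AF-threshold re-estimation.
#' @return A classed list of thresholds.
#' @export
threshold_config <- function(ds_t_nonsyn = 0.43, ds_t_trna = 0.35,
                             af_t_nonsyn = 0.003264, af_t_trna = 0.005020,
                             af_quantile = 0.95) {
  vals <- c(ds_t_nonsyn, ds_t_trna, af_t_nonsyn, af_t_trna, af_quantile)
  if (any(is.na(vals) | vals < 0 | vals > 1))
    abort("thresholds must lie in [0, 1]", "mitotier_domain_error")
  structure(list(ds_t_nonsyn = ds_t_nonsyn, ds_t_trna = ds_t_trna,
                 af_t_nonsyn = af_t_nonsyn, af_t_trna = af_t_trna,
                 af_quantile = af_quantile),
            class = "mt_thresholds")
}

#' Read a key=value threshold configuration file
#'
#' Lines of the form `key = value` (hash comments allowed) overriding any of
#' the [threshold_config()] fields or `trna_weights` (nine comma-separated
#' raw weights).
#'
#' @param path Path to the config file.
#' @return List with elements `thresholds` ([threshold_config()]) and
#'   `trna_weights` (raw, named).
#' @export
read_threshold_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    abort("config lines must be key = value", "mitotier_config_error")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  args <- formals(threshold_config)
  weights <- default_trna_weights()
  opts <- list()
  for (i in seq_along(keys)) {
    if (keys[i] == "trna_weights") {
      w <- as.numeric(strsplit(vals[i], ",", fixed = TRUE)[[1L]])
      if (length(w) != 9L)
        abort("trna_weights needs nine comma-separated values",
              "mitotier_config_error")
      weights <- stats::setNames(w, trna_criteria())
    } else if (keys[i] %in% names(args)) {
      opts[[keys[i]]] <- as.numeric(vals[i])
    } else {
      abort(paste0("unknown config key: ", keys[i]), "mitotier_config_error")
    }
  }
  list(thresholds = do.call(threshold_config, opts), trna_weights = weights)
}

#' Estimate an allele-frequency threshold from scored variants
#'
#' Evaluates the empirical cumulative distribution of allele frequency among
#' variants whose disease score reaches the disease-score threshold, and
#' returns its `af_quantile`-th quantile (inverse-ECDF convention,
#' `stats::quantile` type 1). The shipped defaults in [threshold_config()]
#' are frozen published constants; this estimator reproduces the procedure
#' on a cohort of the caller's own.
#'
#' @param ds Numeric disease scores (NA = unassigned).
#' @param af Numeric allele frequencies.
#' @param ds_t Disease-score threshold (inclusive: DS >= ds_t qualifies).
#' @param af_quantile Quantile in \[0, 1\].
#' @return The estimated AF threshold.
#' @export
estimate_af_threshold <- function(ds, af, ds_t, af_quantile = 0.95) {
  stopifnot(length(ds) == length(af))
  sel <- !is.na(ds) & ds >= ds_t & !is.na(af)
  if (!any(sel))
    abort("no variants with DS >= ds_t and defined AF",
          "mitotier_estimation_error")
  unname(stats::quantile(af[sel], probs = af_quantile, type = 1))
}

#' Assign pathogenicity tiers
#'
#' The joint rules (inclusive operators): DS >= DS_T and AF <= AF_T is
#' Pathogenic; DS >= DS_T and AF > AF_T is Likely Pathogenic; DS < DS_T and
#' AF <= AF_T is Likely Polymorphic; DS < DS_T and AF > AF_T is Polymorphic.
#' A VUS flag overrides the quadrant; an unassigned (NA) disease score
#' yields Unclassified. Thresholds are selected per variant by
#' `variant_class`.
#'
#' @param ds Disease scores (NA = unassigned).
#' @param af Allele frequencies; potential variants carry 0, never NA.
#' @param variant_class `"non-synonymous"` or `"tRNA"`, recycled.
#' @param vus Logical VUS flags, recycled (default `FALSE`).
#' @param thresholds A [threshold_config()].
#' @return Character vector of tiers.
#' @export
assign_tier <- function(ds, af, variant_class, vus = FALSE,
                        thresholds = threshold_config()) {
  n <- max(length(ds), length(af), length(variant_class), length(vus))
  ds <- rep_len(ds, n); af <- rep_len(af, n)
  variant_class <- rep_len(variant_class, n); vus <- rep_len(vus, n)
  if (any(!variant_class %in% c("non-synonymous", "tRNA")))
    abort("variant_class must be 'non-synonymous' or 'tRNA'",
          "mitotier_domain_error")
  if (any(is.na(af)))
    abort("allele frequency must be defined (potential variants carry 0)",
          "mitotier_input_error")
  ds_t <- ifelse(variant_class == "tRNA",
                 thresholds$ds_t_trna, thresholds$ds_t_nonsyn)
  af_t <- ifelse(variant_class == "tRNA",
                 thresholds$af_t_trna, thresholds$af_t_nonsyn)
  tier <- ifelse(is.na(ds), "Unclassified",
          ifelse(ds >= ds_t,
                 ifelse(af <= af_t, "Pathogenic", "Likely Pathogenic"),
                 ifelse(af <= af_t, "Likely Polymorphic", "Polymorphic")))
  tier[vus] <- "VUS"
  tier
}
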