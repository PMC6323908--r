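# Deterministic synthetic cohorts and evidence tables.
#
# The simulator plants substitutions at chosen per-stratum allele
# frequencies in a cohort of otherwise identical genomes; carrier counts
# are realized exactly as round(AF x N) (half-up), so the truth table's
# expected tiers are deterministic functions of the specification, not of
# the random carrier placement. Seeds only move *which* genomes carry a
# variant, never the tier truth.

# 600 bp toy reference (fixed literal, not RNG-dependent at run time)
TOY_SEQUENCE <- paste0(
  "GTCCTGTACGATCAGGTACTCTTAACGCCTTACATTACGATTTAAACGTAATAAGTGTAT",
  "TCACTCATCAATCACGCCGACTCGGGGTACCAACAACCTAGCGAGCCAGAATGTTACTGG",
  "ATTAATAACCGTACGTTGGATACTACAGCCTTGCTTATTCCACAAGCCGCAGATCACGCA",
  "TCCAAAAATGAGCATATCTTCTTCTTAAGTAAAAGGTCGGCAAACGTTGTAAGTATGTTT",
  "AGTGGGTACTTTCTGGCTCCCTTACGTTGGGTCCACGCCCTACGACTTTCATATTCCCGC",
  "AGGTCCCTGCGGCCTTCTACAATTGGGGTCTCAGCAGTAAGCCTGTCTAGGCGAATAACT",
  "GGGTCCCGAGCGAGTGTGGTAATGCGTTATGGCTCCCTAAATATCGGAGACACGCCCTTT",
  "ATTCGGAGTGTCTTTGGTGTTTAAAGAACGTGATGAGTTATGCCACCATTCAGTATCGAA",
  "TCAGCTCGCAAGATTGTTATGGGGCCATTAAGCTCGCTGAATTCACGTCGCCGTATCGGT",
  "CGTTGAGCCGCTTATTCCGGTTGGCCGCCCAGTAAAATCAAACCCTGCTAGTCAGCCGGA"
)

#' Toy mitochondrial reference
#'
#' A fixed 600 bp circular mini-genome whose locus map exercises all four
#' locus-type attribute regimes cheaply: a 100-codon plus-strand CDS, a
#' tRNA, an rRNA, a 10-codon minus-strand CDS, a regulatory locus, and
#' intergenic gaps.
#'
#' @return An [mt_reference()].
#' @export
toy_reference <- function() {
  loci <- data.frame(
    name = c("TOY-CDS1", "TOY-TRNA1", "TOY-RRNA1", "TOY-CDS2", "TOY-DLOOP"),
    type = c("CDS", "tRNA", "rRNA", "CDS", "regulatory"),
    start = c(101L, 411L, 491L, 551L, 581L),
    end = c(400L, 480L, 550L, 580L, 600L),
    strand = c("+", "+", "+", "-", "+"),
    frame = c(101L, NA, NA, 580L, NA),
    stringsAsFactors = FALSE
  )
  mt_reference(TOY_SEQUENCE, loci = loci, name = "toy_mt", circular = TRUE)
}

#' Load the bundled synthetic rCRS-scale reference
#'
#' A 16,569 bp random stand-in at the length and locus layout of the human
#' mitochondrial reference (canonical 37-gene structure; CDS ends adjusted
#' to codon multiples; the control region spans the circular origin). The
#' sequence content is synthetic — it is not NC_012920.1 — so it supports
#' coordinate, enumeration and layout computations, not biological
#' interpretation of specific sites.
#'
#' @return An [mt_reference()] of length 16,569.
#' @export
synthetic_rcrs <- function() {
  fasta <- system.file("extdata", "synthetic_rcrs.fasta",
                       package = "mitotier", mustWork = TRUE)
  loci <- system.file("extdata", "synthetic_rcrs_loci.tsv",
                      package = "mitotier", mustWork = TRUE)
  read_reference(fasta, loci = read_locus_table(loci), circular = TRUE)
}

EVIDENCE_PATTERNS <- c("full", "functional_strong", "weak", "none",
                       "unavailable", "absent")

# expand a pattern name into a profile row (nine logicals + availability)
evidence_pattern <- function(pattern) {
  cr <- trna_criteria()
  p <- stats::setNames(rep(FALSE, 9L), cr)
  avail <- TRUE
  switch(pattern,
    full = { p[] <- TRUE },
    functional_strong = {
      p[c("disease_segregation", "cybrid_or_steady_state_evidence",
          "single_fiber_segregation")] <- TRUE
    },
    weak = { p[c("multiple_pathogenic_reports", "phastcons_conserved")] <- TRUE },
    none = { },
    unavailable = {
      p[c("phastcons_conserved", "phylop_conserved")] <- TRUE
      p[functional_criteria()] <- NA
      avail <- FALSE
    },
    abort(paste0("unknown evidence pattern: ", pattern),
          "mitotier_spec_error")
  )
  list(profile = p, available = avail)
}

#' Specify a synthetic cohort simulation
#'
#' @param planted Data frame of planted variants with columns `position`,
#'   `alt`, `af_healthy`, `af_pathologic` (target allele frequencies per
#'   stratum), `evidence` (a pattern name from
#'   `c("full","functional_strong","weak","none","unavailable","absent")`,
#'   used for tRNA variants) and `predictor` (a consensus probability, `NA`
#'   for no predictor row; used for non-synonymous variants). Positions must
#'   be unique.
#' @param n_healthy,n_pathologic Genomes per health stratum.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   outputs.
#' @return A classed list (`mt_simspec`).
#' @export
simulation_spec <- function(planted, n_healthy = 250L, n_pathologic = 250L,
                            seed = 1L) {
  planted <- as.data.frame(planted, stringsAsFactors = FALSE)
  need <- c("position", "alt", "af_healthy", "af_pathologic", "evidence",
            "predictor")
  if (!all(need %in% names(planted)))
    abort(paste0("planted needs columns: ", paste(need, collapse = ", ")),
          "mitotier_spec_error")
  if (anyDuplicated(planted$position))
    abort("planted positions must be unique", "mitotier_spec_error")
  if (any(planted$af_healthy < 0 | planted$af_healthy > 1 |
            planted$af_pathologic < 0 | planted$af_pathologic > 1))
    abort("target allele frequencies must lie in [0, 1]",
          "mitotier_spec_error")
  if (any(!planted$evidence %in% EVIDENCE_PATTERNS))
    abort("unknown evidence pattern in planted table", "mitotier_spec_error")
  structure(list(planted = planted, n_healthy = as.integer(n_healthy),
                 n_pathologic = as.integer(n_pathologic),
                 seed = as.integer(seed)),
            class = "mt_simspec")
}

#' Default simulation specification
#'
#' Twenty-six planted variants on the toy reference spanning every tier
#' (Pathogenic / Likely Pathogenic / Likely Polymorphic / Polymorphic under
#' the shipped thresholds), VUS and unassigned-DS paths, plus synonymous,
#' stop-gain, rRNA and regulatory annotation-only records. Stratum sizes
#' default to 250 + 250 so a single carrier sits below both published AF
#' thresholds.
#'
#' @param seed Integer seed.
#' @inheritParams simulation_spec
#' @return An `mt_simspec`.
#' @export
default_simulation_spec <- function(seed = 1L, n_healthy = 250L,
                                    n_pathologic = 250L) {
  p <- function(position, alt, afh, afp, evidence = "absent",
                predictor = NA_real_) {
    data.frame(position = position, alt = alt, af_healthy = afh,
               af_pathologic = afp, evidence = evidence,
               predictor = predictor, stringsAsFactors = FALSE)
  }
  planted <- rbind(
    # tRNA locus (411-480)
    p(411L, "T", 0.000, 0.004, "full"),              # Pathogenic
    p(414L, "A", 0.020, 0.020, "full"),              # Likely Pathogenic
    p(418L, "C", 0.000, 0.000, "functional_strong"), # Pathogenic (AF 0)
    p(421L, "G", 0.004, 0.000, "weak"),              # Likely Polymorphic
    p(424L, "A", 0.050, 0.050, "weak"),              # Polymorphic
    p(427L, "T", 0.100, 0.100, "none"),              # Polymorphic
    p(430L, "A", 0.004, 0.004, "unavailable"),       # VUS (DS > 0)
    p(433L, "G", 0.008, 0.008, "absent"),            # VUS (no evidence row)
    p(436L, "A", 0.004, 0.200, "full"),              # Likely Pathogenic
    p(440L, "C", 0.300, 0.100, "none"),              # Polymorphic
    p(443L, "G", 0.004, 0.000, "functional_strong"), # Pathogenic
    p(447L, "C", 0.020, 0.020, "weak"),              # Polymorphic
    # non-synonymous CDS positions (TOY-CDS1, 101-400)
    p(131L, "A", 0.000, 0.004, predictor = 0.90),    # Pathogenic
    p(140L, "C", 0.050, 0.050, predictor = 0.90),    # Likely Pathogenic
    p(152L, "C", 0.004, 0.000, predictor = 0.20),    # Likely Polymorphic
    p(161L, "T", 0.050, 0.050, predictor = 0.20),    # Polymorphic
    p(182L, "A", 0.000, 0.000, predictor = 0.60),    # Pathogenic (AF 0)
    p(200L, "G", 0.010, 0.010),                      # Unclassified (no DS)
    p(210L, "C", 0.000, 0.004, predictor = 0.43),    # Pathogenic (DS = DS_T)
    p(251L, "A", 0.050, 0.050, predictor = 0.50),    # Likely Pathogenic
    p(281L, "C", 0.004, 0.000, predictor = 0.30),    # Likely Polymorphic
    p(300L, "G", 0.200, 0.200, predictor = 0.10),    # Polymorphic
    # annotation-only classes
    p(103L, "A", 0.020, 0.020),                      # synonymous
    p(170L, "T", 0.000, 0.020),                      # stop-gain
    p(491L, "G", 0.010, 0.010),                      # rRNA
    p(583L, "T", 0.010, 0.010)                       # regulatory
  )
  simulation_spec(planted, n_healthy = n_healthy,
                  n_pathologic = n_pathologic, seed = seed)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# generator-side tier arithmetic (kept inline so the truth table does not
# depend on the classifier under test)
truth_tier <- function(class, ds, vus, af_total,
                       thresholds = threshold_config()) {
  if (!class %in% c("non-synonymous", "tRNA")) return("Unclassified")
  if (class == "tRNA" && vus) return("VUS")
  if (is.na(ds)) return("Unclassified")
  ds_t <- if (class == "tRNA") thresholds$ds_t_trna else thresholds$ds_t_nonsyn
  af_t <- if (class == "tRNA") thresholds$af_t_trna else thresholds$af_t_nonsyn
  if (ds >= ds_t) {
    if (af_total <= af_t) "Pathogenic" else "Likely Pathogenic"
  } else {
    if (af_total <= af_t) "Likely Polymorphic" else "Polymorphic"
  }
}

#' Generate evidence tables for a simulation spec
#'
#' Builds the tRNA evidence table (for planted tRNA variants whose pattern
#' is not `absent`) and the predictor table (two concordant predictors at
#' the target consensus for planted non-synonymous variants with a
#' `predictor` value; the second predictor of every other row is missing to
#' exercise weight renormalization). Unlisted variants get no rows, driving
#' the VUS / unassigned-DS paths downstream.
#'
#' @param spec An `mt_simspec`.
#' @param reference The reference the spec targets (default
#'   [toy_reference()]).
#' @return List with data frames `trna_evidence` and `predictors`.
#' @export
generate_evidence_tables <- function(spec, reference = toy_reference()) {
  planted <- spec$planted
  cls <- classify_substitution(reference, planted$position, planted$alt)
  refb <- reference$bases[planted$position]

  ev_rows <- which(cls == "tRNA" & planted$evidence != "absent")
  ev <- NULL
  if (length(ev_rows) > 0L) {
    ev <- do.call(rbind, lapply(ev_rows, function(i) {
      pat <- evidence_pattern(planted$evidence[i])
      row <- data.frame(position = planted$position[i], ref = refb[i],
                        alt = planted$alt[i], stringsAsFactors = FALSE)
      for (cr in trna_criteria()) row[[cr]] <- pat$profile[[cr]]
      row$evidence_available <- pat$available
      row
    }))
  }

  pr_rows <- which(cls == "non-synonymous" & !is.na(planted$predictor))
  pr <- NULL
  if (length(pr_rows) > 0L) {
    pr <- data.frame(position = planted$position[pr_rows],
                     ref = refb[pr_rows], alt = planted$alt[pr_rows],
                     predictor_a = planted$predictor[pr_rows],
                     predictor_b = planted$predictor[pr_rows],
                     stringsAsFactors = FALSE)
    # odd rows lose their second predictor: consensus must renormalize
    drop <- seq_along(pr_rows) %% 2L == 1L
    pr$predictor_b[drop] <- NA_real_
  }
  list(trna_evidence = ev, predictors = pr)
}

#' Generate a synthetic genome cohort with a truth table
#'
#' Starts every genome as a copy of the reference, then plants each
#' specified variant in `round(AF x N)` genomes per health stratum (half-up,
#' sampled without replacement under the spec seed). Returns the cohort, the
#' evidence tables and a truth table carrying the realized per-stratum
#' frequencies, the expected disease score and the expected tier under the
#' shipped thresholds.
#'
#' @param spec An `mt_simspec` (see [simulation_spec()]).
#' @param reference Target reference (default [toy_reference()]).
#' @param dir Optional output directory; when given, writes `genomes.fasta`,
#'   `manifest.tsv`, `truth.tsv`, `trna_evidence.tsv`, `predictors.tsv`,
#'   `reference.fasta` and `loci.tsv`.
#' @param thresholds Thresholds used for the truth-table tiers.
#' @return List with elements `cohort` ([mt_cohort()]), `truth`,
#'   `trna_evidence`, `predictors`, `reference`.
#' @export
generate_cohort <- function(spec, reference = toy_reference(), dir = NULL,
                            thresholds = threshold_config()) {
  stopifnot(inherits(spec, "mt_simspec"))
  planted <- spec$planted
  if (any(planted$position < 1L | planted$position > reference$length))
    abort("planted position outside the reference", "mitotier_spec_error")
  refb <- reference$bases[planted$position]
  if ("ref" %in% names(planted) && any(planted$ref != refb))
    abort("planted ref allele does not match the reference",
          "mitotier_spec_error")
  if (any(planted$alt == refb))
    abort("planted alt equals the reference base", "mitotier_spec_error")

  n_h <- spec$n_healthy; n_p <- spec$n_pathologic; n <- n_h + n_p
  m <- matrix(rep(reference$bases, each = n), nrow = n)
  rownames(m) <- sprintf("genome_%04d", seq_len(n))
  status <- c(rep("healthy", n_h), rep("pathologic", n_p))

  carriers_h <- as.integer(round_half_up(planted$af_healthy * n_h))
  carriers_p <- as.integer(round_half_up(planted$af_pathologic * n_p))
  with_seed(spec$seed, {
    for (i in seq_len(nrow(planted))) {
      rows <- c(if (carriers_h[i] > 0L) sample(seq_len(n_h), carriers_h[i]),
                if (carriers_p[i] > 0L) n_h + sample(seq_len(n_p),
                                                     carriers_p[i]))
      if (length(rows) > 0L) m[rows, planted$position[i]] <- planted$alt[i]
    }
  })
  cohort <- mt_cohort(m, status)

  ev <- generate_evidence_tables(spec, reference)
  cls <- classify_substitution(reference, planted$position, planted$alt)
  ds <- rep(NA_real_, nrow(planted))
  vus <- rep(FALSE, nrow(planted))
  w <- normalize_weights(default_trna_weights())
  for (i in seq_len(nrow(planted))) {
    if (cls[i] == "tRNA") {
      if (planted$evidence[i] == "absent") {
        vus[i] <- TRUE
      } else {
        pat <- evidence_pattern(planted$evidence[i])
        ds[i] <- trna_disease_score(pat$profile, w)
        vus[i] <- !pat$available
      }
    } else if (cls[i] == "non-synonymous") {
      ds[i] <- planted$predictor[i]
    }
  }
  af_h <- carriers_h / n_h
  af_p <- carriers_p / n_p
  af_total <- (carriers_h + carriers_p) / n
  truth <- data.frame(
    position = planted$position, ref = refb, alt = planted$alt,
    functional_class = cls,
    target_af_healthy = planted$af_healthy,
    target_af_pathologic = planted$af_pathologic,
    af_healthy = af_h, af_pathologic = af_p, af_total = af_total,
    expected_ds = ds, expected_vus = vus,
    expected_tier = vapply(seq_len(nrow(planted)), function(i)
      truth_tier(cls[i], ds[i], vus[i], af_total[i], thresholds),
      character(1)),
    stringsAsFactors = FALSE
  )

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    seqs <- Biostrings::DNAStringSet(apply(m, 1L, paste, collapse = ""))
    Biostrings::writeXStringSet(seqs, file.path(dir, "genomes.fasta"),
                                width = 70L)
    utils::write.table(
      data.frame(genome_id = rownames(m), status = status),
      file.path(dir, "manifest.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ev$trna_evidence))
      write_trna_evidence(ev$trna_evidence,
                          file.path(dir, "trna_evidence.tsv"))
    if (!is.null(ev$predictors))
      write_predictor_table(ev$predictors, file.path(dir, "predictors.tsv"))
    refset <- Biostrings::DNAStringSet(reference$sequence)
    names(refset) <- reference$name
    Biostrings::writeXStringSet(refset, file.path(dir, "reference.fasta"),
                                width = 70L)
    utils::write.table(
      reference$loci[, c("name", "type", "start", "end", "strand", "frame")],
      file.path(dir, "loci.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  list(cohort = cohort, truth = truth, trna_evidence = ev$trna_evidence,
       predictors = ev$predictors, reference = reference)
}
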