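test_that("allele frequency counts carrier genomes over called genomes", {
  ref <- mt_reference("AAAA", circular = FALSE)
  genomes <- c(rep("AAAA", 4), "ACAA", rep("AAAA", 3), "ACAA", "ACAA")
  cohort <- string_cohort(genomes, rep(c("healthy", "pathologic"), each = 5))
  expect_equal(allele_frequency(cohort, 2, "C"), 0.3)
  expect_equal(allele_frequency(cohort, 2, "C", "healthy"), 1 / 5)
  expect_equal(allele_frequency(cohort, 2, "C", "pathologic"), 2 / 5)
  expect_equal(allele_frequency(cohort, 3, "C"), 0)         # absence
  expect_equal(allele_frequency(string_cohort(rep("ACAA", 4),
                                              rep("healthy", 4)),
                                2, "C"), 1)                 # saturation
})

test_that("uncalled bases leave the denominator; empty strata are errors", {
  ref_seq <- "AAAA"
  genomes <- c("ACAA", "A-AA", "ANAA", "AAAA")
  cohort <- string_cohort(genomes, rep("healthy", 4))
  expect_equal(allele_frequency(cohort, 2, "C"), 1 / 2)
  expect_error(allele_frequency(cohort, 2, "C", "pathologic"),
               class = "mitotier_undefined_frequency")
})

test_that("stratum frequencies recombine to the overall frequency", {
  set.seed(7)
  for (rep_i in 1:5) {
    n_h <- sample(3:12, 1); n_p <- sample(3:12, 1)
    carriers <- c(sample(c(TRUE, FALSE), n_h, replace = TRUE),
                  sample(c(TRUE, FALSE), n_p, replace = TRUE))
    genomes <- ifelse(carriers, "AG", "AA")
    cohort <- string_cohort(genomes,
                            rep(c("healthy", "pathologic"), c(n_h, n_p)))
    af_t <- allele_frequency(cohort, 2, "G")
    af_h <- allele_frequency(cohort, 2, "G", "healthy")
    af_p <- allele_frequency(cohort, 2, "G", "pathologic")
    expect_equal((n_h + n_p) * af_t, n_h * af_h + n_p * af_p)
  }
})

test_that("nucleotide variability is normalized entropy with its stated extremes", {
  mono <- string_cohort(rep("AAAA", 6), rep("healthy", 6))
  expect_equal(nt_site_variability(mono, 1), 0)
  four <- string_cohort(c("A", "C", "G", "T"), rep("healthy", 4))
  expect_equal(nt_site_variability(four, 1), 1)
  # 90/10 biallelic column equals the direct entropy computation
  col <- string_cohort(c(rep("A", 9), "G"), rep("healthy", 10))
  p <- c(0.9, 0.1)
  expect_equal(nt_site_variability(col, 1), -sum(p * log(p)) / log(4))
  expect_gt(nt_site_variability(col, 1), 0)
  expect_lt(nt_site_variability(col, 1), 1)
  expect_error(nt_site_variability(string_cohort("A", "healthy"), 1),
               class = "mitotier_insufficient_data")
})

test_that("nucleotide variability is invariant under allele relabelling", {
  counts <- c(5, 3, 2, 0)
  perms <- list(c(1, 2, 3, 4), c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))
  vals <- vapply(perms, function(pm) {
    bases <- rep(c("A", "C", "G", "T")[pm], counts)
    nt_site_variability(string_cohort(bases, rep("healthy", sum(counts))), 1)
  }, numeric(1))
  expect_true(all(abs(vals - vals[1]) < 1e-12))
})

test_that("synonymous-only variation gives aa_var 0 while nt_var > 0", {
  # CTA and CTG both encode Leu under the mitochondrial code
  ref <- cds_ref(c("ATG", "CTA", "AAA"))
  cohort <- string_cohort(c(rep("ATGCTAAAA", 5), rep("ATGCTGAAA", 5)),
                          rep("healthy", 10))
  expect_gt(nt_site_variability(cohort, 6), 0)
  expect_equal(aa_site_variability(cohort, ref, "CDS1", 2), 0)
})

test_that("a 50/50 residue split equals two-symbol entropy over the 21-letter alphabet", {
  # CTA (Leu) vs CCA (Pro) at codon 2
  ref <- cds_ref(c("ATG", "CTA", "AAA"))
  cohort <- string_cohort(c(rep("ATGCTAAAA", 4), rep("ATGCCAAAA", 4)),
                          rep("healthy", 8))
  expect_equal(aa_site_variability(cohort, ref, "CDS1", 2), log(2) / log(21))
  expect_error(aa_site_variability(cohort, ref, "missing", 2),
               class = "mitotier_locus_type_error")
})

test_that("aa variability rejects non-CDS loci and sparse codons", {
  ref <- toy_reference()
  cohort <- string_cohort(rep(ref$sequence, 3), rep("healthy", 3))
  expect_error(aa_site_variability(cohort, ref, "TOY-TRNA1", 1),
               class = "mitotier_locus_type_error")
  gapped <- string_cohort(
    c(ref$sequence,
      paste0(substr(ref$sequence, 1, 100), "N",
             substr(ref$sequence, 102, 600)),
      paste0(substr(ref$sequence, 1, 100), "-",
             substr(ref$sequence, 102, 600))),
    rep("healthy", 3))
  expect_error(aa_site_variability(gapped, ref, "TOY-CDS1", 1),
               class = "mitotier_insufficient_data")
})

test_that("planted allele frequencies are recovered within 1/N", {
  for (seed in 1:3) {
    spec <- default_simulation_spec(seed = seed)
    sim <- generate_cohort(spec)
    cat <- enumerate_potential(sim$reference)
    stats <- cohort_stats(sim$cohort, cat, sim$reference)
    k <- match(variant_key(sim$truth$position, sim$truth$ref, sim$truth$alt),
               variant_key(stats$position, stats$ref, stats$alt))
    n <- sim$cohort$n_total
    expect_true(all(abs(stats$af_total[k] -
                          (spec$planted$af_healthy * sim$cohort$n_healthy +
                             spec$planted$af_pathologic *
                               sim$cohort$n_pathologic) / n) <= 1 / n))
    expect_equal(stats$af_total[k], sim$truth$af_total)
    expect_equal(stats$af_healthy[k], sim$truth$af_healthy)
    expect_equal(stats$af_pathologic[k], sim$truth$af_pathologic)
  }
})

test_that("manifest validation books healthy and pathologic genomes", {
  manifest <- data.frame(
    genome_id = paste0("g", 1:10),
    status = rep(c("healthy", "pathologic"), c(7, 3)))
  counts <- validate_manifest(manifest)
  expect_equal(counts$n_total, 10)
  expect_equal(counts$n_healthy + counts$n_pathologic, counts$n_total)
  bad <- manifest; bad$status[1] <- "case"
  expect_error(validate_manifest(bad), class = "mitotier_manifest_error")
  dup <- manifest; dup$genome_id[2] <- "g1"
  expect_error(validate_manifest(dup), class = "mitotier_manifest_error")
})

test_that("cohorts round-trip through FASTA + manifest files", {
  spec <- default_simulation_spec(seed = 11)
  dir <- tempfile()
  sim <- generate_cohort(spec, dir = dir)
  cohort <- read_cohort(file.path(dir, "genomes.fasta"),
                        file.path(dir, "manifest.tsv"))
  expect_equal(cohort$alleles, sim$cohort$alleles)
  expect_equal(cohort$status, sim$cohort$status)
  expect_equal(cohort$n_healthy, spec$n_healthy)
})
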