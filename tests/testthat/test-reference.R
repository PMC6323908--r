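test_that("locus lookup resolves positions, boundaries and wraparound", {
  ref <- toy_reference()
  hit <- locus_of(ref, 430)
  expect_equal(hit$name, "TOY-TRNA1")
  expect_equal(hit$type, "tRNA")
  expect_equal(locus_of(ref, 50)$type, "intergenic")
  expect_error(locus_of(ref, 0), class = "mitotier_coordinate_error")
  expect_error(locus_of(ref, 601), class = "mitotier_coordinate_error")
  # position L on a circular reference is a valid lookup
  expect_equal(locus_of(ref, 600)$name, "TOY-DLOOP")

  # origin-spanning regulatory locus: both arms resolve to it
  rcrs <- synthetic_rcrs()
  expect_equal(locus_of(rcrs, 16569)$name, "MT-CR")
  expect_equal(locus_of(rcrs, 1)$name, "MT-CR")
  expect_equal(locus_of(rcrs, 576)$name, "MT-CR")
  expect_equal(locus_of(rcrs, 577)$name, "MT-TF")
})

test_that("overlapping annotations use the priority tie-break and keep secondaries", {
  rcrs <- synthetic_rcrs()
  # MT-ATP8 (8366-8572) and MT-ATP6 (8527-9207) overlap; earlier start wins
  prim <- locus_of(rcrs, 8550)
  expect_equal(prim$name, "MT-ATP8")
  all_hits <- locus_of(rcrs, 8550, all = TRUE)
  expect_setequal(all_hits$name, c("MT-ATP8", "MT-ATP6"))
  # CDS outranks tRNA where a tRNA abuts inside a CDS-overlap window
  expect_equal(locus_of(rcrs, 10760)$name, "MT-ND4L")
})

test_that("CDS effect calls match a full-translation oracle at every position", {
  ref <- toy_reference()
  cds <- ref$loci[ref$loci$name == "TOY-CDS1", ]
  gene <- substr(ref$sequence, cds$start, cds$end)
  aa_ref <- translate_cds(gene)
  for (pos in seq(cds$start, cds$end)) {
    for (alt in setdiff(c("A", "C", "G", "T"), ref$bases[pos])) {
      mut <- gene
      substr(mut, pos - cds$start + 1, pos - cds$start + 1) <- alt
      aa_alt <- translate_cds(mut)
      i <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
      want <- if (length(i) == 0) "synonymous" else {
        a1 <- substr(aa_ref, i, i); a2 <- substr(aa_alt, i, i)
        if (a1 != "*" && a2 == "*") "stop-gain"
        else if (a1 == "*" && a2 != "*") "stop-loss"
        else "non-synonymous"
      }
      expect_equal(classify_substitution(ref, pos, alt), want,
                   label = sprintf("pos %d alt %s", pos, alt))
    }
  }
})

test_that("minus-strand CDS substitutions are classified on the coding strand", {
  ref <- toy_reference()
  cds <- ref$loci[ref$loci$name == "TOY-CDS2", ]
  gene <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ref$sequence, cds$start, cds$end))))
  aa_ref <- translate_cds(gene)
  for (pos in seq(cds$start, cds$end)) {
    for (alt in setdiff(c("A", "C", "G", "T"), ref$bases[pos])) {
      mut <- gene
      j <- cds$end - pos + 1  # coding-strand coordinate
      substr(mut, j, j) <- chartr("ACGT", "TGCA", alt)
      aa_alt <- translate_cds(mut)
      i <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
      want <- if (length(i) == 0) "synonymous" else {
        a1 <- substr(aa_ref, i, i); a2 <- substr(aa_alt, i, i)
        if (a1 != "*" && a2 == "*") "stop-gain"
        else if (a1 == "*" && a2 != "*") "stop-loss"
        else "non-synonymous"
      }
      expect_equal(classify_substitution(ref, pos, alt), want,
                   label = sprintf("pos %d alt %s", pos, alt))
    }
  }
})

test_that("every sense-to-stop change over the 64-codon table is stop-gain", {
  code <- mito_genetic_code()
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  for (codon in codons) {
    ref <- cds_ref(c("ATG", codon, "CTA"))
    for (k in 1:3) {
      b <- substr(codon, k, k)
      for (alt in setdiff(bases, b)) {
        mut <- codon
        substr(mut, k, k) <- alt
        got <- classify_substitution(ref, 3L + k, alt)
        want <- if (code[[codon]] == code[[mut]]) "synonymous"
        else if (code[[codon]] != "*" && code[[mut]] == "*") "stop-gain"
        else if (code[[codon]] == "*" && code[[mut]] != "*") "stop-loss"
        else "non-synonymous"
        expect_equal(got, want, label = paste(codon, "->", mut))
      }
    }
  }
  # the mitochondrial code's idiosyncrasies are in force
  expect_equal(unname(code["TGA"]), "W")
  expect_equal(unname(code["AGA"]), "*")
  expect_equal(unname(code["ATA"]), "M")
})

test_that("non-coding loci take their locus type as class", {
  ref <- toy_reference()
  expect_equal(classify_substitution(ref, 430, "A"), "tRNA")
  expect_equal(classify_substitution(ref, 500, "A"), "rRNA")
  expect_equal(classify_substitution(ref, 590, "G"), "regulatory")
  expect_equal(classify_substitution(ref, 50, "C"), "intergenic")
})

test_that("classification is pure and validates its inputs", {
  ref <- toy_reference()
  expect_identical(classify_substitution(ref, 131, "A"),
                   classify_substitution(ref, 131, "A"))
  expect_error(classify_substitution(ref, 131, "A", ref_allele = "C"),
               class = "mitotier_reference_mismatch")
  expect_error(classify_substitution(ref, 131, "N"),
               class = "mitotier_unsupported_allele")
  expect_error(classify_substitution(ref, 131, ref$bases[131]),
               class = "mitotier_allele_error")
})

test_that("locus tables are validated and BED input converts coordinates once", {
  expect_error(
    mt_reference("ACGTACGTACGT",
                 loci = data.frame(name = "x", type = "CDS", start = 1,
                                   end = 11, strand = "+")),
    class = "mitotier_locus_error")  # length not a codon multiple
  expect_error(
    mt_reference("ACGTACGTACGT",
                 loci = data.frame(name = "x", type = "gene", start = 1,
                                   end = 12, strand = "+")),
    class = "mitotier_locus_error")
  bed <- tempfile(fileext = ".bed")
  writeLines("chrM\t0\t12\tx\t0\t+\tCDS\t1", bed)
  loci <- read_locus_bed(bed)
  expect_equal(loci$start, 1L)
  expect_equal(loci$end, 12L)
  ref <- mt_reference("ACGTACGTACGT", loci = loci, circular = FALSE)
  expect_equal(locus_of(ref, 1)$name, "x")
})
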