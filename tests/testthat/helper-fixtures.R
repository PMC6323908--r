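# Shared fixture builders: tiny references and cohorts constructed in code.

# a linear reference whose whole sequence is one plus-strand CDS
cds_ref <- function(codons, name = "cds_ref") {
  seq <- paste(codons, collapse = "")
  loci <- data.frame(name = "CDS1", type = "CDS", start = 1L,
                     end = nchar(seq), strand = "+", frame = 1L,
                     stringsAsFactors = FALSE)
  mt_reference(seq, loci = loci, name = name, circular = FALSE)
}

# a cohort from explicit genome strings (one string per genome)
string_cohort <- function(genomes, status) {
  m <- do.call(rbind, strsplit(genomes, "", fixed = TRUE))
  rownames(m) <- paste0("g", seq_along(genomes))
  mt_cohort(m, status)
}

# independent translation oracle: full-gene translation via Biostrings
translate_cds <- function(seq) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(seq),
    genetic.code = Biostrings::getGeneticCode("2"),
    no.init.codon = TRUE))
}

# an evidence data frame row in the logical in-memory form
evidence_row <- function(position, ref, alt, profile, available) {
  row <- data.frame(position = position, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  for (cr in trna_criteria()) row[[cr]] <- unname(profile[cr])
  row$evidence_available <- available
  row
}
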