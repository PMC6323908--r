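# Shared constants and error helper (loaded before the modules that use
# them at top level).

BASES <- c("A", "C", "G", "T")
CALLED <- BASES  # bases that count as called at a site
LOCUS_TYPES <- c("CDS", "tRNA", "rRNA", "regulatory")
# tie-break priority when annotations overlap
TYPE_PRIORITY <- c(CDS = 1L, tRNA = 2L, rRNA = 3L, regulatory = 4L)
FUNCTIONAL_CLASSES <- c("synonymous", "non-synonymous", "stop-gain",
                        "stop-loss", "tRNA", "rRNA", "regulatory",
                        "intergenic")
TIER_LEVELS <- c("Pathogenic", "Likely Pathogenic", "Likely Polymorphic",
                 "Polymorphic", "VUS", "Unclassified")

abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "mitotier_error")))
}
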