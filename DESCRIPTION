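Package: mitotier
Title: Human Mitochondrial DNA Variant Annotation and Pathogenicity Tiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotation of single-nucleotide substitutions on the human
    mitochondrial genome (rCRS coordinate model) and classification into
    pathogenicity tiers. Enumerates the complete potential substitution
    space, estimates allele frequencies and per-site variability from
    health-stratified cohorts of complete mtDNA genomes, scores mt-tRNA
    variants with a normalized nine-criterion disease score, builds a
    consensus disease score for non-synonymous variants from pathogenicity
    predictor probabilities, and assigns each scored variant to a tier
    (Pathogenic, Likely Pathogenic, Likely Polymorphic, Polymorphic, VUS)
    from joint disease-score and allele-frequency thresholds. Includes a
    deterministic synthetic-cohort simulator, annotated VCF and variant-card
    JSON output, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
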