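---
title: "Scoring and tiering mitochondrial DNA substitutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and tiering mitochondrial DNA substitutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotier)
```

## The problem

Human mitochondrial DNA is a 16,569 bp circular genome whose variants range
from haplogroup-defining polymorphisms to substitutions that disrupt
oxidative phosphorylation. Because mtDNA is haploid per consensus genome,
densely annotated, and sequenced at scale in both healthy individuals and
patients, a practical pathogenicity assessment can be built from two
complementary signals: a *disease score* (DS) summarizing evidence of
harmfulness, and the *allele frequency* (AF) of the variant across a large
cohort of complete genomes — a variant common in the population is unlikely
to be strongly deleterious. `mitotier` implements that assessment end to
end: substitution-space enumeration, cohort statistics, two disease-scoring
schemes, and the joint DS/AF tier rules.

## Coordinate model and effect calling

Positions are 1-based on a circular reference; loci with `start > end` span
the origin and are handled with an explicit wraparound flag (the regulatory
control region is the canonical case). CDS effect calling translates the
affected codon with the vertebrate mitochondrial genetic code (translation
table 2: TGA→Trp, ATA→Met, AGA/AGG→stop) before and after the substitution.
Minus-strand genes are classified on the coding strand. Where annotations
overlap (MT-ATP8/MT-ATP6, MT-ND4L/MT-ND4), the primary annotation is chosen
by locus-type priority (CDS > tRNA > rRNA > regulatory), then by start
position; `locus_of(..., all = TRUE)` retains the secondary contexts. This
tie-break is the package's own convention — there is no field standard for
primary assignment in overlapping mitochondrial reading frames.

Two deliberate simplifications: CDS loci must have codon-multiple lengths
(mitochondrial genes whose stop codons are completed by polyadenylation are
not modelled), and insertions/deletions are out of scope throughout — the
catalogue is a substitution space, exactly 3 alleles per site, 3L = 49,707
for the full-length genome.

## Cohort statistics

Genomes are consensus sequences aligned to the reference and labelled
`healthy` or `pathologic`. Allele frequency is computed over genomes, not
chromosomes: carriers of the alternate base divided by genomes with a
called base (A/C/G/T) at the site, within the requested stratum. Gaps and
Ns leave both numerator and denominator. An empty stratum is an error, not
a zero — an undefined frequency must not masquerade as absence. The default
AF used for tier assignment is the all-genomes frequency; both stratum
frequencies are always reported alongside it.

Site variability is the normalized Shannon entropy of the allele column:
`nt_var` = H/log 4 over nucleotides, `aa_var` = H/log 21 over translated
residues (20 amino acids + stop). Both lie in [0, 1], are 0 for monomorphic
columns, 1 at a uniform column, are invariant under allele relabelling, and
increase with decreasing functional constraint — the properties the
published variability metrics for this resource are documented to satisfy.
The entropy form is this package's formulation (the original SiteVar /
MitVarProt algorithms are specified in their own publications, not
reproduced here); it is isolated behind `nt_site_variability()` /
`aa_site_variability()` so an alternative statistic can be dropped in.

## tRNA disease score

Nine criteria with raw point weights in row order
(2, 1, 1, 2, 2, 2, 2, 5, 3): pathogenicity reported by more than one study,
PhastCons conservation, PhyloP conservation, heteroplasmy evidence, and
five functional-study criteria — disease segregation, histochemical
evidence, OXPHOS biochemical defect, cybrid or mt-tRNA steady-state
studies, single-fiber segregation. Weights are normalized by their total
(20), so the normalized weights sum to 1, a fully supported profile scores
exactly 1, and the cybrid criterion alone scores 0.25. The normalized
column is derived, never stored, so alternative raw weightings stay
consistent; conservation booleans are consumed as given (no PhastCons/PhyloP
cutoffs are computed here).

Unknown criteria contribute 0 — the score is a lower bound given the
evidence, and is monotone: recording a new satisfied criterion can only
raise it. The VUS flag is orthogonal to the score: a tRNA variant is VUS
exactly when no functional-study evidence is *available*, even if
conservation criteria already give it DS > 0. Evidence tables therefore
distinguish `no` (a study found nothing) from `unknown` (no study exists),
and the reader rejects tables asserting a functional `no` while declaring
evidence unavailable. Six further tRNA attributes (cloverleaf disruption,
post-transcriptional modification, 3D folding contacts, AF > 2%,
patient-vs-healthy frequency ratio, macrohaplogroup markers) are carried as
annotations only; they are deferred from scoring by design.

## Non-synonymous disease score

The non-synonymous DS is a consensus over external predictor probabilities:
a weighted mean with weights renormalized over the predictors that report a
value, so it is bounded by the available probabilities and invariant under
splitting a predictor's weight across duplicates. The default weighting is
uniform and the panel composition is the caller's. This is the package's
largest fidelity gap relative to the published resource: the original
consensus algorithm (its predictor set, weighting, and any variability
term) is specified in a separate publication, so the package ships the
general mechanism with configuration hooks rather than claiming the
published calibration. Stop-gain, stop-loss and frameshift records are
ineligible for scoring; synonymous, rRNA, regulatory and intergenic
variants are annotation-only and tier as `Unclassified`.

## Thresholds and tiers

The shipped operating points are the published constants: DS_T = 0.43
(non-synonymous) and 0.35 (tRNA); AF_T = 0.003264 and 0.005020. Both
comparisons are inclusive (`DS ≥ DS_T`, `AF ≤ AF_T`) everywhere, including
the estimation filter; where prose and rule tables disagree on strictness,
the rule tables' inclusive operators win, so a variant exactly at both
thresholds is Pathogenic. The four quadrants partition [0,1]²; VUS
overrides; potential variants carry AF = 0 and hence can never be Likely
Pathogenic once their DS clears the threshold.

`estimate_af_threshold()` re-derives AF_T as an empirical quantile of the
AF distribution among variants with DS ≥ DS_T. The published constants were
derived from a corpus of tens of thousands of genomes that is not bundled
here, and the quantile used is not recoverable from the published
description, so: the defaults are frozen constants (classification is
reproducible without re-estimation), and the estimator's quantile defaults
to 0.95 with the inverse-ECDF convention (`stats::quantile` type 1) — an
upper-tail choice consistent with AF_T sitting near the top of the
low-frequency mass of high-DS variants. Both are configurable
(`threshold_config()`, `read_threshold_config()`).

## Reporting conventions

Percentages are computed from integer counts and rounded half-up;
one-decimal rendering drops a trailing `.0` (7.0% prints as "7%"), and a
zero-digit rendering is available where integer percentages are the house
style. Among Pathogenic-tier variants the summary reports the fraction with
healthy-stratum AF = 0 — the expected signature of genuinely deleterious
variants, which persist only in patient genomes.

## The synthetic cohort generator

`generate_cohort()` emulates the study inputs: health-stratified complete
genomes plus per-variant evidence. Every genome starts as a copy of the
reference; each planted variant is placed in `round(AF × N)` genomes per
stratum (half-up), sampled without replacement under the spec seed. Carrier
counts — hence realized AFs and expected tiers — are functions of the spec
alone; the seed only moves which genomes carry. The truth table's expected
tier is computed by inline threshold arithmetic inside the generator,
deliberately independent of the classifier under test.

The default spec plants 26 variants on a 600 bp toy reference (one
100-codon plus-strand CDS, one tRNA, one rRNA, one 10-codon minus-strand
CDS, one regulatory locus) in 250 healthy + 250 pathologic genomes — sized
so a single carrier (AF = 0.002) sits below both AF thresholds, which keeps
all four tiers reachable at small N, while the whole pipeline runs in
seconds. The generator does not emulate phylogenetic structure, haplogroup
correlation, heteroplasmy, sequencing error, or indels: passing recovery
tests shows the pipeline's bookkeeping and rules are correct under planted
truth, not that the thresholds are well calibrated for real population
data.

The bundled full-length reference is a seeded random 16,569 bp sequence
with the canonical 37-gene locus layout (CDS ends nudged to codon
multiples, control region spanning the origin). It is labelled synthetic in
its filename and record header: length- and layout-dependent results
(enumeration counts, coverage arithmetic, coordinate behaviour) transfer to
the real genome; sequence-dependent ones do not.

## Numerical and degenerate-input choices

- Weight normalization requires a positive total; all-zero weights are an
  error, not NaN.
- An all-missing predictor panel yields an *unassigned* DS (`NA`), which
  tiers as `Unclassified`; JSON cards serialize it as an explicit `null`.
- Variability requires at least two called genomes (or fully called
  codons); below that it is an error rather than a spurious 0.
- Tier boundaries are exact floating-point comparisons against the
  configured constants; scores built from the default weights are sums of
  exact twentieths, so boundary cases like DS = 0.25 + 0.1 + 0.1 ≥ 0.35
  evaluate reliably.
- VCF INFO values cannot contain spaces, so tier labels are written with
  underscores and decoded on read; JSON output uses the exact controlled
  vocabulary.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on generated data:
the 600 bp toy reference with 500-genome cohorts for end-to-end recovery
(seconds), exhaustive 512-profile and 101×101-grid enumerations for the
scoring and tier properties, and one full 49,707-variant enumeration of the
bundled synthetic full-length reference. These sizes were chosen as the
smallest that exercise every code path exhaustively rather than by
sampling.
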