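# Cohort handling: allele frequencies per health stratum and per-site
# variability scores.
#
# Genomes are consensus mtDNA sequences, treated as haploid: frequencies
# count genomes, and the denominator at a site is the number of genomes with
# a called base (A/C/G/T) there — gaps and Ns are excluded from both sides.

#' Build a genome cohort from an alignment matrix
#'
#' @param alleles Character matrix, genomes in rows and reference positions
#'   in columns; entries in A/C/G/T/N/-.
#' @param status Health status per genome: `"healthy"` or `"pathologic"`.
#' @param genome_ids Optional genome identifiers (default from rownames).
#' @return An object of class `mt_cohort` with the matrix, statuses and
#'   counts `n_total`, `n_healthy`, `n_pathologic`.
#' @export
mt_cohort <- function(alleles, status, genome_ids = rownames(alleles)) {
  stopifnot(is.matrix(alleles), nrow(alleles) == length(status))
  if (any(!status %in% c("healthy", "pathologic")))
    abort("genome status must be 'healthy' or 'pathologic'",
          "mitotier_manifest_error")
  if (is.null(genome_ids)) genome_ids <- paste0("g", seq_len(nrow(alleles)))
  structure(
    list(alleles = alleles, status = status, genome_ids = genome_ids,
         n_total = nrow(alleles),
         n_healthy = sum(status == "healthy"),
         n_pathologic = sum(status == "pathologic"),
         length = ncol(alleles)),
    class = "mt_cohort"
  )
}

#' @export
print.mt_cohort <- function(x, ...) {
  cat("<mt_cohort> ", x$n_total, " genomes (", x$n_healthy, " healthy, ",
      x$n_pathologic, " pathologic), ", x$length, " positions\n", sep = "")
  invisible(x)
}

#' Validate a health-status manifest
#'
#' Checks the two-column manifest (`genome_id`, `status`) and returns the
#' stratum bookkeeping; the healthy and pathologic counts must sum to the
#' total number of genomes.
#'
#' @param manifest Data frame with columns `genome_id` and `status`, or path
#'   to a TSV with those columns.
#' @return List with `n_total`, `n_healthy`, `n_pathologic`.
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("genome_id", "status")
  if (!all(need %in% names(manifest)))
    abort("manifest needs columns genome_id, status",
          "mitotier_manifest_error")
  if (any(!manifest$status %in% c("healthy", "pathologic")))
    abort("manifest status values must be 'healthy' or 'pathologic'",
          "mitotier_manifest_error")
  if (anyDuplicated(manifest$genome_id))
    abort("duplicate genome_id in manifest", "mitotier_manifest_error")
  n_h <- sum(manifest$status == "healthy")
  n_p <- sum(manifest$status == "pathologic")
  stopifnot(n_h + n_p == nrow(manifest))
  list(n_total = nrow(manifest), n_healthy = n_h, n_pathologic = n_p)
}

#' Read a genome cohort from a multi-FASTA alignment and a status manifest
#'
#' All records must have the reference length (the input is an alignment to
#' the reference, not raw reads); gaps (`-`) and `N` mark uncalled sites.
#'
#' @param fasta Path to the aligned multi-FASTA.
#' @param manifest Manifest data frame or TSV path (see
#'   [validate_manifest()]).
#' @return An [mt_cohort()].
#' @export
read_cohort <- function(fasta, manifest) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (is.character(manifest))
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  validate_manifest(manifest)
  ids <- sub("\\s.*$", "", names(seqs))
  if (!setequal(ids, manifest$genome_id))
    abort("FASTA records and manifest genome_ids differ",
          "mitotier_manifest_error")
  len <- unique(Biostrings::width(seqs))
  if (length(len) != 1L)
    abort("all genomes must have the same aligned length",
          "mitotier_cohort_error")
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), "", fixed = TRUE))
  rownames(m) <- ids
  status <- manifest$status[match(ids, manifest$genome_id)]
  mt_cohort(m, status, ids)
}

stratum_rows <- function(cohort, stratum = c("all", "healthy", "pathologic")) {
  stratum <- match.arg(stratum)
  if (stratum == "all") seq_len(cohort$n_total)
  else which(cohort$status == stratum)
}

#' Allele frequency of a substitution in a cohort stratum
#'
#' The frequency of the allele causing the variation: the count of genomes
#' carrying the alternate base at the position, divided by the count of
#' genomes with a called base there, within the requested stratum.
#'
#' @param cohort An [mt_cohort()].
#' @param position 1-based reference position.
#' @param alt Alternate allele (single base).
#' @param stratum `"all"`, `"healthy"` or `"pathologic"`.
#' @return Frequency in \[0, 1\].
#' @export
allele_frequency <- function(cohort, position, alt,
                             stratum = c("all", "healthy", "pathologic")) {
  rows <- stratum_rows(cohort, stratum)
  if (length(rows) == 0L)
    abort("empty stratum: allele frequency undefined",
          "mitotier_undefined_frequency")
  col <- cohort$alleles[rows, position]
  called <- col %in% CALLED
  if (!any(called))
    abort("no called genomes at position: allele frequency undefined",
          "mitotier_undefined_frequency")
  sum(col[called] == alt) / sum(called)
}

entropy_variability <- function(counts, alphabet_size) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  h <- -sum(p * log(p))
  h / log(alphabet_size)
}

#' Nucleotide variability of a reference site
#'
#' Normalized Shannon entropy of the called allele column (base-4
#' logarithm): 0 for a monomorphic site, 1 when the four bases are
#' equiprobable. Higher values indicate lower functional constraint.
#'
#' @param cohort An [mt_cohort()].
#' @param position 1-based reference position.
#' @return `nt_var` in \[0, 1\].
#' @export
nt_site_variability <- function(cohort, position) {
  col <- cohort$alleles[, position]
  col <- col[col %in% CALLED]
  if (length(col) < 2L)
    abort("fewer than 2 called genomes at position",
          "mitotier_insufficient_data")
  entropy_variability(table(factor(col, levels = BASES)), 4L)
}

codon_column <- function(cohort, locus, codon_index) {
  if (locus$strand == "+") {
    pos <- locus$frame + 3L * (codon_index - 1L) + 0:2
  } else {
    pos <- locus$frame - 3L * (codon_index - 1L) - 0:2
  }
  if (any(pos < locus$start | pos > locus$end))
    abort("codon index outside the CDS locus", "mitotier_coordinate_error")
  m <- cohort$alleles[, pos, drop = FALSE]
  if (locus$strand == "-") m[] <- complement_base(m)
  ok <- rowSums(matrix(m %in% BASES, nrow = nrow(m))) == 3L
  codons <- paste0(m[, 1L], m[, 2L], m[, 3L])
  codons[ok]
}

#' Amino-acid variability of a codon site
#'
#' Translates the codon column with the vertebrate mitochondrial code and
#' applies the same normalized-entropy statistic as
#' [nt_site_variability()] over the 21-letter residue alphabet (20 amino
#' acids plus stop). Genomes with an uncalled base anywhere in the codon are
#' excluded.
#'
#' @param cohort An [mt_cohort()].
#' @param reference The [mt_reference()] the cohort is aligned to.
#' @param locus_name Name of a CDS locus in the reference's locus map.
#' @param codon_index 1-based codon number within the CDS.
#' @return `aa_var` in \[0, 1\].
#' @export
aa_site_variability <- function(cohort, reference, locus_name, codon_index) {
  loci <- reference$loci
  i <- match(locus_name, loci$name)
  if (is.na(i) || loci$type[i] != "CDS")
    abort("aa variability requires a CDS locus", "mitotier_locus_type_error")
  codons <- codon_column(cohort, loci[i, ], codon_index)
  if (length(codons) < 2L)
    abort("fewer than 2 fully called codons", "mitotier_insufficient_data")
  residues <- unname(mito_genetic_code()[codons])
  entropy_variability(table(residues), 21L)
}

#' Per-variant cohort statistics for a catalogue
#'
#' Computes, for every catalogue variant, the allele frequency overall and
#' per health stratum, the nucleotide variability of its site, and — for CDS
#' variants — the amino-acid variability of its codon.
#'
#' @param cohort An [mt_cohort()].
#' @param catalogue A catalogue from [enumerate_potential()].
#' @param reference The [mt_reference()] shared by both.
#' @return Data frame with columns `position`, `ref`, `alt`, `af_total`,
#'   `af_healthy`, `af_pathologic`, `nt_var`, `aa_var` (NA outside CDS).
#' @export
cohort_stats <- function(cohort, catalogue, reference) {
  stopifnot(cohort$length == reference$length)
  h_rows <- stratum_rows(cohort, "healthy")
  p_rows <- stratum_rows(cohort, "pathologic")
  pos_u <- unique(catalogue$position)
  nt <- vapply(pos_u, function(p) nt_site_variability(cohort, p), numeric(1))
  names(nt) <- pos_u

  af_one <- function(rows, p, a) {
    if (length(rows) == 0L) return(NA_real_)
    col <- cohort$alleles[rows, p]
    called <- col %in% CALLED
    if (!any(called)) return(NA_real_)
    sum(col[called] == a) / sum(called)
  }
  n <- nrow(catalogue)
  af_total <- af_healthy <- af_pathologic <- numeric(n)
  for (i in seq_len(n)) {
    p <- catalogue$position[i]; a <- catalogue$alt[i]
    af_total[i] <- af_one(seq_len(cohort$n_total), p, a)
    af_healthy[i] <- af_one(h_rows, p, a)
    af_pathologic[i] <- af_one(p_rows, p, a)
  }

  aa <- rep(NA_real_, n)
  li <- locus_index(reference)[catalogue$position]
  cds <- which(!is.na(li) & reference$loci$type[li] == "CDS" &
                 catalogue$locus_type == "CDS")
  if (length(cds) > 0L) {
    lo <- reference$loci[li[cds], , drop = FALSE]
    ci <- ifelse(lo$strand == "+",
                 (catalogue$position[cds] - lo$frame) %/% 3L,
                 (lo$frame - catalogue$position[cds]) %/% 3L) + 1L
    key <- paste(lo$name, ci)
    for (k in unique(key)) {
      sel <- cds[key == k]
      aa[sel] <- aa_site_variability(cohort, reference,
                                     lo$name[key == k][1L],
                                     ci[key == k][1L])
    }
  }
  data.frame(position = catalogue$position, ref = catalogue$ref,
             alt = catalogue$alt, af_total = af_total,
             af_healthy = af_healthy, af_pathologic = af_pathologic,
             nt_var = nt[as.character(catalogue$position)],
             aa_var = aa, row.names = NULL, stringsAsFactors = FALSE)
}
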