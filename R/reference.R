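# Reference coordinate model, locus map and functional-effect calling.
#
# Coordinates are 1-based inclusive throughout (HGVS-style m.POS REF>ALT);
# BED input is converted at the boundary. The reference is circular by
# default, so a locus may span the origin (start > end, flagged `wraps`).

#' Construct a mitochondrial reference model
#'
#' Bundles a (by default circular) reference sequence with a typed locus map.
#' Positions are 1-based inclusive; a locus with `start > end` spans the
#' circular origin and is flagged `wraps` (only non-CDS loci may wrap).
#'
#' @param sequence Reference sequence: a single character string or a
#'   `Biostrings::DNAString`; bases must be A/C/G/T/N.
#' @param loci Locus table (see [read_locus_table()]) or `NULL`.
#' @param name Accession or display name for the reference.
#' @param circular Logical; whether the molecule is circular.
#' @return An object of class `mt_reference` with elements `name`,
#'   `sequence`, `bases` (per-position character vector), `length`,
#'   `circular` and `loci`.
#' @export
mt_reference <- function(sequence, loci = NULL, name = "reference",
                         circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L, nchar(sequence) > 0L)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(bases), c(BASES, "N"))
  if (length(bad) > 0L)
    abort(paste0("reference contains unsupported characters: ",
                 paste(bad, collapse = ", ")),
          "mitotier_reference_error")
  L <- length(bases)
  if (!is.null(loci)) loci <- validate_loci(loci, L, circular)
  structure(
    list(name = name, sequence = sequence, bases = bases, length = L,
         circular = isTRUE(circular), loci = loci),
    class = "mt_reference"
  )
}

#' @export
print.mt_reference <- function(x, ...) {
  cat("<mt_reference> ", x$name, ": ", x$length, " bp, ",
      if (x$circular) "circular" else "linear", "\n", sep = "")
  if (!is.null(x$loci)) {
    tab <- table(x$loci$type)
    cat("  loci: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

validate_loci <- function(loci, L, circular) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("name", "type", "start", "end", "strand")
  missing_cols <- setdiff(need, names(loci))
  if (length(missing_cols) > 0L)
    abort(paste0("locus table lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          "mitotier_locus_error")
  if (!"frame" %in% names(loci)) loci$frame <- NA_integer_
  loci$start <- as.integer(loci$start)
  loci$end <- as.integer(loci$end)
  loci$frame <- as.integer(loci$frame)
  if (any(!loci$type %in% LOCUS_TYPES))
    abort("locus type must be one of CDS, tRNA, rRNA, regulatory",
          "mitotier_locus_error")
  if (any(!loci$strand %in% c("+", "-")))
    abort("locus strand must be '+' or '-'", "mitotier_locus_error")
  if (any(loci$start < 1L | loci$start > L | loci$end < 1L | loci$end > L))
    abort("locus coordinates outside [1, L]", "mitotier_locus_error")
  loci$wraps <- loci$start > loci$end
  if (any(loci$wraps & !circular))
    abort("origin-spanning locus on a non-circular reference",
          "mitotier_locus_error")
  cds <- loci$type == "CDS"
  if (any(cds & loci$wraps))
    abort("origin-spanning CDS loci are not supported",
          "mitotier_locus_error")
  # default reading-frame origin: first transcribed base
  fix <- cds & is.na(loci$frame)
  loci$frame[fix] <- ifelse(loci$strand[fix] == "+",
                            loci$start[fix], loci$end[fix])
  len <- loci$end - loci$start + 1L
  if (any(cds & len %% 3L != 0L))
    abort("CDS locus length must be a multiple of 3",
          "mitotier_locus_error")
  bad_frame <- cds & (loci$frame < loci$start | loci$frame > loci$end)
  if (any(bad_frame))
    abort("CDS frame origin must lie inside the locus",
          "mitotier_locus_error")
  rownames(loci) <- NULL
  loci[, c("name", "type", "start", "end", "strand", "frame", "wraps")]
}

#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file; the first record is used.
#' @param loci Optional locus table to attach (see [read_locus_table()]).
#' @param circular Logical; default `TRUE` (mtDNA is circular).
#' @return An [mt_reference()] object.
#' @export
read_reference <- function(path, loci = NULL, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L)
    abort("no sequences in FASTA", "mitotier_reference_error")
  nm <- sub("\\s.*$", "", names(seqs)[1L])
  mt_reference(as.character(seqs[[1L]]), loci = loci, name = nm,
               circular = circular)
}

#' Read a tab-separated locus table
#'
#' Expected columns: `name`, `type` (CDS/tRNA/rRNA/regulatory), `start`,
#' `end` (1-based inclusive; `start > end` marks an origin-spanning locus),
#' `strand` (+/-), and optionally `frame` (1-based position of the first
#' base of codon 1; CDS only, defaults to the first transcribed base).
#'
#' @param path Path to the TSV file (header required).
#' @return A data frame suitable for [mt_reference()].
#' @export
read_locus_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a locus map in BED format
#'
#' BED intervals are 0-based half-open and are converted to the package's
#' 1-based inclusive convention exactly once, here. Columns beyond the BED6
#' set are interpreted as `type` (column 7) and `frame` (column 8, 1-based).
#'
#' @param path Path to the BED file (no header).
#' @return A data frame suitable for [mt_reference()].
#' @export
read_locus_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 7L)
    abort("locus BED needs 7+ columns (chrom start end name score strand type [frame])",
          "mitotier_locus_error")
  data.frame(
    name = bed[[4L]],
    type = bed[[7L]],
    start = as.integer(bed[[2L]]) + 1L,
    end = as.integer(bed[[3L]]),
    strand = bed[[6L]],
    frame = if (ncol(bed) >= 8L) as.integer(bed[[8L]]) else NA_integer_,
    stringsAsFactors = FALSE
  )
}

check_positions <- function(reference, position) {
  position <- as.integer(position)
  if (any(is.na(position) | position < 1L | position > reference$length))
    abort(sprintf("position outside [1, %d]", reference$length),
          "mitotier_coordinate_error")
  position
}

locus_positions <- function(locus, L) {
  if (locus$wraps) c(locus$start:L, 1L:locus$end) else locus$start:locus$end
}

# Per-position index of the primary locus (NA = intergenic). Ties are broken
# by locus-type priority (CDS > tRNA > rRNA > regulatory), then by start.
locus_index <- function(reference) {
  loci <- reference$loci
  idx <- rep(NA_integer_, reference$length)
  if (is.null(loci) || nrow(loci) == 0L) return(idx)
  ord <- order(TYPE_PRIORITY[loci$type], loci$start)
  for (i in rev(ord))
    idx[locus_positions(loci[i, ], reference$length)] <- i
  idx
}

intergenic_row <- function() {
  data.frame(name = "intergenic", type = "intergenic",
             start = NA_integer_, end = NA_integer_, strand = NA_character_,
             frame = NA_integer_, wraps = FALSE, stringsAsFactors = FALSE)
}

#' Locate the locus containing a position
#'
#' @param reference An [mt_reference()] with a locus map.
#' @param position 1-based position (scalar).
#' @param all If `TRUE`, return every containing locus (primary first);
#'   overlapping annotations beyond the primary are secondary contexts.
#' @return A one-row data frame describing the locus (a row with
#'   `type = "intergenic"` when no locus contains the position), or a
#'   multi-row data frame when `all = TRUE`.
#' @export
locus_of <- function(reference, position, all = FALSE) {
  position <- check_positions(reference, position)
  stopifnot(length(position) == 1L)
  loci <- reference$loci
  if (is.null(loci)) return(intergenic_row())
  inside <- ifelse(loci$wraps,
                   position >= loci$start | position <= loci$end,
                   position >= loci$start & position <= loci$end)
  hits <- which(inside)
  if (length(hits) == 0L) return(intergenic_row())
  hits <- hits[order(TYPE_PRIORITY[loci$type[hits]], loci$start[hits])]
  out <- loci[if (all) hits else hits[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Vertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid map (translation table 2): TGA = Trp, ATA = Met,
#' AGA/AGG = stop. Used for all CDS effect calling.
#'
#' @return Named character vector of length 64 (names are codons, `*` marks
#'   stop).
#' @export
mito_genetic_code <- function() {
  Biostrings::getGeneticCode("2")
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

# Codon context for CDS positions: reference codon (coding-strand sense),
# within-codon offset, and the effective coding-strand alt allele.
codon_context <- function(reference, position, alt, loci_rows) {
  plus <- loci_rows$strand == "+"
  off <- ifelse(plus, position - loci_rows$frame, loci_rows$frame - position)
  if (any(off < 0L))
    abort("position upstream of CDS frame origin", "mitotier_locus_error")
  ci <- off %/% 3L
  within <- off %% 3L
  p1 <- ifelse(plus, loci_rows$frame + 3L * ci, loci_rows$frame - 3L * ci)
  step <- ifelse(plus, 1L, -1L)
  m <- cbind(reference$bases[p1],
             reference$bases[p1 + step],
             reference$bases[p1 + 2L * step])
  minus <- !plus
  if (any(minus)) m[minus, ] <- complement_base(m[minus, , drop = FALSE])
  alt_eff <- ifelse(plus, alt, complement_base(alt))
  list(codon = m, within = within, alt_eff = alt_eff)
}

#' Classify a substitution's functional effect
#'
#' For CDS loci the affected codon is translated with the vertebrate
#' mitochondrial genetic code before and after the substitution:
#' unchanged residue is `synonymous`, a changed residue `non-synonymous`,
#' a gained stop `stop-gain`, a lost stop `stop-loss`. Variants in tRNA,
#' rRNA or regulatory loci take their locus type as class; positions outside
#' any locus are `intergenic`. When annotations overlap, the primary locus
#' (see [locus_of()]) drives the class.
#'
#' @param reference An [mt_reference()] with a locus map.
#' @param position 1-based position(s).
#' @param alt Alternate allele(s), single bases; recycled against `position`.
#' @param ref_allele Optional expected reference allele(s); a mismatch with
#'   the reference sequence is an error.
#' @return Character vector of functional classes.
#' @export
classify_substitution <- function(reference, position, alt,
                                  ref_allele = NULL) {
  position <- check_positions(reference, position)
  n <- max(length(position), length(alt))
  position <- rep_len(position, n)
  alt <- rep_len(toupper(alt), n)
  if (any(!alt %in% BASES))
    abort("alt allele must be one of A, C, G, T",
          "mitotier_unsupported_allele")
  refb <- reference$bases[position]
  if (!is.null(ref_allele)) {
    ref_allele <- rep_len(toupper(ref_allele), n)
    if (any(ref_allele != refb))
      abort("ref allele does not match the reference sequence",
            "mitotier_reference_mismatch")
  }
  if (any(alt == refb))
    abort("alt allele equals the reference base", "mitotier_allele_error")
  li <- locus_index(reference)[position]
  type <- ifelse(is.na(li), "intergenic", reference$loci$type[li])
  cls <- type
  is_cds <- type == "CDS"
  if (any(is_cds)) {
    idx <- which(is_cds)
    ctx <- codon_context(reference, position[idx], alt[idx],
                         reference$loci[li[idx], , drop = FALSE])
    if (any(!ctx$codon %in% BASES))
      abort("ambiguous base in affected codon",
            "mitotier_unsupported_allele")
    code <- mito_genetic_code()
    codon_ref <- paste0(ctx$codon[, 1L], ctx$codon[, 2L], ctx$codon[, 3L])
    m <- ctx$codon
    m[cbind(seq_along(idx), ctx$within + 1L)] <- ctx$alt_eff
    codon_alt <- paste0(m[, 1L], m[, 2L], m[, 3L])
    aa_ref <- unname(code[codon_ref])
    aa_alt <- unname(code[codon_alt])
    cls[idx] <- ifelse(aa_ref == aa_alt, "synonymous",
                ifelse(aa_ref != "*" & aa_alt == "*", "stop-gain",
                ifelse(aa_ref == "*" & aa_alt != "*", "stop-loss",
                       "non-synonymous")))
  }
  cls
}
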