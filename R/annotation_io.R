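# Interchange formats: annotated VCF (namespaced HV_* INFO fields),
# evidence/predictor TSVs, and variant-card JSON documents.
#
# Tier labels carry spaces, which are illegal inside VCF INFO values; the
# writer encodes them with underscores and the reader decodes them, so the
# controlled vocabulary round-trips intact. JSON cards use the exact labels.

VCF_INFO_KEYS <- c(
  HV_LOCUS = "Locus name containing the variant",
  HV_TYPE = "Locus type (CDS/tRNA/rRNA/regulatory/intergenic)",
  HV_CLASS = "Functional class of the substitution",
  HV_STATUS = "observed or potential",
  HV_AF = "Allele frequency over all genomes",
  HV_AF_H = "Allele frequency in healthy genomes",
  HV_AF_P = "Allele frequency in pathologic genomes",
  HV_NTVAR = "Nucleotide site variability (normalized entropy)",
  HV_AAVAR = "Amino-acid site variability (CDS only)",
  HV_DS = "Disease score",
  HV_VUS = "1 if flagged Variant of Undefined Significance, else 0",
  HV_TIER = "Pathogenicity tier"
)

fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))
fmt_str <- function(x) ifelse(is.na(x), ".", gsub(" ", "_", x))

#' Write an annotated catalogue as VCF 4.2
#'
#' One record per substitution, sorted by position then alt allele, with all
#' annotations carried in namespaced `HV_*` INFO fields declared in the
#' header. Allele frequencies of potential variants are written as explicit
#' zeros, never as missing.
#'
#' @param annotation An `mt_annotation` object or its annotation table (see
#'   [annotate_cohort()]).
#' @param path Output path.
#' @param contig Contig name for the header and CHROM column.
#' @param contig_length Reference length for the header.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(annotation, path, contig = "chrM",
                                contig_length = NULL) {
  tab <- as.data.frame(annotation)
  ord <- order(tab$position, tab$alt)
  if (!identical(ord, seq_len(nrow(tab)))) {
    warning("records were not sorted; sorting by position and alt")
    tab <- tab[ord, , drop = FALSE]
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mitotier",
    if (is.null(contig_length)) sprintf("##contig=<ID=%s>", contig)
    else sprintf("##contig=<ID=%s,length=%d>", contig, contig_length),
    sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
            names(VCF_INFO_KEYS),
            ifelse(names(VCF_INFO_KEYS) %in%
                     c("HV_AF", "HV_AF_H", "HV_AF_P", "HV_NTVAR",
                       "HV_AAVAR", "HV_DS"), "Float",
                   ifelse(names(VCF_INFO_KEYS) == "HV_VUS",
                          "Integer", "String")),
            VCF_INFO_KEYS),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  info <- paste0(
    "HV_LOCUS=", fmt_str(tab$locus_name),
    ";HV_TYPE=", fmt_str(tab$locus_type),
    ";HV_CLASS=", fmt_str(tab$functional_class),
    ";HV_STATUS=", fmt_str(tab$status),
    ";HV_AF=", fmt_num(tab$af_total),
    ";HV_AF_H=", fmt_num(tab$af_healthy),
    ";HV_AF_P=", fmt_num(tab$af_pathologic),
    ";HV_NTVAR=", fmt_num(tab$nt_var),
    ";HV_AAVAR=", fmt_num(tab$aa_var),
    ";HV_DS=", fmt_num(tab$ds),
    ";HV_VUS=", ifelse(tab$vus, "1", "0"),
    ";HV_TIER=", fmt_str(tab$tier)
  )
  recs <- paste(contig, tab$position,
                paste0("m.", tab$position, tab$ref, ">", tab$alt),
                tab$ref, tab$alt, ".", ".", info, sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read an annotated VCF written by [write_annotated_vcf()]
#'
#' @param path Path to the VCF file.
#' @return The annotation table (data frame), with tier labels decoded back
#'   to the controlled vocabulary.
#' @export
read_annotated_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  get_str <- function(key) {
    x <- vcfR::extract.info(vcf, element = key)
    x[x == "."] <- NA
    gsub("_", " ", x)
  }
  get_raw <- function(key) {
    x <- vcfR::extract.info(vcf, element = key)
    x[x == "."] <- NA
    x
  }
  get_num <- function(key) as.numeric(get_raw(key))
  data.frame(
    position = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    locus_name = get_raw("HV_LOCUS"),
    locus_type = get_raw("HV_TYPE"),
    functional_class = get_raw("HV_CLASS"),
    status = get_raw("HV_STATUS"),
    af_total = get_num("HV_AF"),
    af_healthy = get_num("HV_AF_H"),
    af_pathologic = get_num("HV_AF_P"),
    nt_var = get_num("HV_NTVAR"),
    aa_var = get_num("HV_AAVAR"),
    ds = get_num("HV_DS"),
    vus = get_num("HV_VUS") == 1,
    tier = get_str("HV_TIER"),
    stringsAsFactors = FALSE
  )
}

#' Write a tRNA evidence table as TSV
#'
#' Inverse of [read_trna_evidence()]: logical criteria become
#' `yes`/`no`/`unknown`.
#'
#' @param evidence Evidence data frame (logical criterion columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trna_evidence <- function(evidence, path) {
  out <- evidence
  to_str <- function(x) ifelse(is.na(x), "unknown", ifelse(x, "yes", "no"))
  for (cr in trna_criteria()) out[[cr]] <- to_str(out[[cr]])
  out$evidence_available <- ifelse(out$evidence_available, "yes", "no")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a predictor probability table as TSV
#'
#' Inverse of [read_predictor_table()]: missing calls become `.`.
#'
#' @param predictors Predictor data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictor_table <- function(predictors, path) {
  out <- predictors
  for (cl in setdiff(names(out), c("position", "ref", "alt")))
    out[[cl]] <- ifelse(is.na(out[[cl]]), ".", sprintf("%.17g", out[[cl]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

variant_name <- function(position, ref, alt) {
  paste0("m.", position, ref, ">", alt)
}

check_variant_key <- function(position, ref, alt) {
  ok <- length(position) == 1L && !is.na(suppressWarnings(as.integer(position))) &&
    as.integer(position) >= 1L &&
    length(ref) == 1L && ref %in% BASES &&
    length(alt) == 1L && alt %in% BASES && ref != alt
  if (!ok)
    abort("malformed variant key: need position >= 1 and distinct single bases",
          "mitotier_malformed_key")
  invisible(TRUE)
}

na_null <- function(x) if (is.null(x) || length(x) == 0L || is.na(x)) NA else x

#' Assemble a variant card
#'
#' Gathers everything known about one variant into a structured record with
#' a main-info block (locus and functional context), a variability block
#' (frequencies and site variability) and a pathogenicity block (disease
#' score, thresholds used, tier, VUS flag). For variants outside the scored
#' classes the pathogenicity block is explicitly null (annotation-only
#' record). Absent attributes are explicit nulls in the JSON rendering,
#' never silently omitted.
#'
#' @param annotation An `mt_annotation` object.
#' @param position,ref,alt The variant key.
#' @return A nested list (the card).
#' @export
variant_card <- function(annotation, position, ref, alt) {
  check_variant_key(position, ref, alt)
  tab <- annotation$table
  i <- which(tab$position == as.integer(position) & tab$ref == ref &
               tab$alt == alt)
  if (length(i) != 1L)
    abort(paste0("variant not found: ", variant_name(position, ref, alt)),
          "mitotier_not_found")
  row <- tab[i, ]
  scored <- row$functional_class %in% c("non-synonymous", "tRNA")
  th <- annotation$thresholds
  is_trna <- identical(row$functional_class, "tRNA")
  list(
    variant = list(
      name = variant_name(row$position, row$ref, row$alt),
      position = row$position, ref = row$ref, alt = row$alt
    ),
    main_info = list(
      locus = na_null(row$locus_name),
      locus_type = na_null(row$locus_type),
      functional_class = na_null(row$functional_class),
      status = na_null(row$status)
    ),
    variability = list(
      af_total = na_null(row$af_total),
      af_healthy = na_null(row$af_healthy),
      af_pathologic = na_null(row$af_pathologic),
      nt_var = na_null(row$nt_var),
      aa_var = na_null(row$aa_var)
    ),
    pathogenicity = if (!scored) NA else list(
      disease_score = na_null(row$ds),
      ds_threshold = if (is_trna) th$ds_t_trna else th$ds_t_nonsyn,
      af_threshold = if (is_trna) th$af_t_trna else th$af_t_nonsyn,
      vus = row$vus,
      tier = na_null(row$tier)
    )
  )
}

#' Serialize a variant card as JSON
#'
#' @inheritParams variant_card
#' @return A JSON string (UTF-8; unassigned values as `null`).
#' @export
variant_card_json <- function(annotation, position, ref, alt) {
  card <- variant_card(annotation, position, ref, alt)
  jsonlite::toJSON(card, auto_unbox = TRUE, na = "null", null = "null",
                   digits = NA)
}

#' Serialize a variant list as JSON
#'
#' Each element carries a limited set of basic information plus a locator
#' string pointing at the variant's complete card.
#'
#' @param annotation An `mt_annotation` object.
#' @param keys Data frame with columns `position`, `ref`, `alt`; default all
#'   variants in the annotation.
#' @param locator_prefix Prefix for the per-variant locator string.
#' @return A JSON string (array of summaries).
#' @export
variant_list_json <- function(annotation, keys = NULL,
                              locator_prefix = "/api/variant/") {
  tab <- annotation$table
  if (!is.null(keys)) {
    i <- match(variant_key(keys$position, keys$ref, keys$alt),
               variant_key(tab$position, tab$ref, tab$alt))
    if (anyNA(i))
      abort("variant not found in annotation", "mitotier_not_found")
    tab <- tab[i, , drop = FALSE]
  }
  nm <- variant_name(tab$position, tab$ref, tab$alt)
  out <- data.frame(name = nm, position = tab$position, ref = tab$ref,
                    alt = tab$alt, functional_class = tab$functional_class,
                    tier = tab$tier,
                    url = paste0(locator_prefix, nm),
                    stringsAsFactors = FALSE)
  jsonlite::toJSON(out, na = "null", digits = NA)
}
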