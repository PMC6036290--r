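#' Read population allele counts from a VCF
#'
#' Population databases (gnomAD, 1000 Genomes) distribute allele frequencies
#' as sites-only VCF with `AC`/`AN` INFO fields, plus per-population fields
#' such as `AC_sas`/`AN_sas`.  Parsing goes through
#' [VariantAnnotation::readVcf()]; multi-allelic sites are decomposed into one
#' record per alternate allele.
#'
#' @param path VCF file (v4.x, plain text or bgzipped).
#' @param populations Named character vector mapping population tags to INFO
#'   suffixes; the empty suffix `""` selects the plain `AC`/`AN` fields.
#'   Default: `c(GNOMAD_ALL = "")`.
#' @param gene_field,consequence_field Optional INFO fields carrying the gene
#'   symbol and an HGVS-style consequence annotation.  Absent annotations give
#'   gene `NA` and category `"other"`.
#' @return A variant tibble in the [read_variant_table()] layout.
#' @export
read_vcf <- function(path, populations = c(GNOMAD_ALL = ""),
                     gene_field = "GENE", consequence_field = "CONSEQ") {
  if (is.null(names(populations))) {
    abort("`populations` must be a named vector: c(TAG = \"info_suffix\")")
  }
  vcf0 <- VariantAnnotation::readVcf(path, genome = "GRCh37")
  site_ids <- names(SummarizedExperiment::rowRanges(vcf0))
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf0))
  vcf <- VariantAnnotation::expand(vcf0)  # one row per alt allele
  info <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)

  fld <- function(suffix, base) if (suffix == "") base else paste0(base, "_", suffix)
  for (suffix in populations) {
    for (base in c("AC", "AN")) {
      if (!fld(suffix, base) %in% names(info)) {
        abort(sprintf("VCF %s lacks INFO field %s", path, fld(suffix, base)))
      }
    }
  }

  # expand() drops row names; carry the site IDs over per alt allele
  ids <- if (is.null(site_ids)) rep(NA_character_, length(rr)) else {
    rep(site_ids, n_alt)
  }
  x <- tibble(
    gene  = if (gene_field %in% names(info)) as.character(info[[gene_field]]) else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos   = GenomicRanges::start(rr),
    rsid  = ifelse(!is.na(ids) & grepl("^rs", ids), ids, NA_character_),
    ref   = as.character(rr$REF),
    alt   = as.character(rr$ALT),
    consequence = if (consequence_field %in% names(info)) {
      as.character(info[[consequence_field]])
    } else NA_character_
  )
  x$category <- ifelse(is.na(x$consequence), "other",
                       consequence_category(x$consequence))
  for (s in ns_score_cols) {
    x[[s]] <- if (s == "condel_label") NA_character_ else NA_real_
  }
  csq_opt <- c(CONDEL = "condel", SIFT = "sift", PPH2 = "pph2")
  for (f in names(csq_opt)) {
    if (f %in% names(info)) x[[csq_opt[[f]]]] <- as.numeric(info[[f]])
  }
  for (tag in names(populations)) {
    suffix <- populations[[tag]]
    ac <- as.integer(info[[fld(suffix, "AC")]])
    an <- as.integer(info[[fld(suffix, "AN")]])
    if (any(ac > an, na.rm = TRUE)) {
      abort(sprintf("VCF %s: AC > AN for population %s", path, tag))
    }
    x[[paste0("ac_", tag)]] <- ac
    x[[paste0("an_", tag)]] <- an
  }
  x
}
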