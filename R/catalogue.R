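#' Read a pathogenic-variant catalogue
#'
#' A catalogue is the lookup set of variants already reported as disease
#' causing (HGMD / ClinVar style): TSV with columns `chrom`, `pos`, `ref`,
#' `alt`, optional `rsid`, `source_id` (e.g. an HGMD `CM######` accession or a
#' ClinVar accession) and free-text `significance`.  Catalogue membership, by
#' genomic key or by rsID fallback, defines the "known pathogenic" curation
#' class.
#'
#' @param path TSV file path.
#' @return A tibble of unique entries with class `ns_catalogue`.  Duplicate
#'   keys keep the first entry with a warning.
#' @export
read_catalogue <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "-"), progress = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(sprintf("catalogue %s is missing column(s): %s",
                  path, paste(miss, collapse = ", ")))
  }
  x <- tibble(
    chrom = raw$chrom, pos = as.integer(raw$pos),
    ref = raw$ref, alt = raw$alt,
    rsid = if ("rsid" %in% names(raw)) raw$rsid else NA_character_,
    source_id = if ("source_id" %in% names(raw)) raw$source_id else NA_character_,
    significance = if ("significance" %in% names(raw)) raw$significance else NA_character_
  )
  key <- variant_key(x)
  if (anyDuplicated(key)) {
    warn(sprintf("catalogue %s: %d duplicate key(s), keeping first occurrence",
                 path, sum(duplicated(key))))
    x <- x[!duplicated(key), ]
  }
  class(x) <- c("ns_catalogue", class(x))
  x
}

#' Match variants against a catalogue
#'
#' Lookup is by the genomic key (chrom, pos, ref, alt); variants that miss on
#' the key but carry an rsID present in the catalogue match by rsID fallback.
#'
#' @param variants A variant tibble.
#' @param catalogue An `ns_catalogue` (or `NULL`, matching nothing).
#' @return Logical vector along the rows of `variants`.
#' @export
catalogue_match <- function(variants, catalogue) {
  if (is.null(catalogue) || nrow(catalogue) == 0 || nrow(variants) == 0) {
    return(rep(FALSE, nrow(variants)))
  }
  hit <- variant_key(variants) %in% variant_key(catalogue)
  rs <- catalogue$rsid[!is.na(catalogue$rsid)]
  hit | (!is.na(variants$rsid) & variants$rsid %in% rs)
}
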