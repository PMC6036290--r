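#' Translation consequence of an insertion in a coding sequence
#'
#' Given a coding sequence (CDS, starting at the ATG) and an insertion of one
#' or more bases after a 1-based cDNA position, translates the edited sequence
#' with the standard genetic code and reports whether the edit shifts the
#' reading frame, the first codon whose amino acid differs from the reference
#' translation, and the position of the first in-frame stop codon at or after
#' that point (a premature stop when it falls before the natural end).
#'
#' An insertion whose length is a multiple of three preserves the frame
#' (`is_frameshift = FALSE`); the altered-codon/stop fields are still reported
#' for such in-frame insertions, e.g. an inserted stop codon.
#'
#' A duplication is an insertion of the duplicated bases after their last
#' position: for the congenital nephrotic syndrome allele c.2673dupCA in
#' *NPHS1*, `frameshift_consequence(nphs1_cds, 2673, "CA")` reports the frame
#' shifting from amino-acid position 893 with a premature stop at 904 (the
#' reference CDS is user-supplied, e.g. from Ensembl).
#'
#' @param cds Character scalar of A/C/G/T starting with `ATG`, length >= 3.
#' @param position 1-based cDNA coordinate; the insertion lands immediately
#'   after this base.
#' @param inserted_bases Non-empty character scalar of A/C/G/T.
#' @return A list with `is_frameshift` (logical), `first_altered_codon` and
#'   `premature_stop_codon` (1-based amino-acid indices, `NA` when absent).
#' @examples
#' frameshift_consequence("ATGAAACCCTAA", 3, "TA")
#' frameshift_consequence("ATGAAACCCTAA", 3, "GGG")
#' @export
frameshift_consequence <- function(cds, position, inserted_bases) {
  cds <- toupper(as.character(cds))
  inserted_bases <- toupper(as.character(inserted_bases))
  if (!grepl("^[ACGT]+$", cds) || nchar(cds) < 3) {
    abort("`cds` must be an A/C/G/T string of length >= 3")
  }
  if (!grepl("^[ACGT]+$", inserted_bases)) {
    abort("`inserted_bases` must be a non-empty A/C/G/T string")
  }
  if (position < 1 || position > nchar(cds)) {
    abort("`position` must lie within the CDS")
  }

  edited <- paste0(substr(cds, 1, position), inserted_bases,
                   substr(cds, position + 1, nchar(cds)))
  ref_aa <- translate_codons(cds)
  alt_aa <- translate_codons(edited)

  n <- min(length(ref_aa), length(alt_aa))
  diff <- which(ref_aa[seq_len(n)] != alt_aa[seq_len(n)])
  first_altered <- if (length(diff)) diff[1] else NA_integer_

  stop_at <- NA_integer_
  if (!is.na(first_altered)) {
    stops <- which(alt_aa == "*")
    stops <- stops[stops >= first_altered]
    if (length(stops)) stop_at <- stops[1]
  }

  list(
    is_frameshift = (nchar(inserted_bases) %% 3L) != 0L,
    first_altered_codon = first_altered,
    premature_stop_codon = stop_at
  )
}

# translate complete codons of a nucleotide string (trailing partial codon
# dropped), returning a character vector of single-letter amino acids with
# "*" for stop
translate_codons <- function(seq) {
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L) return(character(0))
  dna <- Biostrings::DNAString(substr(seq, 1, 3L * n_codon))
  aa <- Biostrings::translate(dna, no.init.codon = TRUE)
  strsplit(as.character(aa), "")[[1]]
}
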