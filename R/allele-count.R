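#' Parse "AC/AN" allele-count cells
#'
#' Population databases report, per variant and population, the number of
#' alternate alleles observed (AC) and the total number of chromosomes
#' genotyped (AN).  Summary tables print these as `"380/256102"` style cells.
#' This parser accepts exactly that grammar: `<integer>/<integer>`.
#'
#' @param text Character vector of count cells.  `NA`, `""`, `"-"` and the
#'   typographic dash `"–"` are treated as "no data in this population"
#'   and yield `NA` counts (never zero).
#' @return A tibble with integer columns `ac` and `an`, one row per input.
#' @examples
#' parse_allele_count("380/256102")
#' parse_allele_count(c("0/30780", "17/5008", "-"))
#' @export
parse_allele_count <- function(text) {
  text <- as.character(text)
  missing <- is.na(text) | text %in% c("", "-", "–", "—")
  out <- tibble(ac = rep(NA_integer_, length(text)),
                an = rep(NA_integer_, length(text)))
  todo <- which(!missing)
  if (length(todo)) {
    ok <- grepl("^[0-9]+/[0-9]+$", text[todo])
    if (any(!ok)) {
      abort(sprintf("malformed allele-count cell(s): %s (expected \"<int>/<int>\")",
                    paste(unique(text[todo][!ok]), collapse = ", ")))
    }
    parts <- strsplit(text[todo], "/", fixed = TRUE)
    ac <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    an <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    bad <- ac > an | an <= 0
    if (any(bad)) {
      abort(sprintf("invalid allele count(s): %s (need 0 <= AC <= AN, AN > 0)",
                    paste(text[todo][bad], collapse = ", ")))
    }
    out$ac[todo] <- as.integer(ac)
    out$an[todo] <- as.integer(an)
  }
  out
}

#' Format allele counts back to "AC/AN" cells
#'
#' Inverse of [parse_allele_count()]; missing counts become `"-"`.
#'
#' @param ac,an Integer vectors of alternate allele counts and total allele
#'   numbers.
#' @return Character vector of `"<int>/<int>"` cells.
#' @export
format_allele_count <- function(ac, an) {
  ifelse(is.na(ac) | is.na(an), "-", paste0(ac, "/", an))
}

#' Minor allele frequency of an allele count
#'
#' `min(AC/AN, 1 - AC/AN)`: the frequency of the rarer allele, used by the
#' rarity filter (variants with MAF below 1 % qualify as rare).
#'
#' @param ac,an Integer vectors (`NA` propagates).
#' @return Numeric vector in `[0, 0.5]`.
#' @examples
#' compute_maf(205, 276570)
#' compute_maf(3, 192)
#' @export
compute_maf <- function(ac, an) {
  f <- ac / an
  pmin(f, 1 - f)
}
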