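# Core (non-population) columns of the variant-table dialect.  Everything
# else in the header is taken to be a population count column.
ns_core_cols <- c("gene", "chrom", "pos", "rsid", "ref", "alt",
                  "consequence", "category")
ns_score_cols <- c("sift", "pph2", "ma", "fathmm", "condel", "condel_label")

#' Infer a consequence category from an HGVS-style consequence string
#'
#' The variant tables annotate consequence as HGVS protein notation
#' (`p.Tyr255His`, `p.Glu188Ter`, `p.Ser95IlefsTer8`) or, for splice-site
#' substitutions, cDNA notation (`c.1405+1G>A`, `c.874-1G>A`).  This maps the
#' notation to the categories the curation rules operate on; it is string
#' classification of an annotation that is already an input, not consequence
#' calling from sequence.
#'
#' @param consequence Character vector of HGVS-style strings.
#' @return Character vector with values among `missense`, `stop_gained`,
#'   `frameshift`, `inframe_indel`, `splice_acceptor`, `splice_donor`,
#'   `synonymous`, `other`.
#' @examples
#' consequence_category(c("p.Arg575Ter", "c.1405+1G>A", "p.Lys126ArgfsTer9"))
#' @export
consequence_category <- function(consequence) {
  x <- as.character(consequence)
  out <- rep("other", length(x))
  prot <- grepl("^p\\.", x)
  out[prot] <- "missense"
  out[prot & grepl("(Ter|\\*)$", x) & !grepl("fs", x)] <- "stop_gained"
  out[prot & grepl("fs", x)] <- "frameshift"
  out[prot & grepl("(del|dup|ins)", x) & !grepl("fs", x)] <- "inframe_indel"
  out[prot & grepl("=$", x)] <- "synonymous"
  # p.Ser100Ser style: identical residue on both sides is also synonymous
  same <- prot & grepl("^p\\.([A-Z][a-z]{2})[0-9]+\\1$", x)
  out[same] <- "synonymous"
  # c.<pos>+<k> / c.<pos>-<k>: intronic side of a splice site
  out[grepl("^c\\.[0-9_]+\\+[0-9]+", x)] <- "splice_donor"
  out[grepl("^c\\.[0-9_]+-[0-9]+", x)] <- "splice_acceptor"
  out[is.na(x)] <- NA_character_
  out
}

ns_categories <- c("missense", "stop_gained", "frameshift", "inframe_indel",
                   "splice_acceptor", "splice_donor", "synonymous", "other")

#' Read a variant table with per-population allele counts
#'
#' Reads the TSV dialect used throughout this package: one row per coding
#' variant with columns `gene`, `chrom`, `pos`, `rsid`, `ref`, `alt`,
#' `consequence` (HGVS-style; an explicit `category` column overrides the
#' inferred category), one `"AC/AN"` column per population, and optional
#' in-silico score columns `sift`, `pph2`, `ma`, `fathmm`, `condel`,
#' `condel_label`.
#'
#' Dash or empty count cells mean "no data in this population", never zero.
#' Rows duplicated on the variant key (chrom, pos, ref, alt) are dropped with
#' a warning when their content is identical and rejected when it conflicts.
#'
#' @param path Path to a tab-separated file.
#' @param populations Names of the count columns.  `NULL` (default) treats
#'   every non-core, non-score column as a population.
#' @return A tibble (`nrow` = number of unique variants) with integer columns
#'   `ac_<TAG>` / `an_<TAG>` per population (NA = no data) plus the core and
#'   score columns.
#' @seealso [write_variant_table()], [read_vcf()]
#' @export
read_variant_table <- function(path, populations = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  names(raw) <- tolower_core(names(raw))
  mandatory <- c("gene", "chrom", "pos", "ref", "alt", "consequence")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    abort(sprintf("variant table %s is missing mandatory column(s): %s",
                  path, paste(miss, collapse = ", ")))
  }
  populations <- populations %||%
    setdiff(names(raw), c(ns_core_cols, ns_score_cols))
  if (!length(populations)) {
    abort(sprintf("variant table %s has no population count columns", path))
  }

  na_like <- function(x) dplyr::na_if(dplyr::na_if(dplyr::na_if(x, ""), "-"), "–")
  x <- tibble(
    gene  = raw$gene,
    chrom = raw$chrom,
    pos   = as.integer(raw$pos),
    rsid  = if ("rsid" %in% names(raw)) na_like(raw$rsid) else NA_character_,
    ref   = raw$ref,
    alt   = raw$alt,
    consequence = na_like(raw$consequence)
  )
  x$category <- if ("category" %in% names(raw)) {
    na_like(raw$category)
  } else {
    consequence_category(x$consequence)
  }
  for (s in ns_score_cols) {
    x[[s]] <- if (s %in% names(raw)) {
      if (s == "condel_label") na_like(raw[[s]]) else as.numeric(na_like(raw[[s]]))
    } else if (s == "condel_label") NA_character_ else NA_real_
  }
  for (p in populations) {
    ct <- parse_allele_count(raw[[p]])
    x[[paste0("ac_", p)]] <- ct$ac
    x[[paste0("an_", p)]] <- ct$an
  }

  if (nrow(x)) {
    if (any(x$pos < 1, na.rm = TRUE)) abort("positions must be 1-based (>= 1)")
    if (any(x$ref == x$alt, na.rm = TRUE)) {
      abort(sprintf("ref and alt allele identical for: %s",
                    paste(variant_key(x[x$ref == x$alt, ]), collapse = ", ")))
    }
    has_count <- rowSums(!is.na(as.matrix(x[paste0("ac_", populations)]))) > 0
    if (any(!has_count)) {
      abort(sprintf("variant(s) with no allele count in any population: %s",
                    paste(variant_key(x[!has_count, ]), collapse = ", ")))
    }
    key <- variant_key(x)
    if (anyDuplicated(key)) {
      dup <- duplicated(key)
      identical_dup <- duplicated(x)
      conflict <- dup & !identical_dup
      if (any(conflict)) {
        abort(sprintf("conflicting duplicate rows for variant key(s): %s",
                      paste(unique(key[conflict]), collapse = ", ")))
      }
      warn(sprintf("dropping %d duplicated variant row(s): %s",
                   sum(dup), paste(unique(key[dup]), collapse = ", ")))
      x <- x[!dup, ]
    }
  }
  x
}

# header normalization: core/score names are case-insensitive, population
# tags are preserved as written
tolower_core <- function(nm) {
  low <- tolower(nm)
  ifelse(low %in% c(ns_core_cols, ns_score_cols), low, nm)
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]: population counts are formatted as
#' `"AC/AN"` cells and missing data as `"-"`.  `read_variant_table()` on the
#' result reproduces every field exactly.
#'
#' @param x A variant tibble as returned by [read_variant_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  pops <- variant_populations(x)
  out <- x[intersect(c(ns_core_cols, ns_score_cols), names(x))]
  for (p in pops) {
    out[[p]] <- format_allele_count(x[[paste0("ac_", p)]], x[[paste0("an_", p)]])
  }
  # score columns: full precision, dash for NA
  for (s in ns_score_cols) {
    v <- out[[s]]
    fmt <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    out[[s]] <- ifelse(is.na(v), "-", fmt)
  }
  readr::write_tsv(out, path, na = "-", progress = FALSE)
  invisible(path)
}

#' Population tags present in a variant table
#'
#' @param x A variant tibble.
#' @return Character vector of tags (the `<TAG>` of the `ac_<TAG>` columns).
#' @export
variant_populations <- function(x) {
  sub("^ac_", "", grep("^ac_", names(x), value = TRUE))
}
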