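#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' ns_example()
#' ns_example("known_pathogenic_variants.tsv")
#' @export
ns_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "nephroprev")))
  }
  path <- system.file("extdata", file, package = "nephroprev")
  if (path == "") abort(sprintf("no packaged file named %s", file))
  path
}

#' Packaged variant tables and catalogue
#'
#' Convenience loaders for the transcribed gnomAD/1000 Genomes allele-count
#' tables: the 56 known pathogenic variants (HGMD/ClinVar-annotated), the 23
#' rare predicted-deleterious candidates, and the catalogue keyed on the known
#' set.
#'
#' @param which `"known"` or `"candidates"`.
#' @return A variant tibble, or for `ns_catalogue_fixture()` an `ns_catalogue`.
#' @export
ns_variants <- function(which = c("known", "candidates")) {
  which <- match.arg(which)
  file <- switch(which,
                 known = "known_pathogenic_variants.tsv",
                 candidates = "rare_predicted_deleterious_variants.tsv")
  read_variant_table(ns_example(file))
}

#' @rdname ns_variants
#' @export
ns_catalogue_fixture <- function() {
  read_catalogue(ns_example("pathogenic_catalogue.tsv"))
}

#' Published summary tables
#'
#' The published per-gene / per-population summary blocks that the
#' reproduction suite compares against, in tidy form.  Each cell carries a
#' check class: `exact` cells are asserted to reproduce bit-exactly from the
#' packaged variant tables; `denominator` cells have an exactly reproducing
#' pooled numerator but a printed effective allele number deviating (<= 1.1 %)
#' from the mean-AN convention; `deviation` cells are internally inconsistent
#' in the source and are reported without assertion.
#'
#' @param which `"known"` (known mutant alleles only) or
#'   `"known_plus_predicted"` (known plus rare predicted-deleterious).
#' @return A tibble: `gene`, `column`, printed `allele_count` / `freq_pct` /
#'   `prevalence` / `carrier`, and a `*_check` class per measure.
#' @export
published_summary <- function(which = c("known", "known_plus_predicted")) {
  which <- match.arg(which)
  file <- sprintf("published_summary_%s.tsv", which)
  readr::read_tsv(ns_example(file), col_types = readr::cols(.default = "c"),
                  na = character(), progress = FALSE)
}

#' Recompute the published summary tables from the packaged variant tables
#'
#' Runs the full pipeline on the packaged fixtures — curation, pooling,
#' dataset merging, gene combination, Hardy-Weinberg estimation with
#' paper-compatible rounding — and compares every computed cell with the
#' published value.
#'
#' The known-set table is built from the candidate variant table (whose
#' per-variant counts the published known-set summary sums); the
#' known-plus-predicted table concatenates both packaged tables, keeping the
#' one variant they share (1:179520493 A/G, annotated under two transcript
#' numberings) duplicated, as the published sums do.
#'
#' @param which Which summary to reproduce (see [published_summary()]).
#' @param rounding Rounding convention; reproduction requires the default.
#' @return A tibble with one row per cell: `gene`, `column`, `measure`,
#'   `published`, `computed`, `check` (the fixture's check class) and `match`.
#'   Attribute `report` holds the computed report.
#' @seealso [cmd_reproduce()] for the asserting wrapper.
#' @export
reproduce_published <- function(which = c("known", "known_plus_predicted"),
                                rounding = "paper_compat") {
  which <- match.arg(which)
  variants <- if (which == "known") {
    ns_variants("candidates")
  } else {
    suppressWarnings(bind_rows(ns_variants("known"), ns_variants("candidates")))
  }
  report <- build_report(variants, genes = c("NPHS2", "LAMB2", "NPHS1"),
                         rounding = rounding)
  report$gene[!report$gene %in% c("NPHS2", "LAMB2", "NPHS1")] <- "COMBINED"

  fmt_or_dash <- function(x, f) ifelse(is.na(x), "-", f(x))
  computed <- tibble(
    gene = report$gene, column = report$column,
    allele_count = format_allele_count(report$ac, report$an),
    freq_pct = fmt_or_dash(report$q_used, function(q) sprintf("%.3f", q * 100)),
    prevalence = fmt_or_dash(report$prevalence, function(n) sprintf("%.0f", n)),
    carrier = fmt_or_dash(report$carrier, function(n) sprintf("%.0f", n))
  )
  pub <- published_summary(which)

  measures <- c("allele_count", "freq_pct", "prevalence", "carrier")
  check_col <- c(allele_count = "ac_check", freq_pct = "freq_check",
                 prevalence = "prev_check", carrier = "carrier_check")
  out <- list()
  for (m in measures) {
    cmp <- left_join(
      pub[c("gene", "column", m, check_col[[m]])],
      computed[c("gene", "column", m)],
      by = c("gene", "column"), suffix = c("_pub", "_comp")
    )
    published_v <- cmp[[paste0(m, "_pub")]]
    computed_v <- cmp[[paste0(m, "_comp")]]
    out[[m]] <- tibble(
      gene = cmp$gene, column = cmp$column, measure = m,
      published = published_v, computed = computed_v,
      check = cmp[[check_col[[m]]]],
      match = cell_match(m, published_v, computed_v)
    )
  }
  out <- bind_rows(out)
  attr(out, "report") <- report
  out
}

# a frequency cell matches when numerically equal (the source prints "0.18"
# for 0.180); counts and 1-in-N cells match on the exact string/integer
cell_match <- function(measure, published, computed) {
  if (measure == "freq_pct") {
    p <- suppressWarnings(as.numeric(published))
    s <- suppressWarnings(as.numeric(computed))
    (is.na(p) & is.na(s)) | (!is.na(p) & !is.na(s) & abs(p - s) < 1e-9)
  } else {
    published == computed
  }
}

#' Headline prevalence and carrier-frequency figures
#'
#' The headline worldwide and South-Asian figures derive from the published
#' combined three-gene frequencies of the known-plus-predicted set (0.23 % and
#' 0.420 %), whose derivation from the printed per-gene counts is ambiguous in
#' the source (see [published_summary()]); this helper therefore applies the
#' Hardy-Weinberg formulas to those printed frequencies.
#'
#' @return A tibble with `population`, `q_pct`, `prevalence`, `carrier`:
#'   1 in 189036 / 1 in 218 worldwide and 1 in 56689 / 1 in 120 South-Asian.
#' @export
headline_estimates <- function() {
  pub <- published_summary("known_plus_predicted")
  rows <- pub$gene == "COMBINED" &
    pub$column %in% c("gnomAD+1KG", "gnomAD-SAS+1KG-PJL")
  q_pct <- as.numeric(pub$freq_pct[rows])
  q <- q_pct / 100
  tibble(
    population = c("worldwide", "south_asian"),
    q_pct = q_pct,
    prevalence = round_half_up(hwe_prevalence(q)),
    carrier = round_half_up(hwe_carrier(q))
  )
}
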