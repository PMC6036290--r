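#' Build a per-gene / per-population prevalence report
#'
#' Runs the full estimation over a curated variant table: per gene and report
#' column it pools alleles ([aggregate_gene()]), merges datasets where a
#' column spans several population tags ([merge_datasets()]), adds the
#' combined row over all genes ([combine_genes()]), and applies the
#' Hardy-Weinberg formulas ([hw_estimate()]).
#'
#' A report column is one or more population tags: single tags give the
#' per-dataset columns, multi-tag columns (e.g. gnomAD all + 1KG all) are
#' merged pools.  When a gene has no observed variant in a population listed
#' in `default_an`, the pool for that population is taken as 0 out of the
#' database's full chromosome count — absence from a complete callset is an
#' observation of zero alternate alleles, not missing data.  Populations
#' without a default yield undefined cells.
#'
#' @param variants A curated variant tibble (e.g. the `known` part of
#'   [curate_set()], or the concatenation of known and candidate sets).
#' @param genes Genes to report, in row order; default: order of appearance.
#' @param columns Named list mapping column labels to character vectors of
#'   population tags; default: the six standard gnomAD/1KG columns.
#' @param default_an Named vector of fallback allele numbers per population
#'   tag (default: 1000 Genomes all = 5008, PJL = 192).
#' @param rounding Passed to [hw_estimate()].
#' @param combine `"pooled_counts"` (default) or `"sum_homozygote"`, the
#'   convention for the combined-genes row ([combine_genes()]).
#' @return A tibble with one row per gene x column (plus a combined pseudo-gene
#'   row per column) and the [hw_estimate()] columns, with attribute
#'   `rounding`.
#' @examples
#' v <- read_variant_table(ns_example("rare_predicted_deleterious_variants.tsv"))
#' rep <- build_report(v, genes = c("NPHS2", "LAMB2", "NPHS1"))
#' subset(rep, column == "gnomAD+1KG")
#' @export
build_report <- function(variants,
                         genes = unique(variants$gene),
                         columns = ns_default_columns,
                         default_an = ns_default_an,
                         rounding = c("paper_compat", "raw"),
                         combine = c("pooled_counts", "sum_homozygote")) {
  rounding <- match.arg(rounding)
  combine <- match.arg(combine)
  if (nrow(variants) == 0) abort("cannot build a report from an empty variant set")

  one_pool <- function(gene, tag) {
    s <- aggregate_gene(variants, gene, tag)
    if (is.na(s$ac) && tag %in% names(default_an)) {
      s$ac <- 0L
      s$an <- as.integer(default_an[[tag]])
    }
    s
  }
  rows <- list()
  for (cn in names(columns)) {
    per_gene <- lapply(genes, function(g) {
      Reduce(merge_datasets, lapply(columns[[cn]], function(tag) one_pool(g, tag)))
    })
    defined <- !vapply(per_gene, function(s) is.na(s$ac), logical(1))
    col_rows <- lapply(per_gene, hw_estimate, rounding = rounding)
    if (any(defined)) {
      comb <- combine_genes(bind_rows(per_gene[defined]), mode = combine,
                            rounding = rounding)
      comb_row <- if (combine == "pooled_counts") {
        hw_estimate(comb, rounding = rounding)
      } else {
        comb
      }
      comb_row$gene <- paste(genes, collapse = "+")
      col_rows <- c(col_rows, list(comb_row))
    }
    col_rows <- bind_rows(col_rows)
    col_rows$column <- cn
    rows[[cn]] <- col_rows
  }
  out <- bind_rows(rows)
  out <- out[c("column", setdiff(names(out), "column"))]
  attr(out, "rounding") <- rounding
  out
}

#' Write a report as a gene-block summary table
#'
#' Emits the layout of the published summary tables: one block of four rows
#' per gene (and one for the combined genes) labelled `Allele Count`,
#' `Mutant Allele Feq (%)`, `Prevalence (1 in)` and `Carrier Frq (1 in)`,
#' with one column per report column.  Undefined prevalence/carrier cells are
#' written as `"-"`.  [read_summary()] on the result reproduces the values
#' bit-exactly.
#'
#' @param report A report tibble from [build_report()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(report, path) {
  rounding <- attr(report, "rounding") %||% "paper_compat"
  fmt_q <- function(q) {
    ifelse(is.na(q), "-",
           if (rounding == "paper_compat") sprintf("%.3f", q * 100)
           else sprintf("%.17g", q * 100))
  }
  fmt_n <- function(n) ifelse(is.na(n), "-", sprintf("%.0f", n))
  genes <- unique(report$gene)
  cols <- unique(report$column)
  lines <- c(paste(c("gene", "measure", cols), collapse = "\t"))
  for (g in genes) {
    block <- report[report$gene == g, ]
    block <- block[match(cols, block$column), ]
    lines <- c(
      lines,
      paste(c(g, "Allele Count", format_allele_count(block$ac, block$an)),
            collapse = "\t"),
      paste(c(g, "Mutant Allele Feq (%)", fmt_q(block$q_used)), collapse = "\t"),
      paste(c(g, "Prevalence (1 in)", fmt_n(block$prevalence)), collapse = "\t"),
      paste(c(g, "Carrier Frq (1 in)", fmt_n(block$carrier)), collapse = "\t")
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a gene-block summary table
#'
#' @param path A TSV written by [write_summary()].
#' @return A tidy tibble with columns `gene`, `column`, `ac`, `an`, `q_used`,
#'   `prevalence`, `carrier` (`NA` for `"-"` cells).
#' @export
read_summary <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  cols <- setdiff(names(raw), c("gene", "measure"))
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "-", NA, x)))
  out <- list()
  for (g in unique(raw$gene)) {
    block <- raw[raw$gene == g, ]
    grab <- function(measure) {
      unlist(block[block$measure == measure, cols], use.names = FALSE)
    }
    ct <- parse_allele_count(grab("Allele Count"))
    out[[g]] <- tibble(
      gene = g, column = cols,
      ac = ct$ac, an = ct$an,
      q_used = num(grab("Mutant Allele Feq (%)")) / 100,
      prevalence = num(grab("Prevalence (1 in)")),
      carrier = num(grab("Carrier Frq (1 in)"))
    )
  }
  bind_rows(out)
}
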