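#' Pool the mutant alleles of one gene in one population
#'
#' Pooling follows the sum-AC / mean-AN convention: the pooled alternate
#' count is the exact sum of the per-variant alternate counts (zero-count
#' variants included), and the effective allele number is the arithmetic mean
#' of the contributing variants' AN, rounded half-up to an integer.  Variants
#' with no data in the population do not contribute; a gene with no data at
#' all yields an undefined summary (`NA` counts), which is distinct from an
#' observed frequency of zero.
#'
#' @param variants A variant tibble.
#' @param gene Gene symbol to pool.
#' @param population Population tag (an `ac_<TAG>` column must exist).
#' @param dataset Dataset tag recorded on the summary; defaults to the part of
#'   the population tag before the first underscore (`GNOMAD_SAS` ->
#'   `GNOMAD`).
#' @return A one-row tibble: `gene`, `population`, `dataset`, `ac`, `an`,
#'   `n_variants`.
#' @examples
#' v <- read_variant_table(ns_example("rare_predicted_deleterious_variants.tsv"))
#' aggregate_gene(v, "NPHS2", "GNOMAD_ALL")  # 380/256102 from 9 variants
#' @export
aggregate_gene <- function(variants, gene, population,
                           dataset = sub("_.*$", "", population)) {
  ac_col <- paste0("ac_", population)
  an_col <- paste0("an_", population)
  if (!ac_col %in% names(variants)) {
    abort(sprintf("population %s not present in variant table", population))
  }
  rows <- variants$gene == gene & !is.na(variants[[ac_col]])
  if (!any(rows)) {
    return(tibble(gene = gene, population = population, dataset = dataset,
                  ac = NA_integer_, an = NA_integer_, n_variants = 0L))
  }
  tibble(
    gene = gene, population = population, dataset = dataset,
    ac = sum(variants[[ac_col]][rows]),
    an = as.integer(round_half_up(mean(variants[[an_col]][rows]))),
    n_variants = sum(rows)
  )
}

#' Merge per-gene summaries across datasets
#'
#' Merging the same gene across disjoint datasets (e.g. gnomAD exomes with
#' 1000 Genomes) sums both the alternate counts and the allele numbers —
#' the merged pool simply has more chromosomes.
#'
#' @param a,b One-row gene summaries ([aggregate_gene()]) for the same gene
#'   from different datasets.
#' @return A merged one-row summary with dataset tag `MERGED` and a combined
#'   population label.
#' @examples
#' \dontrun{merge_datasets(s_gnomad, s_kg)  # 380/256102 + 20/5008 = 400/261110}
#' @export
merge_datasets <- function(a, b) {
  if (!identical(a$gene, b$gene)) {
    abort(sprintf("cannot merge summaries of different genes (%s vs %s)",
                  a$gene, b$gene))
  }
  if (is.na(a$ac)) return(mutate(b, dataset = "MERGED"))
  if (is.na(b$ac)) return(mutate(a, dataset = "MERGED"))
  tibble(
    gene = a$gene,
    population = paste(a$population, b$population, sep = "+"),
    dataset = "MERGED",
    ac = a$ac + b$ac,
    an = a$an + b$an,
    n_variants = a$n_variants + b$n_variants
  )
}

#' Combine several genes into a single recessive-disease pool
#'
#' Two conventions are provided for turning per-gene mutant-allele
#' frequencies into a combined estimate over a gene panel:
#'
#' * `pooled_counts` (default): sum the per-gene alternate counts and take the
#'   mean of the per-gene effective allele numbers (rounded half-up), then
#'   estimate as usual.  This is the convention that reproduces the published
#'   combined rows.
#' * `sum_homozygote`: add the per-gene homozygote frequencies, i.e. combined
#'   prevalence = 1 / sum(q_i^2), with the carrier frequency derived from the
#'   effective frequency q_eff = sqrt(sum(q_i^2)).  This treats the genes as
#'   independent recessive loci any one of which can cause disease.
#'
#' @param summaries A tibble of defined one-row gene summaries, same
#'   population.
#' @param mode `"pooled_counts"` or `"sum_homozygote"`.
#' @param rounding Passed to [hw_estimate()].
#' @return For `pooled_counts`, a one-row summary (gene = the joined symbol
#'   list) ready for [hw_estimate()]; for `sum_homozygote`, the estimate
#'   tibble itself.
#' @export
combine_genes <- function(summaries, mode = c("pooled_counts", "sum_homozygote"),
                          rounding = c("paper_compat", "raw")) {
  mode <- match.arg(mode)
  rounding <- match.arg(rounding)
  if (nrow(summaries) < 1) abort("need at least one gene summary")
  if (length(unique(summaries$population)) != 1) {
    abort("cannot combine gene summaries across different populations")
  }
  if (any(is.na(summaries$ac))) abort("cannot combine undefined summaries")
  if (mode == "pooled_counts") {
    return(tibble(
      gene = paste(summaries$gene, collapse = "+"),
      population = summaries$population[1],
      dataset = if (length(unique(summaries$dataset)) == 1) summaries$dataset[1] else "MERGED",
      ac = sum(summaries$ac),
      an = as.integer(round_half_up(mean(summaries$an))),
      n_variants = sum(summaries$n_variants)
    ))
  }
  # sum_homozygote: prevalence from the summed q_i^2
  q <- vapply(seq_len(nrow(summaries)), function(i) {
    used_q(summaries$ac[i], summaries$an[i], rounding)
  }, numeric(1))
  hom <- sum(q^2)
  q_eff <- sqrt(hom)
  est <- estimate_from_q(q_eff, q_raw = sum(summaries$ac) / mean(summaries$an))
  est$gene <- paste(summaries$gene, collapse = "+")
  est$population <- summaries$population[1]
  est
}

#' Hardy-Weinberg prevalence of a fully penetrant recessive condition
#'
#' For mutant allele frequency `q`, affected (biallelic) individuals occur at
#' frequency `q^2`; the expected "1 in N" prevalence denominator is `1/q^2`.
#'
#' @param q Mutant allele frequency in `(0, 1]`.
#' @return `1/q^2`; `NA` for `q <= 0` (prevalence undefined, not zero).
#' @examples
#' hwe_prevalence(0.0023)  # ~ 1 in 189036
#' @export
hwe_prevalence <- function(q) {
  ifelse(is.na(q) | q <= 0, NA_real_, 1 / q^2)
}

#' Hardy-Weinberg carrier frequency
#'
#' Heterozygous carriers occur at frequency `2pq` with `p = 1 - q`; the
#' "1 in N" carrier denominator is `1/(2pq)`.
#'
#' @param q Mutant allele frequency strictly inside `(0, 1)`.
#' @return `1/(2*(1-q)*q)`; `NA` at `q = 0` or `q = 1`.
#' @examples
#' hwe_carrier(0.0042)  # ~ 1 in 120
#' @export
hwe_carrier <- function(q) {
  ifelse(is.na(q) | q <= 0 | q >= 1, NA_real_, 1 / (2 * (1 - q) * q))
}

# frequency actually fed into the HWE formulas under a rounding convention;
# paper_compat truncates the percentage at 3 decimals (computed on the
# integer grid m/1e5 so printed frequencies reproduce bit-exactly)
used_q <- function(ac, an, rounding) {
  q_raw <- ac / an
  if (rounding == "raw") q_raw else floor(q_raw * 1e5) / 1e5
}

estimate_from_q <- function(q_used, q_raw) {
  prevalence_raw <- hwe_prevalence(q_used)
  carrier_raw <- hwe_carrier(q_used)
  tibble(
    q_raw = q_raw,
    q_used = q_used,
    p = 1 - q_used,
    prevalence_raw = prevalence_raw,
    carrier_raw = carrier_raw,
    prevalence = ifelse(is.na(prevalence_raw), NA_real_, round_half_up(prevalence_raw)),
    carrier = ifelse(is.na(carrier_raw), NA_real_, round_half_up(carrier_raw))
  )
}

#' Hardy-Weinberg estimate from a pooled gene summary
#'
#' Converts a pooled allele count into the mutant allele frequency `q`, its
#' complement `p`, and "1 in N" prevalence (`1/q^2`) and carrier frequency
#' (`1/(2pq)`) figures with half-up integer rounding.
#'
#' Under `rounding = "paper_compat"` the frequency is first truncated at
#' three decimal places of its percentage value (the convention the published
#' summary tables follow); `"raw"` feeds the unrounded frequency into the
#' formulas and is the scientifically preferable default for new analyses.
#'
#' A summary with `q = 0` yields undefined (`NA`) prevalence and carrier
#' values: no mutant allele was observed, which bounds, but does not
#' estimate, the frequency.
#'
#' @param summary One-row gene summary ([aggregate_gene()], [merge_datasets()]
#'   or [combine_genes()] output).
#' @param rounding `"paper_compat"` (default) or `"raw"`.
#' @return A one-row tibble: `gene`, `population`, `ac`, `an`, `q_raw`,
#'   `q_used`, `p`, `prevalence_raw`, `carrier_raw`, `prevalence`, `carrier`.
#' @examples
#' s <- tibble::tibble(gene = "NPHS2", population = "GNOMAD_ALL",
#'                     dataset = "GNOMAD", ac = 380L, an = 256102L,
#'                     n_variants = 9L)
#' hw_estimate(s)  # q = 0.148 %, prevalence 1 in 456538, carrier 1 in 338
#' @export
hw_estimate <- function(summary, rounding = c("paper_compat", "raw")) {
  rounding <- match.arg(rounding)
  if (is.na(summary$ac)) {
    est <- tibble(q_raw = NA_real_, q_used = NA_real_, p = NA_real_,
                  prevalence_raw = NA_real_, carrier_raw = NA_real_,
                  prevalence = NA_real_, carrier = NA_real_)
  } else {
    est <- estimate_from_q(used_q(summary$ac, summary$an, rounding),
                           q_raw = summary$ac / summary$an)
    # algebraic self-checks: 1/q^2 and 1/2pq identities hold pre-rounding
    with(est, {
      if (!is.na(prevalence_raw)) {
        stopifnot(abs(prevalence_raw * q_used^2 - 1) < 1e-9,
                  abs(carrier_raw * 2 * p * q_used - 1) < 1e-9,
                  abs(prevalence_raw - 4 * p^2 * carrier_raw^2) <
                    1e-9 * prevalence_raw)
      }
    })
  }
  dplyr::bind_cols(
    summary[intersect(c("gene", "population", "dataset", "ac", "an", "n_variants"),
                      names(summary))],
    est
  )
}
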