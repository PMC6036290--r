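#' Pipeline run configuration
#'
#' Builds and validates the configuration consumed by the `cmd_*` commands.
#' Accepts a JSON config file and/or individual overrides; unknown keys are
#' rejected.
#'
#' @param config_file Optional path to a JSON file of the same keys.
#' @param variants,catalogue Input paths (variant table TSV or VCF; catalogue
#'   TSV).
#' @param out_dir Output directory.
#' @param maf_threshold,maf_reference_population,condel_threshold Curation
#'   thresholds (see [classify_variants()]).
#' @param rounding `"paper_compat"` or `"raw"`.
#' @param combine `"pooled_counts"` or `"sum_homozygote"`.
#' @param seed Integer seed ([cmd_simulate()] requires it).
#' @return A validated list of class `ns_run_config`.
#' @export
run_config <- function(config_file = NULL, variants = NULL, catalogue = NULL,
                       out_dir = NULL, maf_threshold = NULL,
                       maf_reference_population = NULL,
                       condel_threshold = NULL,
                       rounding = NULL, combine = NULL,
                       seed = NULL) {
  defaults <- list(variants = NULL, catalogue = NULL, out_dir = ".",
                   maf_threshold = 0.01,
                   maf_reference_population = "GNOMAD_ALL",
                   condel_threshold = 0.5, rounding = "paper_compat",
                   combine = "pooled_counts", seed = NULL)
  explicit <- list(variants = variants, catalogue = catalogue,
                   out_dir = out_dir, maf_threshold = maf_threshold,
                   maf_reference_population = maf_reference_population,
                   condel_threshold = condel_threshold, rounding = rounding,
                   combine = combine, seed = seed)
  explicit <- explicit[!vapply(explicit, is.null, logical(1))]
  cfg <- defaults
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      abort(sprintf("config file not found: %s", config_file))
    }
    file_cfg <- jsonlite::read_json(config_file, simplifyVector = TRUE)
    unknown <- setdiff(names(file_cfg), names(defaults))
    if (length(unknown)) {
      abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    }
    cfg <- modifyList(cfg, file_cfg, keep.null = TRUE)
  }
  cfg <- modifyList(cfg, explicit, keep.null = TRUE)  # flags beat the file
  for (key in c("variants", "catalogue")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      abort(sprintf("%s path does not exist: %s", key, cfg[[key]]))
    }
  }
  stopifnot(cfg$maf_threshold > 0, cfg$maf_threshold < 0.5,
            cfg$rounding %in% c("paper_compat", "raw"),
            cfg$combine %in% c("pooled_counts", "sum_homozygote"))
  structure(cfg, class = "ns_run_config")
}

read_any_variants <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##fileformat=VCF")) read_vcf(path) else read_variant_table(path)
}

#' Curate a variant file into class-wise TSVs
#'
#' Reads the configured variant table (TSV or VCF) and catalogue, partitions
#' the variants with [curate_set()], writes `known.tsv`, `candidates.tsv` and
#' `excluded.tsv` into `out_dir` and logs per-gene tallies to stderr.
#'
#' @param config An [run_config()] object.
#' @return The `ns_curation` object, invisibly.
#' @export
cmd_curate <- function(config) {
  stopifnot(inherits(config, "ns_run_config"))
  if (is.null(config$variants)) abort("config lacks a `variants` path")
  variants <- read_any_variants(config$variants)
  catalogue <- if (!is.null(config$catalogue)) read_catalogue(config$catalogue)
  cur <- curate_set(variants, catalogue,
                    maf_reference_population = config$maf_reference_population,
                    maf_threshold = config$maf_threshold,
                    condel_threshold = config$condel_threshold)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(cur$known, file.path(config$out_dir, "known.tsv"))
  write_variant_table(cur$candidates, file.path(config$out_dir, "candidates.tsv"))
  excl <- cur$excluded
  write_variant_table(excl[names(excl) != "reason"],
                      file.path(config$out_dir, "excluded.tsv"))
  readr::write_tsv(cur$tally, file.path(config$out_dir, "tally.tsv"),
                   progress = FALSE)
  message(sprintf("curated %d variants: %d known, %d candidates, %d excluded",
                  nrow(variants), nrow(cur$known), nrow(cur$candidates),
                  nrow(excl)))
  invisible(cur)
}

#' Estimate prevalence and write summary tables
#'
#' Curates the configured inputs, then writes two summary TSVs into
#' `out_dir`: `summary_known.tsv` (known pathogenic set only) and, when any
#' candidate passes curation, `summary_known_plus_predicted.tsv` (known plus
#' rare predicted-deleterious).
#'
#' @param config An [run_config()] object.
#' @return A list of the two report tibbles, invisibly.
#' @export
cmd_estimate <- function(config) {
  stopifnot(inherits(config, "ns_run_config"))
  if (is.null(config$variants)) abort("config lacks a `variants` path")
  variants <- read_any_variants(config$variants)
  catalogue <- if (!is.null(config$catalogue)) read_catalogue(config$catalogue)
  cur <- curate_set(variants, catalogue,
                    maf_reference_population = config$maf_reference_population,
                    maf_threshold = config$maf_threshold,
                    condel_threshold = config$condel_threshold)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- list()
  if (nrow(cur$known)) {
    reports$known <- build_report(cur$known, rounding = config$rounding,
                                  combine = config$combine)
    write_summary(reports$known, file.path(config$out_dir, "summary_known.tsv"))
  }
  kept <- bind_rows(cur$known, cur$candidates)
  if (nrow(kept)) {
    reports$known_plus_predicted <-
      build_report(kept, rounding = config$rounding, combine = config$combine)
    write_summary(reports$known_plus_predicted,
                  file.path(config$out_dir, "summary_known_plus_predicted.tsv"))
  } else {
    message("no variant passed curation; nothing to estimate")
  }
  invisible(reports)
}

#' Reproduce the published summary tables from the packaged fixtures
#'
#' Runs [reproduce_published()] for both variant sets, prints a comparison of
#' every computed versus published cell with its check class, reports the
#' headline figures ([headline_estimates()]), and errors if any cell of check
#' class `exact` fails to match — `denominator` and `deviation` cells are
#' flagged, not asserted (see [published_summary()]).
#'
#' @param quiet Suppress the per-cell listing.
#' @return A list of the two comparison tibbles, invisibly.
#' @export
cmd_reproduce <- function(quiet = FALSE) {
  out <- list()
  for (which in c("known", "known_plus_predicted")) {
    cmp <- reproduce_published(which)
    out[[which]] <- cmp
    bad <- cmp$check == "exact" & !cmp$match
    if (!quiet) {
      n_exact <- sum(cmp$check == "exact")
      message(sprintf("%s summary: %d/%d exact cells reproduce; %d documented-deviation cells",
                      which, sum(cmp$match & cmp$check == "exact"), n_exact,
                      sum(cmp$check != "exact")))
      flagged <- cmp[!cmp$match, ]
      if (nrow(flagged)) {
        message(paste(sprintf("  [%s] %s %s %s: published %s, computed %s",
                              flagged$check, flagged$gene, flagged$column,
                              flagged$measure, flagged$published,
                              flagged$computed), collapse = "\n"))
      }
    }
    if (any(bad)) {
      abort(sprintf("exact reproduction failed for %d cell(s) of the %s summary",
                    sum(bad), which))
    }
  }
  hl <- headline_estimates()
  if (!quiet) {
    message(sprintf("headline: 1 in %d prevalence / 1 in %d carriers (%s)",
                    hl$prevalence, hl$carrier, hl$population))
  }
  invisible(out)
}

#' Simulate a dataset from a config
#'
#' Thin wrapper over [simulate_dataset()] writing into the configured output
#' directory; refuses to run without a seed.
#'
#' @param config An [run_config()] with a non-`NULL` `seed`.
#' @param ... Passed to [sim_config()] (genes, populations, decoys).
#' @return The [simulate_dataset()] result, invisibly.
#' @export
cmd_simulate <- function(config, ...) {
  stopifnot(inherits(config, "ns_run_config"))
  if (is.null(config$seed)) abort("simulation requires a seed")
  sim <- simulate_dataset(sim_config(seed = config$seed, ...),
                          dir = config$out_dir)
  message(sprintf("simulated %d variants into %s", nrow(sim$truth), sim$dir))
  invisible(sim)
}
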