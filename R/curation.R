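# Consequence categories that qualify a variant for the rare-candidate
# filter: non-synonymous coding changes, indels and essential splice sites.
ns_qualifying <- c("missense", "stop_gained", "frameshift", "inframe_indel",
                   "splice_acceptor", "splice_donor")

# Truncating categories bypass the score consensus entirely: nonsense,
# frameshift and essential-splice alleles carry no in-silico scores in the
# source tables yet count as deleterious.
ns_truncating <- c("stop_gained", "frameshift", "splice_acceptor", "splice_donor")

# Conventional per-tool damaging cutoffs for the fallback vote, used only
# when no Condel score is available for a missense variant.
ns_default_cutoffs <- c(sift = 0.05, pph2 = 0.85, ma = 1.9, fathmm = -1.5)

#' Does a consequence category qualify for the rare-variant filter?
#'
#' @param category Character vector of consequence categories.
#' @return Logical vector; unknown categories give `FALSE` with a warning.
#' @export
qualifying_consequence <- function(category) {
  unknown <- !is.na(category) & !category %in% ns_categories
  if (any(unknown)) {
    warn(sprintf("unknown consequence categor%s: %s (treated as non-qualifying)",
                 if (sum(unknown) > 1) "ies" else "y",
                 paste(unique(category[unknown]), collapse = ", ")))
  }
  !is.na(category) & category %in% ns_qualifying
}

#' Consensus deleteriousness call
#'
#' Truncating variants (stop gained, frameshift, essential splice) are
#' deleterious regardless of scores.  Otherwise the Condel consensus score
#' decides (`>= threshold` is deleterious).  When Condel is absent the call
#' falls back to a majority vote over the available single-tool predictions
#' (SIFT < 0.05, PolyPhen-2 >= 0.85, MutationAssessor >= 1.9,
#' FATHMM <= -1.5): at least two damaging calls give `deleterious`, at least
#' two tolerated calls give `benign`, anything else is `uncertain`.
#'
#' @param category Consequence category vector.
#' @param sift,pph2,ma,fathmm,condel Numeric score vectors (NA = not scored).
#' @param condel_threshold Condel deleterious threshold, default 0.5 (every
#'   published Condel value labelled `D` in the packaged tables is >= 0.52).
#' @param cutoffs Named numeric vector of fallback-vote cutoffs.
#' @return Character vector: `"deleterious"`, `"benign"` or `"uncertain"`.
#' @export
consensus_deleterious <- function(category, sift = NA_real_, pph2 = NA_real_,
                                  ma = NA_real_, fathmm = NA_real_,
                                  condel = NA_real_, condel_threshold = 0.5,
                                  cutoffs = ns_default_cutoffs) {
  stopifnot(condel_threshold > 0, condel_threshold < 1)
  n <- length(category)
  r <- function(v) rep_len(v, n)
  sift <- r(sift); pph2 <- r(pph2); ma <- r(ma)
  fathmm <- r(fathmm); condel <- r(condel)

  damaging <- cbind(sift < cutoffs[["sift"]], pph2 >= cutoffs[["pph2"]],
                    ma >= cutoffs[["ma"]], fathmm <= cutoffs[["fathmm"]])
  n_dam <- rowSums(damaging, na.rm = TRUE)
  n_tol <- rowSums(!damaging, na.rm = TRUE)
  vote <- ifelse(n_dam >= 2, "deleterious",
                 ifelse(n_tol >= 2, "benign", "uncertain"))

  out <- ifelse(!is.na(condel),
                ifelse(condel >= condel_threshold, "deleterious", "benign"),
                vote)
  out[category %in% ns_truncating] <- "deleterious"
  out
}

#' Classify variants into curation classes
#'
#' Applies the selection rules in order of priority:
#' \enumerate{
#'   \item catalogue membership (genomic key, rsID fallback) makes a variant
#'     `known_pathogenic` regardless of frequency — the known set is defined
#'     by HGMD/ClinVar listing, and the frequency filter applies only to the
#'     remaining variants;
#'   \item MAF at or above `maf_threshold` (strictly-below passes) excludes as
#'     `common_allele`; the MAF is taken in `maf_reference_population`, or, if
#'     that population has no data, as the maximum MAF over the populations
#'     that do;
#'   \item non-qualifying consequences (synonymous, other) are excluded;
#'   \item the deleteriousness consensus keeps (`predicted_deleterious`) or
#'     excludes (`benign_prediction` / `insufficient_scores`) the rest.
#' }
#'
#' @param variants A variant tibble ([read_variant_table()] layout).
#' @param catalogue An `ns_catalogue` or `NULL`.
#' @param maf_reference_population Population tag whose frequency the rarity
#'   filter uses; default `"GNOMAD_ALL"`.
#' @param maf_threshold Strict MAF cutoff, default 0.01.
#' @param condel_threshold,cutoffs Passed to [consensus_deleterious()].
#' @return `variants` with columns `label` (`known_pathogenic`,
#'   `predicted_deleterious`, `excluded`) and `reason` (`NA` unless excluded:
#'   `common_allele`, `non_qualifying_consequence`, `benign_prediction`,
#'   `insufficient_scores`).
#' @export
classify_variants <- function(variants, catalogue = NULL,
                              maf_reference_population = "GNOMAD_ALL",
                              maf_threshold = 0.01,
                              condel_threshold = 0.5,
                              cutoffs = ns_default_cutoffs) {
  x <- variants
  if (nrow(x) == 0) {
    x$label <- character(0); x$reason <- character(0)
    return(x)
  }
  pops <- variant_populations(x)
  if (!length(pops)) abort("variant table has no population counts")

  maf_by_pop <- vapply(pops, function(p) {
    compute_maf(x[[paste0("ac_", p)]], x[[paste0("an_", p)]])
  }, numeric(nrow(x)))
  maf_by_pop <- matrix(maf_by_pop, nrow = nrow(x),
                       dimnames = list(NULL, pops))
  no_data <- rowSums(!is.na(maf_by_pop)) == 0
  if (any(no_data)) {
    abort(sprintf("variant(s) with no allele count in any population: %s",
                  paste(variant_key(x[no_data, ]), collapse = ", ")))
  }
  max_maf <- apply(maf_by_pop, 1, max, na.rm = TRUE)
  maf <- if (maf_reference_population %in% pops) {
    ref <- maf_by_pop[, maf_reference_population]
    ifelse(is.na(ref), max_maf, ref)
  } else {
    max_maf
  }

  known <- catalogue_match(x, catalogue)
  verdict <- consensus_deleterious(x$category, x$sift, x$pph2, x$ma, x$fathmm,
                                   x$condel, condel_threshold, cutoffs)
  qualifies <- qualifying_consequence(x$category)

  label <- rep("excluded", nrow(x))
  reason <- rep(NA_character_, nrow(x))
  rare <- maf < maf_threshold
  reason[!rare] <- "common_allele"
  reason[rare & !qualifies] <- "non_qualifying_consequence"
  keepable <- rare & qualifies
  reason[keepable & verdict == "benign"] <- "benign_prediction"
  reason[keepable & verdict == "uncertain"] <- "insufficient_scores"
  label[keepable & verdict == "deleterious"] <- "predicted_deleterious"
  label[known] <- "known_pathogenic"
  reason[label != "excluded"] <- NA_character_

  x$label <- label
  x$reason <- reason
  x
}

#' Curate a variant set
#'
#' Partitions a deduplicated variant table into the known-pathogenic set, the
#' rare predicted-deleterious candidate set, and the excluded remainder, per
#' [classify_variants()].  The three parts always partition the input.
#'
#' @inheritParams classify_variants
#' @return An object of class `ns_curation`: a list with tibbles `known`,
#'   `candidates` and `excluded` (the latter keeping its `reason` column) and
#'   a `tally` of per-gene class counts.
#' @examples
#' variants <- read_variant_table(ns_example("rare_predicted_deleterious_variants.tsv"))
#' curate_set(variants)
#' @export
curate_set <- function(variants, catalogue = NULL, ...) {
  key <- variant_key(variants)
  if (anyDuplicated(key)) {
    warn(sprintf("curating a set with %d duplicated variant key(s); each row is classified independently",
                 sum(duplicated(key))))
  }
  cls <- classify_variants(variants, catalogue, ...)
  out <- list(
    known      = cls[cls$label == "known_pathogenic", names(cls) != "reason"],
    candidates = cls[cls$label == "predicted_deleterious", names(cls) != "reason"],
    excluded   = cls[cls$label == "excluded", ],
    tally      = dplyr::count(cls, .data$gene, .data$label)
  )
  structure(out, class = "ns_curation")
}

#' @export
print.ns_curation <- function(x, ...) {
  cat(sprintf("Curated variant set: %d known pathogenic, %d predicted deleterious, %d excluded\n",
              nrow(x$known), nrow(x$candidates), nrow(x$excluded)))
  print(x$tally)
  invisible(x)
}
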