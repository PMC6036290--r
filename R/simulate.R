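#' Configuration for a simulated population variant dataset
#'
#' Describes a gnomAD-like stated world: per-gene summed pathogenic allele
#' frequencies split over several rare variants, per-population chromosome
#' counts, and decoy variants exercising every curation filter.  Defaults
#' mirror the real databases the pipeline consumes: gnomAD exomes all
#' populations (~246,000 chromosomes), gnomAD South-Asian (~30,780), 1000
#' Genomes phase 3 (5,008) and its PJL subset (192); three nephrosis genes
#' with summed pathogenic frequencies of the order observed there (0.15 % for
#' *NPHS2*, low 0.01 % range for *LAMB2*/*NPHS1*).
#'
#' @param genes Tibble with `name`, `true_q` (summed pathogenic allele
#'   frequency, in (0, 0.05)), `n_pathogenic` (variants carrying it),
#'   `n_catalogued` (how many of those are in the catalogue).
#' @param populations Tibble with `tag` and `an` (chromosomes genotyped,
#'   >= 1000... the PJL subset, 192, is deliberately below that floor and is
#'   accepted with a warning as the real database it mirrors).
#' @param decoys Named integer vector: `n_common` (missense with MAF >= 1 %),
#'   `n_benign` (rare missense with low Condel), `n_synonymous`.
#' @param seed Mandatory integer seed; all sampling is reproducible.
#' @return A list of class `ns_sim_config`.
#' @export
sim_config <- function(genes = NULL, populations = NULL,
                       decoys = c(n_common = 6L, n_benign = 6L, n_synonymous = 6L),
                       seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory")
  genes <- genes %||% tibble(
    name = c("NPHS2", "LAMB2", "NPHS1"),
    true_q = c(0.0015, 1e-4, 3e-4),
    n_pathogenic = c(9L, 4L, 9L),
    n_catalogued = c(4L, 2L, 4L)
  )
  populations <- populations %||% tibble(
    tag = ns_default_populations,
    an = c(246000L, 30780L, 5008L, 192L)
  )
  stopifnot(all(genes$true_q > 0), all(genes$true_q < 0.05),
            all(genes$n_catalogued <= genes$n_pathogenic),
            all(genes$n_pathogenic >= 1))
  if (any(populations$an < 1000)) {
    warn("population(s) with fewer than 1000 chromosomes: expect noisy frequencies")
  }
  decoys <- decoys[c("n_common", "n_benign", "n_synonymous")]
  structure(list(genes = genes, populations = populations,
                 decoys = decoys, seed = as.integer(seed)),
            class = "ns_sim_config")
}

#' Split a gene's summed frequency over its variants
#'
#' Draws positive per-variant frequencies summing exactly to `true_q`
#' (symmetric Dirichlet weights, concentration 1) — rare recessive alleles in
#' population databases are typically spread over many ultra-rare variants
#' plus a few more frequent ones, which flat Dirichlet weights emulate.
#'
#' @param true_q Summed frequency.
#' @param n Number of variants.
#' @return Numeric vector of length `n`, positive, summing to `true_q`.
#' @export
split_gene_frequency <- function(true_q, n) {
  stopifnot(n >= 1, true_q > 0)
  if (n == 1) return(true_q)
  w <- rgamma(n, shape = 1)
  true_q * w / sum(w)
}

#' Sample database allele counts for a variant
#'
#' Each population's alternate count is Binomial(AN, q): chromosomes are
#' sampled independently, with no relatedness or population structure — the
#' simplest model consistent with database AC/AN semantics.
#'
#' @param q Per-variant true alternate allele frequency.
#' @param an Named integer vector of chromosome counts per population tag.
#' @return Named integer vector of alternate counts (`AC <= AN` by
#'   construction).
#' @export
sample_allele_counts <- function(q, an) {
  stopifnot(q >= 0, q <= 1)
  counts <- rbinom(length(an), size = an, prob = q)
  names(counts) <- names(an)
  counts
}

#' Simulate a gnomAD-like dataset with known ground truth
#'
#' Writes a variant table (TSV and VCF), a pathogenic catalogue and a truth
#' table to `dir`.  Pathogenic variants are made unambiguously curatable:
#' roughly a third are truncating (stop gained / frameshift, no scores), the
#' rest missense with Condel in `[0.55, 0.95]`; benign decoys get Condel in
#' `[0.05, 0.30]`, common decoys a true frequency in `[0.05, 0.30]`, and
#' synonymous decoys a synonymous annotation — margins wide enough that
#' curation must recover the truth labels exactly.
#'
#' @param config An [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @return A list: `paths` (files `variants`, `vcf`, `catalogue`, `truth`),
#'   `truth` (tibble of per-variant labels and true frequencies),
#'   `variants_table` and `dir`.
#' @export
simulate_dataset <- function(config, dir = tempfile("ns_sim_")) {
  stopifnot(inherits(config, "ns_sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  an <- stats::setNames(config$populations$an, config$populations$tag)
  chrom_of <- c(NPHS2 = "1", LAMB2 = "3", NPHS1 = "19")
  bases <- c("A", "C", "G", "T")
  aa3 <- c("Ala", "Arg", "Asn", "Asp", "Gly", "His", "Leu", "Pro", "Ser", "Val")

  rows <- list()
  truth <- list()
  pos_counter <- 0L
  add_variant <- function(gene, q, label, category) {
    pos_counter <<- pos_counter + 1L
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    ac <- sample_allele_counts(q, an)
    csq <- switch(category,
      missense    = sprintf("p.%s%d%s", sample(aa3, 1), pos_counter,
                            sample(aa3, 1)),
      stop_gained = sprintf("p.%s%dTer", sample(aa3, 1), pos_counter),
      frameshift  = sprintf("p.%s%dfsTer%d", sample(aa3, 1), pos_counter,
                            sample(3:40, 1)),
      synonymous  = {
        res <- sample(aa3, 1)
        sprintf("p.%s%d%s", res, pos_counter, res)  # "=" is INFO-unsafe in VCF
      }
    )
    row <- tibble(
      gene = gene,
      chrom = chrom_of[[gene]] %||% "1",
      pos = 1000000L + pos_counter * 100L,
      rsid = sprintf("rs9%06d", pos_counter),
      ref = ref, alt = alt,
      consequence = csq,
      category = category,
      sift = NA_real_, pph2 = NA_real_, ma = NA_real_, fathmm = NA_real_,
      condel = NA_real_, condel_label = NA_character_
    )
    if (category == "missense") {
      row$condel <- switch(label,
        benign_decoy = runif(1, 0.05, 0.30),
        runif(1, 0.55, 0.95))
      row$condel_label <- ifelse(row$condel >= 0.5, "D", "N")
    }
    for (tag in names(an)) {
      row[[paste0("ac_", tag)]] <- as.integer(ac[[tag]])
      row[[paste0("an_", tag)]] <- as.integer(an[[tag]])
    }
    rows[[length(rows) + 1L]] <<- row
    truth[[length(truth) + 1L]] <<- tibble(
      gene = gene, chrom = row$chrom, pos = row$pos, ref = ref, alt = alt,
      label = label, true_q = q
    )
  }

  catalogue_rows <- list()
  for (i in seq_len(nrow(config$genes))) {
    g <- config$genes[i, ]
    q_split <- split_gene_frequency(g$true_q, g$n_pathogenic)
    cats <- rep("missense", g$n_pathogenic)
    if (g$n_pathogenic >= 3) {
      n_trunc <- max(1L, g$n_pathogenic %/% 3L)
      cats[seq_len(n_trunc)] <- sample(c("stop_gained", "frameshift"),
                                       n_trunc, replace = TRUE)
    }
    for (j in seq_len(g$n_pathogenic)) {
      label <- if (j <= g$n_catalogued) "known_pathogenic" else "predicted_deleterious"
      add_variant(g$name, q_split[j], label, cats[j])
      if (label == "known_pathogenic") {
        v <- rows[[length(rows)]]
        catalogue_rows[[length(catalogue_rows) + 1L]] <- tibble(
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          rsid = v$rsid, source_id = sprintf("CM%06d", length(catalogue_rows) + 1L),
          significance = "pathogenic"
        )
      }
    }
  }
  gene_names <- config$genes$name
  decoy_gene <- function() sample(gene_names, 1)
  for (k in seq_len(config$decoys[["n_common"]])) {
    add_variant(decoy_gene(), runif(1, 0.05, 0.30), "common_decoy", "missense")
  }
  for (k in seq_len(config$decoys[["n_benign"]])) {
    add_variant(decoy_gene(), runif(1, 1e-4, 1e-3), "benign_decoy", "missense")
  }
  for (k in seq_len(config$decoys[["n_synonymous"]])) {
    add_variant(decoy_gene(), runif(1, 1e-4, 1e-3), "synonymous_decoy", "synonymous")
  }

  variants <- bind_rows(rows)
  truth <- bind_rows(truth)
  truth$label_expected <- unname(c(known_pathogenic = "known_pathogenic",
                            predicted_deleterious = "predicted_deleterious",
                            common_decoy = "excluded",
                            benign_decoy = "excluded",
                            synonymous_decoy = "excluded")[truth$label])

  paths <- list(
    variants = file.path(dir, "variants.tsv"),
    vcf = file.path(dir, "variants.vcf"),
    catalogue = file.path(dir, "catalogue.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_variant_table(variants, paths$variants)
  write_sim_vcf(variants, config$populations, paths$vcf)
  catalogue <- if (length(catalogue_rows)) bind_rows(catalogue_rows) else {
    tibble(chrom = character(), pos = integer(), ref = character(),
           alt = character(), rsid = character(), source_id = character(),
           significance = character())
  }
  readr::write_tsv(catalogue, paths$catalogue, progress = FALSE)
  readr::write_tsv(truth, paths$truth, progress = FALSE)
  list(paths = paths, truth = truth, variants_table = variants, dir = dir)
}

# sites-only VCFv4.2 emission: AC/AN INFO per population, plus GENE/CONSEQ/
# CONDEL annotations read back by read_vcf(); the first population tag maps
# to plain AC/AN, the rest to AC_<tag in lower case>
write_sim_vcf <- function(variants, populations, path) {
  tags <- populations$tag
  suffix <- c("", tolower(tags[-1]))
  names(suffix) <- tags
  fld <- function(s, base) if (s == "") base else paste0(base, "_", s)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"HGVS-style consequence\">",
    "##INFO=<ID=CONDEL,Number=1,Type=Float,Description=\"Condel consensus score\">",
    unlist(lapply(tags, function(t) c(
      sprintf("##INFO=<ID=%s,Number=A,Type=Integer,Description=\"Alternate allele count (%s)\">",
              fld(suffix[[t]], "AC"), t),
      sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Total allele number (%s)\">",
              fld(suffix[[t]], "AN"), t)
    ))),
    unlist(lapply(unique(variants$chrom), function(ch)
      sprintf("##contig=<ID=%s>", ch))),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  ord <- order(variants$chrom, variants$pos)
  v <- variants[ord, ]
  info <- vapply(seq_len(nrow(v)), function(i) {
    parts <- c(sprintf("GENE=%s", v$gene[i]),
               sprintf("CONSEQ=%s", v$consequence[i]))
    if (!is.na(v$condel[i])) {
      parts <- c(parts, sprintf("CONDEL=%.6f", v$condel[i]))
    }
    for (t in names(suffix)) {
      parts <- c(parts,
                 sprintf("%s=%d", fld(suffix[[t]], "AC"), v[[paste0("ac_", t)]][i]),
                 sprintf("%s=%d", fld(suffix[[t]], "AN"), v[[paste0("an_", t)]][i]))
    }
    paste(parts, collapse = ";")
  }, character(1))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                  v$chrom, v$pos, v$rsid, v$ref, v$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
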