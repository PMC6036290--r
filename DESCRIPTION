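Package: nephroprev
Title: Recessive Nephrotic Syndrome Prevalence and Carrier Frequency from
    Population Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the population prevalence and carrier frequency of
    autosomal-recessive nephrotic syndrome from aggregated allele counts of
    pathogenic and candidate-deleterious variants in the NPHS1, NPHS2 and
    LAMB2 genes.  Provides readers for gnomAD/1000 Genomes style allele-count
    tables (TSV and VCF), curation of variants into known-pathogenic,
    predicted-deleterious and excluded classes (HGMD/ClinVar catalogue
    membership, MAF < 0.01 rarity filter, consequence filter and Condel-based
    deleteriousness consensus), per-gene allele-frequency pooling under a
    sum-AC / mean-AN convention, Hardy-Weinberg prevalence (1/q^2) and
    carrier-frequency (1/2pq) estimation with per-population, merged-dataset
    and combined-gene reports, a frameshift translation-consequence utility,
    and a seeded binomial simulator of gnomAD-like datasets with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    jsonlite,
    readr,
    rlang,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tibble,
    utils,
    VariantAnnotation
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
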