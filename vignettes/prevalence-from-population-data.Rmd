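---
title: "Estimating recessive-disease prevalence from population allele counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating recessive-disease prevalence from population allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephroprev)
```

## The model

Nephrotic syndrome in early childhood is, in a large fraction of cases, an
autosomal-recessive disease of the glomerular filtration barrier, caused by
biallelic mutations in *NPHS1* (nephrin), *NPHS2* (podocin) or *LAMB2*
(laminin β2). Population sequencing databases record for each variant and
population an alternate allele count (AC) and total allele number (AN). If a
set of variants in a gene is accepted as disease causing, their pooled
frequency

$$q = \frac{\sum_i \mathrm{AC}_i}{\overline{\mathrm{AN}}}, \qquad p = 1 - q$$

estimates the gene's mutant allele frequency, and Hardy–Weinberg equilibrium
converts it into population figures:

$$\text{prevalence} = q^2 \;(\text{"1 in } 1/q^2\text{"}), \qquad
  \text{carrier frequency} = 2pq \;(\text{"1 in } 1/2pq\text{"}).$$

The assumptions are strong and worth stating: random mating, full penetrance,
every pooled allele fully pathogenic and recessive, no copy-number or deep
intronic alleles, and independence of loci. Any violation (consanguinity,
incomplete penetrance of missense alleles, benign alleles slipping through
curation) biases the estimate — mostly upward for prevalence. The package
therefore treats these figures as *population-genomic upper-bound style
estimates*, complementary to clinical-registry counts.

All three genes sit on autosomes and are modelled identically; X-linked or
dominant models are out of scope.

## Curation rules

`classify_variants()` applies, in priority order:

1. **Catalogue membership.** A variant listed in an HGMD/ClinVar-style
   catalogue (genomic key, rsID fallback) is `known_pathogenic` regardless of
   its frequency — the known set is defined by the catalogue, and the rarity
   filter below applies only to the *remaining* variants.
2. **Rarity.** Minor allele frequency strictly below `maf_threshold`
   (default 0.01) in the reference population (`GNOMAD_ALL` by default,
   falling back to the maximum MAF over populations with data when the
   reference has none). At-threshold variants are excluded as common.
3. **Consequence.** Only missense, stop-gained, frameshift, in-frame indel
   and essential splice (±1, ±2) variants qualify; synonymous and other
   categories are excluded.
4. **Deleteriousness consensus.** Truncating categories pass with no scores —
   the source tables leave score cells empty for nonsense/frameshift/splice
   alleles yet count them. Scored missense variants pass iff Condel ≥
   `condel_threshold` (default 0.5; every published Condel value labelled
   `D` in the packaged tables is ≥ 0.52, so the default separates cleanly).
   When Condel is absent, a majority vote over the available single tools
   (SIFT < 0.05, PolyPhen-2 ≥ 0.85, MutationAssessor ≥ 1.9, FATHMM ≤ −1.5 —
   each tool's conventional default, all configurable) decides; fewer than
   two calls either way yields `insufficient_scores`.

The partition property — known + candidates + excluded = input — is
property-tested, as is monotonicity in the MAF threshold.

## Pooling conventions

Three conventions were genuinely open and were fixed by reverse-engineering
which choice reproduces the reference summary tables exactly; each is
asserted in the test suite.

* **Within a gene and population: sum AC, average AN** (arithmetic mean,
  half-up to an integer). Variant-level AN differs across variants because
  coverage differs; the mean-AN denominator reproduces the published pooled
  cells (e.g. nine *NPHS2* variants with 380 summed alleles over mean AN
  256,102). One published denominator (*NPHS1* gnomAD, 251,247) cannot be
  obtained this way — the recomputed value 248,556 deviates by 1.08 %, the
  pooled numerator being exact; the discrepancy is documented per cell in the
  packaged published-summary fixtures and asserted *as a deviation bound*,
  not silently absorbed.
* **Across databases: sum AC and AN.** Merging gnomAD with 1000 Genomes
  simply adds chromosomes (380/256,102 ⊕ 20/5,008 = 400/261,110).
* **Across genes: pooled counts by default.** The combined row sums the
  per-gene AC and averages the per-gene effective AN, which reproduces the
  published combined cells. The alternative reading of the stated method —
  adding the per-gene homozygote frequencies, prevalence $1/\sum_g q_g^2$ —
  is provided as `combine_genes(mode = "sum_homozygote")`; neither is
  asserted as "correct", and for small $q$ with one dominant gene the two
  agree closely anyway.

A gene with *no observed variant* in a population is not "frequency zero" in
general; but absence from a *complete* callset like 1000 Genomes phase 3 is
an observation of 0 alternate alleles out of the full chromosome count. The
report builder therefore substitutes 0/5,008 (and 0/192 for PJL) for genes
without 1KG rows — matching the published tables — while leaving populations
without a configured default undefined. Zero-frequency pools yield `-` cells,
never a division by zero: undefined and zero are kept distinct throughout.

## Rounding

Two conventions:

* `rounding = "raw"` — the scientific default: the unrounded $q$ enters the
  formulas.
* `rounding = "paper_compat"` — reproduces the reference tables: the
  percentage is **truncated at three decimal places** before the formulas
  (computed on the integer grid $\lfloor 10^5 q \rfloor / 10^5$ so that
  printed frequencies like 0.148 % are reproduced bit-exactly), and the
  "1 in N" figures are rounded **half-up** to integers (verified boundary
  cases: 10,000.5 → 10,001 and 1,250.5 → 1,251).

Truncation was chosen over rounding or 3-significant-figure formatting
because it reproduces strictly more of the published cells (e.g. 0.048 from
0.0487, 0.022 from 0.0226, and 0.005 from 0.0053, which 3 significant
figures cannot produce). The single published column it cannot reproduce is
the 192-chromosome PJL subset, printed under a different convention (1.560
for 3/192 = 1.5625); those cells are flagged as documented deviations by
`cmd_reproduce()` rather than matched by a special case.

Pre-rounding, every estimate self-checks the algebraic identities
$\mathrm{prev}_\mathrm{raw}\,q^2 = 1$, $\mathrm{carrier}_\mathrm{raw}\,2pq = 1$
and $\mathrm{prev}_\mathrm{raw} = 4p^2\,\mathrm{carrier}_\mathrm{raw}^2$.

## The packaged fixtures and what "reproduces" means

`inst/extdata/` ships transcriptions of the reference variant tables (56
known pathogenic variants; 23 rare predicted-deleterious candidates), a
catalogue keyed on the known set, and the published summary values with a
per-cell check class (`exact` / `denominator` / `deviation`; see
`?published_summary` and `inst/extdata/README-fixtures.md`). Notable
wrinkles, handled explicitly rather than papered over:

* The two variant tables share one genomic variant (1:179520493 A/G),
  annotated under two transcript numberings. The published
  known-plus-predicted sums double-count it, so `reproduce_published()`
  concatenates the tables without cross-table deduplication; deduplication
  applies *within* a table read. Classifying the 79-row concatenation against
  the catalogue yields 57 known / 22 candidates (catalogue membership is
  genomic), while the per-table runs yield the published 56 and 23.
* The published combined South-Asian numerator (127) does not equal the sum
  of its own per-gene cells (29 + 40 + 53 = 122); the combined frequencies
  0.23 %/0.420 % likewise cannot be derived from the printed counts. The
  headline worldwide and South-Asian figures (1 in 189,036 / 1 in 218 and
  1 in 56,689 / 1 in 120) are therefore reproduced by applying the
  Hardy–Weinberg formulas to those *printed* frequencies
  (`headline_estimates()`), which matches exactly.

## The simulator's stated world

`simulate_dataset()` emulates what the pipeline actually consumes: database
summary counts. Per gene, a true summed pathogenic frequency (defaults on the
scale observed for these genes: 0.15 % for *NPHS2*, 0.01–0.03 % for the
others) is split over several variants with flat (symmetric, concentration-1)
Dirichlet weights, and each variant's AC is drawn Binomial(AN, q)
independently per population, with the real database sizes as defaults
(246,000 / 30,780 / 5,008 / 192 chromosomes). Decoys exercise every filter:
common missense (true frequency 5–30 %), rare benign missense (Condel
0.05–0.30), and synonymous variants. Pathogenic variants get Condel in
[0.55, 0.95] or truncating consequences, so score margins never straddle the
thresholds and curation must recover the truth labels exactly.

What this world does **not** contain: relatedness, population structure,
linkage between variants, genotype-level data, sequencing error, or realistic
in-silico score distributions. A green parameter-recovery test therefore
establishes that the *pipeline arithmetic* is unbiased at binomial sampling
noise — not that real gnomAD counts are unbiased estimates of pathogenic
allele frequencies. Seeds are mandatory; equal seeds give byte-identical
output files.

## Limitations

* No confidence intervals are attached to $q$ or the 1-in-N figures (the
  reference analysis reports none); for rare pooled counts a
  Poisson/binomial interval would be wide and should be added before any
  clinical use.
* No inbreeding correction: in consanguineous populations prevalence exceeds
  $q^2$, so the South-Asian figures are conservative in that respect.
* Catalogue membership is trusted as pathogenic; reclassified or
  benign-in-hindsight catalogue entries inflate $q$.
* Consequence categories are inputs (HGVS-string classification); there is no
  sequence-based consequence calling, liftover, or splice-strength
  prediction.
* The mean-AN effective denominator is a reverse-engineered reporting
  convention, not an estimator with optimality properties; `rounding = "raw"`
  plus per-variant AN inspection is preferable for new analyses.
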