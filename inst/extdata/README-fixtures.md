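# Packaged fixtures

All fixtures are small plain-text TSV files transcribed from the published
gnomAD r2 exome / 1000 Genomes phase-3 allele-count summaries for the *NPHS1*,
*NPHS2* and *LAMB2* genes that this package reproduces.

## Variant tables

- `known_pathogenic_variants.tsv` — 56 coding variants (12 *NPHS2*, 26 *LAMB2*,
  18 *NPHS1*) annotated as disease causing in HGMD/ClinVar, with per-population
  `AC/AN` cells (gnomAD all, gnomAD-SAS, 1KG all, 1KG-PJL) and SIFT / PolyPhen-2
  / MutationAssessor / FATHMM / Condel scores where the source printed them.
- `rare_predicted_deleterious_variants.tsv` — 23 additional rare coding variants
  (10 *NPHS2*, 4 *LAMB2*, 9 *NPHS1*) not catalogued as known disease alleles but
  scored deleterious (Condel label D) or truncating.

Normalizations applied during transcription (the source tables contain
typographic variants):

- count cells printed as `20in5008`, `56in30960`, bare `192` etc. are
  normalized to the strict `<int>/<int>` grammar (`20/5008`, `0/192`);
- Unicode minus signs in FATHMM scores are ASCII `-`;
- one row (*LAMB2* p.Tyr275Ter, 3:49168473) is printed with Ref/Alt `A/A`,
  which is impossible; the alt is recorded here as `T` (the ref/alt pair is
  metadata only for every computation in this package — counts drive all
  estimates);
- empty or dash cells mean "no data in that population", never zero.

## Catalogue

`pathogenic_catalogue.tsv` — lookup keys (chrom, pos, ref, alt, rsid) for the
56 known pathogenic variants. The source prints dbSNP rsIDs but not HGMD
accessions, so `source_id` repeats the rsID; this column is synthetic stand-in
metadata, never used numerically.

## Published summary tables

`published_summary_known.tsv` and `published_summary_known_plus_predicted.tsv`
transcribe the published per-gene / per-population summary blocks (allele
count, mutant allele frequency in percent, prevalence "1 in N", carrier
frequency "1 in N") for the known-only and known-plus-predicted variant sets.
Each value carries a check class used by `reproduce_published()`:

- `exact` — the pipeline recomputes this value bit-for-bit from the variant
  tables above;
- `denominator` — the pooled alternate-allele numerator reproduces exactly but
  the printed effective allele number deviates (at most 1.1 %) from the
  mean-AN pooling convention that reproduces every other cell; derived cells
  may inherit the discrepancy;
- `deviation` — the printed value is internally inconsistent with the printed
  per-variant counts (e.g. the combined SAS numerator 127 versus the printed
  per-gene cells summing to 122, frequencies rounded under a different
  convention in the PJL column, and one garbled combined count cell stored
  here as `-`). These cells are reported, not asserted.
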