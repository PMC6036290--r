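test_that("allele-count cells parse, reject bad input, and round-trip", {
  ct <- parse_allele_count(c("380/256102", "0/30780", "17/5008"))
  expect_equal(ct$ac, c(380L, 0L, 17L))
  expect_equal(ct$an, c(256102L, 30780L, 5008L))

  # dash and empty cells are missing data, never zero
  miss <- parse_allele_count(c("-", "", NA, "–"))
  expect_true(all(is.na(miss$ac)))

  expect_error(parse_allele_count("20in5008"), "malformed")
  expect_error(parse_allele_count("5/7"), NA)
  expect_error(parse_allele_count("8/5"), "AC <= AN")

  # format o parse is the identity on valid counts
  cells <- c("0/1000", "380/256102", "17/5008", "1/192")
  rt <- parse_allele_count(cells)
  expect_identical(format_allele_count(rt$ac, rt$an), cells)
})

test_that("packaged variant tables load with the published per-gene splits", {
  known <- ns_variants("known")
  cand <- ns_variants("candidates")
  expect_equal(nrow(known), 56L)
  expect_equal(nrow(cand), 23L)
  expect_equal(as.list(table(known$gene)),
               list(LAMB2 = 26L, NPHS1 = 18L, NPHS2 = 12L))
  expect_equal(as.list(table(cand$gene)),
               list(LAMB2 = 4L, NPHS1 = 9L, NPHS2 = 10L))
  expect_setequal(variant_populations(known),
                  c("GNOMAD_ALL", "GNOMAD_SAS", "KG_ALL", "KG_PJL"))
  # a dash 1KG cell is distinct from the zero-count SAS cell on the same row
  row1 <- known[known$pos == 179520493, ]
  expect_identical(row1$ac_GNOMAD_SAS, 0L)
  expect_identical(row1$ac_KG_ALL, 1L)
  expect_true(is.na(known$ac_KG_ALL[known$pos == 179520354]))
})

test_that("variant tables round-trip through write/read and reject bad schemas", {
  withr::local_seed(11)
  x <- random_variant_table(25)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(x, path)
  expect_equal(read_variant_table(path), x)

  # header-only file gives an empty table
  empty <- x[0, ]
  write_variant_table(empty, path)
  expect_equal(nrow(read_variant_table(path)), 0L)

  # identical duplicate rows collapse with a warning; conflicting ones error
  write_variant_table(rbind(x, x[1, ]), path)
  expect_warning(dup <- read_variant_table(path), "duplicated")
  expect_equal(nrow(dup), 25L)
  y <- x[1, ]
  y$condel <- 0.99
  write_variant_table(rbind(x, y), path)
  expect_error(suppressWarnings(read_variant_table(path)), "conflicting")

  # missing mandatory column
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tchrom\tpos\tref", bad)
  expect_error(read_variant_table(bad), "missing mandatory")
})

test_that("catalogues load, deduplicate and match by key or rsid fallback", {
  cat56 <- ns_catalogue_fixture()
  expect_equal(nrow(cat56), 56L)

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\trsid\tsource_id",
               "1\t100\tA\tG\trs1\tCM000001",
               "1\t100\tA\tG\trs1\tCM000002"), path)
  expect_warning(cat1 <- read_catalogue(path), "duplicate")
  expect_equal(nrow(cat1), 1L)
  expect_equal(cat1$source_id, "CM000001")

  writeLines("chrom\tpos\tref\talt\trsid\tsource_id", path)
  expect_equal(nrow(read_catalogue(path)), 0L)

  v <- tibble::tibble(chrom = c("1", "1", "2"), pos = c(100L, 999L, 5L),
                      ref = "A", alt = "G", rsid = c(NA, "rs1", "rs2"))
  expect_equal(catalogue_match(v, cat1), c(TRUE, TRUE, FALSE))
})

test_that("VCF reading decomposes multi-allelic sites and round-trips simulated counts", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\trs1\tG\tA\t.\t.\tAC=2;AN=5008",
    "1\t200\t.\tC\tA,T\t.\t.\tAC=3,1;AN=5008"
  ), vcf)
  x <- read_vcf(vcf, populations = c(KG_ALL = ""))
  expect_equal(nrow(x), 3L)
  expect_equal(x$ac_KG_ALL, c(2L, 3L, 1L))
  expect_equal(x$an_KG_ALL, rep(5008L, 3))
  expect_equal(x$pos, c(100L, 200L, 200L))
  expect_equal(x$alt, c("A", "A", "T"))
  expect_equal(x$rsid, c("rs1", NA, NA))

  # simulated VCF round-trips every count against the generator's truth
  sim <- simulate_dataset(suppressWarnings(sim_config(seed = 402)),
                          dir = withr::local_tempdir())
  tags <- c(GNOMAD_ALL = "", GNOMAD_SAS = "gnomad_sas", KG_ALL = "kg_all",
            KG_PJL = "kg_pjl")
  from_vcf <- read_vcf(sim$paths$vcf, populations = tags)
  tab <- sim$variants_table
  ord_v <- order(from_vcf$chrom, from_vcf$pos)
  ord_t <- order(tab$chrom, tab$pos)
  for (tag in names(tags)) {
    expect_equal(from_vcf[[paste0("ac_", tag)]][ord_v],
                 tab[[paste0("ac_", tag)]][ord_t])
    expect_equal(from_vcf[[paste0("an_", tag)]][ord_v],
                 tab[[paste0("an_", tag)]][ord_t])
  }
  expect_equal(from_vcf$category[ord_v], tab$category[ord_t])

  noac <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
               "##contig=<ID=1>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "1\t100\t.\tG\tA\t.\t.\tAN=5008"), noac)
  expect_error(read_vcf(noac, populations = c(KG_ALL = "")), "lacks INFO field AC")
})

test_that("summary tables write in the gene-block layout and round-trip bit-exactly", {
  v <- ns_variants("candidates")
  rep <- build_report(v, genes = c("NPHS2", "LAMB2", "NPHS1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary(rep, path)

  lines <- readLines(path)
  expect_match(lines[1], "^gene\tmeasure\tgnomAD\t")
  nphs2 <- strsplit(grep("^NPHS2\t", lines, value = TRUE), "\t")
  expect_equal(nphs2[[1]][2:3], c("Allele Count", "380/256102"))
  expect_equal(nphs2[[2]][2:3], c("Mutant Allele Feq (%)", "0.148"))
  expect_equal(nphs2[[3]][2:3], c("Prevalence (1 in)", "456538"))
  expect_equal(nphs2[[4]][2:3], c("Carrier Frq (1 in)", "338"))
  # zero-frequency cells are dashes, not divisions by zero
  lamb2 <- strsplit(grep("^LAMB2\t", lines, value = TRUE), "\t")
  expect_equal(lamb2[[3]][5], "-")

  back <- read_summary(path)
  key <- c("gene", "column", "ac", "an", "q_used", "prevalence", "carrier")
  rep_df <- as.data.frame(rep[key])
  back_df <- as.data.frame(back[key])
  expect_equal(back_df[order(back_df$gene, back_df$column), ],
               rep_df[order(rep_df$gene, rep_df$column), ],
               ignore_attr = TRUE)

  # raw rounding mode round-trips full-precision frequencies too
  rep_raw <- build_report(v, genes = c("NPHS2", "LAMB2", "NPHS1"),
                          rounding = "raw")
  write_summary(rep_raw, path)
  back_raw <- read_summary(path)
  expect_equal(sort(back_raw$q_used), sort(rep_raw$q_used))
})
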