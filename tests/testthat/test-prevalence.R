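test_that("gene pooling follows the sum-AC / mean-AN convention", {
  v <- ns_variants("candidates")

  s <- aggregate_gene(v, "NPHS2", "GNOMAD_ALL")
  expect_equal(s$ac, 380L)
  expect_equal(s$an, 256102L)
  expect_equal(s$n_variants, 9L)

  kg <- aggregate_gene(v, "NPHS2", "KG_ALL")
  expect_equal(kg$ac, 20L)   # 1 + 1 + 1 + 17
  expect_equal(kg$an, 5008L)
  expect_equal(kg$n_variants, 4L)

  lamb2 <- aggregate_gene(v, "LAMB2", "GNOMAD_ALL")
  expect_equal(c(lamb2$ac, lamb2$an), c(13L, 244165L))

  # single variant: pooling is the identity
  one <- v[v$consequence == "p.Pro43Ala", ]
  s1 <- aggregate_gene(one, "NPHS2", "KG_ALL")
  expect_equal(c(s1$ac, s1$an, s1$n_variants), c(17L, 5008L, 1L))

  # no data: undefined, not zero
  s0 <- aggregate_gene(v, "LAMB2", "KG_ALL")
  expect_true(is.na(s0$ac))
  expect_equal(s0$n_variants, 0L)
})

test_that("pooling equals a brute-force per-variant summation oracle", {
  withr::local_seed(31)
  for (i in 1:10) {
    x <- random_variant_table(30)
    for (g in unique(x$gene)) {
      s <- aggregate_gene(x, g, "GNOMAD_ALL")
      keep <- x$gene == g & !is.na(x$ac_GNOMAD_ALL)
      if (!any(keep)) {
        expect_true(is.na(s$ac))
      } else {
        expect_equal(s$ac, sum(x$ac_GNOMAD_ALL[keep]))
        expect_equal(s$an, as.integer(floor(mean(x$an_GNOMAD_ALL[keep]) + 0.5)))
      }
    }
  }

  # monotonicity: an extra variant with AC > 0 at the same AN never lowers q
  x <- random_variant_table(10)
  x$an_GNOMAD_ALL <- 10000L
  x$ac_GNOMAD_ALL <- rbinom(10, 10000L, 0.001)
  base <- aggregate_gene(x, x$gene[1], "GNOMAD_ALL")
  extra <- x[1, ]
  extra$pos <- 999999L
  extra$ac_GNOMAD_ALL <- 3L
  grown <- aggregate_gene(rbind(x, extra), x$gene[1], "GNOMAD_ALL")
  expect_gte(grown$ac / grown$an, base$ac / base$an)
})

test_that("dataset merging sums counts and chromosomes, commutatively and associatively", {
  v <- ns_variants("candidates")
  gnomad <- aggregate_gene(v, "NPHS2", "GNOMAD_ALL")
  kg <- aggregate_gene(v, "NPHS2", "KG_ALL")
  m <- merge_datasets(gnomad, kg)
  expect_equal(c(m$ac, m$an), c(400L, 261110L))

  sas <- aggregate_gene(v, "NPHS2", "GNOMAD_SAS")
  pjl <- aggregate_gene(v, "NPHS2", "KG_PJL")
  m2 <- merge_datasets(sas, pjl)
  expect_equal(c(m2$ac, m2$an), c(18L, 30964L))

  # commutative on the counts
  m_rev <- merge_datasets(kg, gnomad)
  expect_equal(c(m_rev$ac, m_rev$an), c(m$ac, m$an))
  # associative across three pools
  a <- gnomad; b <- kg; c3 <- sas
  left <- merge_datasets(merge_datasets(a, b), c3)
  right <- merge_datasets(a, merge_datasets(b, c3))
  expect_equal(c(left$ac, left$an), c(right$ac, right$an))

  # zero-count merge only adds chromosomes
  zero <- tibble::tibble(gene = "NPHS2", population = "X", dataset = "X",
                         ac = 0L, an = 5008L, n_variants = 1L)
  mz <- merge_datasets(gnomad, zero)
  expect_equal(c(mz$ac, mz$an), c(gnomad$ac, gnomad$an + 5008L))

  expect_error(merge_datasets(gnomad, aggregate_gene(v, "LAMB2", "GNOMAD_ALL")),
               "different genes")
})

test_that("gene combination reproduces pooled counts and the sum-of-homozygotes mode", {
  v <- ns_variants("candidates")
  per_gene <- dplyr::bind_rows(lapply(c("NPHS2", "LAMB2", "NPHS1"),
                                      aggregate_gene, variants = v,
                                      population = "GNOMAD_ALL"))
  comb <- combine_genes(per_gene)
  expect_equal(c(comb$ac, comb$an), c(451L, 249608L))

  # permutation-invariant
  comb_perm <- combine_genes(per_gene[c(3, 1, 2), ])
  expect_equal(c(comb_perm$ac, comb_perm$an), c(comb$ac, comb$an))

  # single summary: both modes collapse to the per-gene estimate
  single <- combine_genes(per_gene[1, ])
  expect_equal(c(single$ac, single$an), c(per_gene$ac[1], per_gene$an[1]))
  single_h <- combine_genes(per_gene[1, ], mode = "sum_homozygote",
                            rounding = "raw")
  expect_equal(single_h$prevalence,
               hw_estimate(per_gene[1, ], rounding = "raw")$prevalence)

  # three genes at q = 0.001 each: prevalence denominator 1/(3e-6)
  eq <- tibble::tibble(gene = c("A", "B", "C"), population = "P", dataset = "D",
                       ac = c(10L, 10L, 10L), an = 10000L, n_variants = 1L)
  hom <- combine_genes(eq, mode = "sum_homozygote", rounding = "raw")
  expect_equal(hom$prevalence, 333333)
  expect_equal(hom$q_used, sqrt(3e-6))

  expect_error(combine_genes(dplyr::bind_rows(
    aggregate_gene(v, "NPHS2", "GNOMAD_ALL"),
    aggregate_gene(v, "NPHS2", "KG_ALL"))), "different populations")
})

test_that("Hardy-Weinberg formulas give the published 1-in-N figures", {
  # prevalence = 1/q^2, carrier = 1/2pq, half-up integer rounding
  expect_equal(floor(hwe_prevalence(0.0023) + 0.5), 189036)
  expect_equal(floor(hwe_carrier(0.0023) + 0.5), 218)
  expect_equal(floor(hwe_prevalence(0.0042) + 0.5), 56689)
  expect_equal(floor(hwe_carrier(0.0042) + 0.5), 120)
  expect_equal(hwe_prevalence(1), 1)
  expect_equal(hwe_carrier(0.5), 2)
  expect_true(is.na(hwe_prevalence(0)))
  expect_true(is.na(hwe_carrier(1)))

  s <- tibble::tibble(gene = "NPHS2", population = "GNOMAD_ALL",
                      dataset = "GNOMAD", ac = 380L, an = 256102L,
                      n_variants = 9L)
  est <- hw_estimate(s)
  expect_equal(est$q_used * 100, 0.148)
  expect_equal(est$prevalence, 456538)
  expect_equal(est$carrier, 338)

  # the LAMB2 row exercises truncation and the half-up boundary 10000.5
  lamb2 <- tibble::tibble(gene = "LAMB2", population = "GNOMAD_ALL",
                          dataset = "GNOMAD", ac = 13L, an = 244165L,
                          n_variants = 4L)
  est2 <- hw_estimate(lamb2)
  expect_equal(est2$q_used * 100, 0.005)
  expect_equal(est2$prevalence, 400000000)
  expect_equal(est2$carrier, 10001)

  # q = 1/2 exactly
  half <- tibble::tibble(gene = "G", population = "P", dataset = "D",
                         ac = 50L, an = 100L, n_variants = 1L)
  est3 <- hw_estimate(half, rounding = "raw")
  expect_equal(est3$prevalence, 4)
  expect_equal(est3$carrier, 2)

  # zero observed alleles: undefined, not zero or infinite
  none <- tibble::tibble(gene = "G", population = "P", dataset = "D",
                         ac = 0L, an = 5008L, n_variants = 1L)
  est4 <- hw_estimate(none)
  expect_true(is.na(est4$prevalence) && is.na(est4$carrier))
})

test_that("HWE algebraic identities hold for every estimate produced", {
  withr::local_seed(17)
  for (i in 1:50) {
    an <- sample(1000:300000, 1)
    ac <- sample(0:an, 1)
    s <- tibble::tibble(gene = "G", population = "P", dataset = "D",
                        ac = ac, an = an, n_variants = 1L)
    for (rounding in c("raw", "paper_compat")) {
      est <- hw_estimate(s, rounding = rounding)
      if (is.na(est$prevalence_raw)) next
      q <- est$q_used
      expect_equal(est$prevalence_raw * q^2, 1, tolerance = 1e-12)
      expect_equal(est$carrier_raw * 2 * (1 - q) * q, 1, tolerance = 1e-12)
      expect_equal(est$prevalence_raw, 4 * (1 - q)^2 * est$carrier_raw^2,
                   tolerance = 1e-12)
    }
  }
})

test_that("the full report reproduces the published known-set combined estimates", {
  v <- ns_variants("candidates")
  rep <- build_report(v, genes = c("NPHS2", "LAMB2", "NPHS1"))
  comb <- rep[rep$column == "gnomAD+1KG" & grepl("\\+", rep$gene), ]
  expect_equal(c(comb$ac, comb$an), c(471L, 254616L))
  expect_equal(comb$q_used * 100, 0.184)
  expect_equal(comb$prevalence, 295369)
  expect_equal(comb$carrier, 272)

  sas <- rep[rep$column == "gnomAD-SAS+1KG-PJL" & grepl("\\+", rep$gene), ]
  expect_equal(c(sas$prevalence, sas$carrier), c(308642, 278))

  # degenerate case: one gene, one population column collapses to estimate()
  one <- build_report(v[v$gene == "NPHS2", ], genes = "NPHS2",
                      columns = list(gnomAD = "GNOMAD_ALL"),
                      default_an = c())
  expect_equal(one$prevalence[1], 456538)
})
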