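test_that("hypergeometric pmf matches direct binomial-coefficient arithmetic", {
  expect_equal(hypergeom_pmf(0, N = 1, K = 0, n = 1), 1)
  expect_equal(hypergeom_pmf(3, N = 12, K = 6, n = 3), 20 / 220)
  # out-of-support values are zero, not errors
  expect_equal(hypergeom_pmf(c(-1, 11, 4.5), N = 37, K = 23, n = 10),
               c(0, 0, 0))
  expect_error(hypergeom_pmf(1, N = 10, K = 11, n = 2), "domain error")
  expect_error(hypergeom_pmf(1, N = 10, K = 2, n = 11), "domain error")
})

test_that("pmf agrees with stats::dhyper across random margins", {
  set.seed(3)
  for (i in 1:50) {
    N <- sample(1:150, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- 0:n
    expect_equal(hypergeom_pmf(k, N, K, n),
                 stats::dhyper(k, K, N - K, n), tolerance = 1e-12)
  }
})

test_that("one-sided Fisher reproduces the published association grid", {
  grid <- printed_grid()
  # pooled STS column, printed to 2-3 decimals
  sts_p <- vapply(grid, function(g)
    fisher_one_sided(do.call(contingency_2x2, as.list(g$STS)))$p,
    numeric(1))
  expect_equal(round(sts_p[["Dox"]], 3), 0.036)
  expect_equal(round(sts_p[["Ifo"]], 2), 0.56)
  expect_equal(round(sts_p[["Dox+Ifo"]], 2), 0.24)
  expect_equal(round(sts_p[["Doc"]], 2), 0.36)
  expect_equal(round(sts_p[["Gem"]], 2), 0.14)
  expect_equal(round(sts_p[["Doc+Gem"]], 2), 0.21)
  # tail direction: resistance enrichment for Dox, depletion for Gem
  expect_equal(fisher_one_sided(contingency_2x2(1, 9, 13, 14))$tail,
               "upper")
  expect_equal(fisher_one_sided(contingency_2x2(6, 4, 9, 18))$tail,
               "lower")
  # UPS stratum for the headline drug
  expect_equal(round(fisher_one_sided(
    do.call(contingency_2x2, as.list(grid$Dox$UPS)))$p, 2), 0.25)
})

test_that("auto tail is the smaller of the two fixed tails", {
  set.seed(9)
  for (i in 1:100) {
    tab <- random_table(8)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) next
    up <- fisher_one_sided(tab, tail = "upper")$p
    lo <- fisher_one_sided(tab, tail = "lower")$p
    au <- fisher_one_sided(tab, tail = "auto")$p
    expect_equal(au, min(up, lo))
    expect_lte(au, max(up, lo))
    expect_gt(au, 0)
    expect_lte(up, 1); expect_lte(lo, 1)
  }
})

test_that("fixed tails agree with stats::fisher.test one-sided p-values", {
  set.seed(13)
  for (i in 1:100) {
    tab <- random_table(8)
    # upper tail on resistant among Mut+ = "less" on the sensitive column
    expect_equal(fisher_one_sided(tab, tail = "upper")$p,
                 stats::fisher.test(tab, alternative = "less")$p.value,
                 tolerance = 1e-9)
    expect_equal(fisher_one_sided(tab, tail = "lower")$p,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("swapping the call columns swaps tails but not the auto p", {
  set.seed(17)
  for (i in 1:50) {
    tab <- random_table(8)
    swapped <- tab[, 2:1]
    expect_equal(fisher_one_sided(tab, tail = "upper")$p,
                 fisher_one_sided(swapped, tail = "lower")$p,
                 tolerance = 1e-12)
    expect_equal(fisher_one_sided(tab, tail = "auto")$p,
                 fisher_one_sided(swapped, tail = "auto")$p,
                 tolerance = 1e-12)
  }
})

test_that("degenerate margins give p = 1 with a flag", {
  r <- fisher_one_sided(contingency_2x2(0, 0, 5, 7))
  expect_equal(r$p, 1)
  expect_true(r$degenerate)
  r2 <- fisher_one_sided(contingency_2x2(5, 7, 0, 0))
  expect_true(r2$degenerate)
  expect_error(fisher_one_sided(contingency_2x2(0, 0, 0, 0)),
               "empty table")
  expect_error(contingency_2x2(-1, 2, 3, 4), "domain error")
})

test_that("the stratified grid reproduces the published pooled analysis", {
  rc <- ref_cohort()
  m <- build_mutation_matrix(rc$variants, rc$panel, rc$specimens)
  g <- stratified_association(m, rc$calls, rc$annotations)
  sts <- g[g$stratum == "STS", ]
  expect_equal(round(sts$p[sts$drug == "Dox"], 3), 0.036)
  expect_equal(round(sts$p[sts$drug == "Ifo"], 2), 0.56)
  expect_equal(round(sts$p[sts$drug == "Dox+Ifo"], 2), 0.24)
  expect_equal(round(sts$p[sts$drug == "Doc"], 2), 0.36)
  expect_equal(round(sts$p[sts$drug == "Gem"], 2), 0.14)
  expect_equal(round(sts$p[sts$drug == "Doc+Gem"], 2), 0.21)
  # pairwise deletion: the two drugs with missing calls use 27 specimens
  expect_equal(sts$n_evaluable[sts$drug == "Ifo"], 27L)
  expect_equal(sts$n_evaluable[sts$drug == "Dox"], 37L)
  # UPS Dox as printed
  expect_equal(round(g$p[g$drug == "Dox" & g$stratum == "UPS"], 2), 0.25)
})

test_that("strata with no mutated or no evaluable specimens are flagged", {
  rc <- ref_cohort()
  m0 <- build_mutation_matrix(rc$variants[0, ], rc$panel, rc$specimens)
  g <- stratified_association(m0, rc$calls, rc$annotations,
                              drugs = "Dox")
  expect_true(all(g$p == 1))
  expect_true(all(g$degenerate))
  # a stratum with zero evaluable specimens comes back NA
  calls_ups_only <- rc$calls[rc$calls$specimen_id %in%
    rc$annotations$specimen_id[rc$annotations$histotype == "UPS"], ]
  g2 <- stratified_association(m0, calls_ups_only, rc$annotations,
                               drugs = "Dox")
  expect_true(is.na(g2$p[g2$stratum == "SS"]))
  expect_equal(g2$n_evaluable[g2$stratum == "SS"], 0L)
})

test_that("optional BH adjustment adds a column without changing p", {
  rc <- ref_cohort()
  m <- build_mutation_matrix(rc$variants, rc$panel, rc$specimens)
  g <- stratified_association(m, rc$calls, rc$annotations,
                              bh_adjust = TRUE)
  expect_true("p_bh" %in% names(g))
  expect_true(all(g$p_bh >= g$p, na.rm = TRUE))
})

test_that("partial-LOF reassignment strengthens the doxorubicin signal", {
  rc <- ref_cohort()
  v <- apply_lof_overrides(rc$variants, rc$lof_overrides)
  re <- reassignment_analysis(v, rc$panel, rc$specimens, rc$calls,
                              rc$annotations, drug = "Dox",
                              policy = "reassign")
  expect_equal(re$reassigned, "AF98b")
  expect_true(re$changed)
  # exact hypergeometric point mass: all 9 remaining Mut+ are resistant
  expect_equal(re$p, choose(23, 9) / choose(37, 9), tolerance = 1e-12)
  expect_equal(unname(re$table[1, ]), c(0L, 9L))
  expect_equal(unname(re$table[2, ]), c(14L, 14L))
  expect_lt(re$p, re$baseline_p)

  ex <- reassignment_analysis(v, rc$panel, rc$specimens, rc$calls,
                              rc$annotations, policy = "exclude")
  expect_equal(ex$p, choose(23, 9) / choose(36, 9), tolerance = 1e-12)
  expect_equal(sum(ex$table), 36L)
})

test_that("reassignment without partial-LOF variants is a flagged no-op", {
  rc <- ref_cohort()
  re <- reassignment_analysis(rc$variants, rc$panel, rc$specimens,
                              rc$calls, rc$annotations)
  expect_false(re$changed)
  expect_equal(re$p, re$baseline_p)
  expect_equal(round(re$p, 3), 0.036)
})

test_that("TP53 vs other-gene distribution differs between histotypes", {
  rc <- ref_cohort()
  r <- gene_class_distribution_test(rc$variants, rc$panel, rc$specimens,
                                    rc$annotations)
  # UPS: 6 TP53 + 1 other; SS: 0 TP53 + 3 other
  expect_equal(unname(r$table[1, ]), c(6L, 1L))
  expect_equal(unname(r$table[2, ]), c(0L, 3L))
  expect_equal(round(r$p, 2), 0.03)
  expect_equal(r$p, 4 / 120, tolerance = 1e-12)
})

test_that("an all-TP53 mutation spectrum in both histotypes is null", {
  rc <- ref_cohort()
  v <- rc$variants
  v$gene <- "TP53"
  r <- gene_class_distribution_test(v, rc$panel, rc$specimens,
                                    rc$annotations)
  expect_equal(r$p, 1)
})
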