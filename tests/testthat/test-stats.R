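# Nonparametric tests, percentile cutoff, exceedance, pooling and summaries.

test_that("KS screen separates normal from lognormal samples", {
  set.seed(101)
  norm <- rnorm(1e4)
  res <- ksNormality(norm)
  expect_gt(res$p_value, 0.05)
  expect_false(res$significant)

  lnorm <- rlnorm(1e4, 0, 0.8)
  res2 <- ksNormality(lnorm)
  expect_lt(res2$p_value, 0.001)
  expect_true(res2$significant)

  expect_error(ksNormality(c(1, 2, 3, 4)), "n >= 5")
  expect_error(ksNormality(rep(3, 10)), "degenerate")
})

test_that("Mann-Whitney exact p matches exhaustive enumeration", {
  res <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, mwExactOracle(c(1, 2, 3), c(4, 5, 6)))

  # another configuration, against the same oracle
  a <- c(1.2, 3.4, 7.1, 2.2); b <- c(2.8, 5.5, 9.3)
  expect_equal(mannWhitney(a, b)$p_value, mwExactOracle(a, b))
})

test_that("Mann-Whitney is symmetric and null on identical groups", {
  set.seed(7)
  a <- rlnorm(40); b <- rlnorm(35)
  expect_equal(mannWhitney(a, b)$p_value, mannWhitney(b, a)$p_value)
  expect_gte(mannWhitney(a, a)$p_value, 0.99)
  expect_error(mannWhitney(numeric(0), a), "empty")
})

test_that("Kruskal-Wallis degenerates correctly and matches MW on two groups", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- kruskalWallis(g)
  expect_equal(res$statistic, 0)
  expect_gte(res$p_value, 0.999)

  set.seed(8)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  kw <- kruskalWallis(list(a, b))
  mw <- mannWhitney(a, b)
  expect_equal(kw$p_value, mw$p_value, tolerance = 1e-12)  # H = z^2

  # permutation invariance to group order
  g3 <- list(a = rnorm(20), b = rnorm(25, 0.3), c = rnorm(15, -0.2))
  expect_equal(kruskalWallis(g3)$p_value,
               kruskalWallis(rev(g3))$p_value, tolerance = 1e-12)

  expect_error(kruskalWallis(list(a)), ">= 2 groups")
})

test_that("percentile cutoff follows the linear-interpolation convention", {
  expect_equal(percentileCutoff(0:100, 95), 95)
  expect_equal(suppressWarnings(percentileCutoff(rep(4.2, 10))), 4.2)
  expect_equal(percentileCutoff(1:101, 50), 51)  # median on a symmetric set
  expect_warning(percentileCutoff(1:10), "n < 20")
  expect_error(percentileCutoff(numeric(0)), "empty")
  expect_error(percentileCutoff(1:30, q = 0), "q must")
  # parametric variant: mean + 1.645 SD at q = 95
  x <- c(1, 2, 3, 4, 5)
  expect_equal(suppressWarnings(percentileCutoff(x, 95, "parametric")),
               mean(x) + qnorm(0.95) * sd(x))
})

test_that("exceedance uses strict comparisons and the 50% rule", {
  ref <- 1:100
  hi <- rep(200, 10)
  res <- exceedance(ref, hi)
  expect_equal(res$proportion_pct, 100)
  expect_true(res$strong_indicator)

  lo <- rep(min(ref), 10)   # at-or-below the cutoff never exceeds
  res2 <- exceedance(ref, lo)
  expect_equal(res2$n_exceeding, 0L)
  expect_false(res2$strong_indicator)

  atCut <- rep(percentileCutoff(ref), 5)
  expect_equal(exceedance(ref, atCut)$n_exceeding, 0L)

  below <- exceedance(ref, rep(0, 4), direction = "below")
  expect_equal(below$proportion_pct, 100)
  expect_error(exceedance(ref, numeric(0)), "empty test")
})

test_that("pooling conserves counts and provenance, and rejects collisions", {
  cfg <- tinyFieldConfig(seed = 61L)
  t1 <- generateDensityTable(cfg, 30, caseId = "case1")$table
  t2 <- generateDensityTable(tinyFieldConfig(seed = 62L), 20,
                             caseId = "case2")$table
  pooled <- poolTables(list(t1, t2))
  expect_identical(nrow(records(pooled)), 50L)
  expect_identical(poolTables(list(t1))@records, t1@records)

  # balanced average of group means
  m <- mean(c(records(t1)$density_pct, records(t2)$density_pct))
  expect_equal(mean(records(pooled)$density_pct), m)

  expect_error(poolTables(list(t1, t1)), "collision")
})

test_that("summaries report mean and SEM with the n = 1 convention", {
  s <- densitySummary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))
  expect_equal(densitySummary(rep(5, 8))$sem, 0)
  s1 <- densitySummary(4.2)
  expect_equal(s1$mean, 4.2)
  expect_true(is.na(s1$sem))
})

test_that("count percentages round half away from zero", {
  expect_identical(pctFromCounts(17, 85), 20L)
  expect_identical(pctFromCounts(3, 34), 9L)
  expect_identical(pctFromCounts(0, 50), 0L)
  expect_identical(pctFromCounts(1, 40), 3L)   # 2.5 rounds up, not to even
  expect_identical(pctFromCounts(c(1, 30), c(30, 30)), c(3L, 100L))
  expect_error(pctFromCounts(5, 0), "n must")
  expect_error(pctFromCounts(6, 5), "0 <= x <= n")
  expect_error(pctFromCounts(2.5, 10), "integers")
})

test_that("the full stats stage flags shifted oligodendrocytes, not neurons", {
  # inclusion-shifted oligodendrocytes (x1.5), unshifted neurons
  cfg <- synthFieldConfig(
    cellsPerType = c(neuron = 300L, oligodendrocyte = 300L),
    nucleusRadiusUm = c(neuron = 5, oligodendrocyte = 3),
    cellRadiusUm = c(neuron = 10, oligodendrocyte = 5),
    densityLaw = list(
      neuron = list(noninclusion = lognormalFromMean(7.2, 0.8),
                    inclusion = lognormalFromMean(7.2, 0.8)),
      oligodendrocyte = list(noninclusion = lognormalFromMean(3.1, 0.8),
                             inclusion = lognormalFromMean(3.1 * 1.5, 0.8))),
    inclusionFraction = c(neuron = 0.5, oligodendrocyte = 0.5),
    seed = 71L)
  tab <- generateDensityTable(cfg, 1200)$table
  rep <- runDensityStats(tab)
  cmp <- rep$comparisons[rep$comparisons$region == "pooled", ]
  pOligo <- cmp$p_value[cmp$cell_type == "oligodendrocyte"]
  pNeuron <- cmp$p_value[cmp$cell_type == "neuron"]
  expect_lt(pOligo, 0.01)
  expect_gt(pNeuron, 0.05)
  ex <- rep$exceedance
  exOligo <- ex[ex$cell_type == "oligodendrocyte" & ex$region == "pooled" &
                  ex$direction == "above", ]
  exNeuron <- ex[ex$cell_type == "neuron" & ex$region == "pooled" &
                   ex$direction == "above", ]
  expect_gt(exOligo$proportion_pct, exNeuron$proportion_pct)
})
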