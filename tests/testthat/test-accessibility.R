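# Size factors, dispersion, the conditional exact NB test, independent
# filtering and its diagnostics.

test_that("size factors are median-of-ratios and scale-equivariant", {
  m <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # hand oracle: ratios to the row geometric means
  geo <- sqrt(m2[, 1] * m2[, 2])
  expect_equal(unname(sf), c(median(m2[, 1] / geo), median(m2[, 2] / geo)))

  set.seed(4)
  m3 <- matrix(rpois(300, 30) + 1, ncol = 3)
  sf3 <- size_factors(m3)
  m3c <- m3; m3c[, 2] <- m3c[, 2] * 5
  # scaling one sample scales its factor relative to the others exactly
  # (the overall scale is pinned to the geometric-mean reference)
  expect_equal(size_factors(m3c)[2] / size_factors(m3c)[1],
               5 * sf3[2] / sf3[1])

  expect_error(size_factors(cbind(c(0, 1), c(1, 0))),
               class = "citfoot_degenerate_error")
  # cross-check against the field-standard implementation
  expect_equal(unname(size_factors(m3)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m3)),
               tolerance = 1e-10)
})

test_that("dispersion estimation recovers alpha and degenerates sensibly", {
  g <- gen_counts(n_regions = 2000, alpha = 0.2, seed = 5)
  d <- estimate_dispersion(g$counts)
  expect_gte(median(d), 0.1)
  expect_lte(median(d), 0.3)

  gp <- gen_counts(n_regions = 2000, alpha = 0, seed = 5)
  dp <- estimate_dispersion(gp$counts)
  expect_lt(median(dp), 0.02)

  const <- count_matrix(matrix(7L, nrow = 5, ncol = 4), rep(c("A", "B"), each = 2))
  expect_equal(as.numeric(estimate_dispersion(const)), rep(0, 5))

  # 1-vs-1 falls back to a pooled estimate, one value for all regions
  g11 <- gen_counts(n_regions = 500, n_rep = 1, alpha = 0.2, seed = 6)
  d11 <- estimate_dispersion(g11$counts)
  expect_equal(length(unique(d11)), 1L)
  expect_gt(d11[1], 0)
})

test_that("the exact NB test is p = 1 at the modal split and powerful at 10x", {
  r <- nb_test(k_a = c(10, 10), k_b = c(10, 10), sf_a = c(1, 1),
               sf_b = c(1, 1), alpha = 0.1)
  expect_equal(r$pval, 1)
  expect_equal(r$log2fc, 0)

  r0 <- nb_test(k_a = c(0, 0), k_b = c(0, 0), sf_a = c(1, 1),
                sf_b = c(1, 1), alpha = 0.1)
  expect_equal(r0$pval, 1)
  expect_equal(r0$log2fc, 0)

  r10 <- nb_test(k_a = c(50, 55), k_b = c(500, 520), sf_a = c(1, 1),
                 sf_b = c(1, 1), alpha = 0.01)
  expect_lt(r10$pval, 1e-4)
  expect_gt(r10$log2fc, 3)
})

test_that("the normal fallback approximates the exact tail", {
  for (ka in list(c(100, 120), c(60, 80))) {
    ex <- nb_test(ka, c(180, 200), rep(1, 2), rep(1, 2), alpha = 0.05)
    ap <- nb_test(ka, c(180, 200), rep(1, 2), rep(1, 2), alpha = 0.05,
                  exact_cutoff = 10)
    expect_lt(abs(ex$pval - ap$pval), 0.03)
  }
})

test_that("type-I error under the NB null is near nominal", {
  g <- gen_counts(n_regions = 1000, alpha = 0.2, pi_alt = 0, seed = 17)
  res <- nb_test_all(g$counts)
  t1 <- mean(res$pval <= 0.05)
  expect_gt(t1, 0.02)
  expect_lt(t1, 0.08)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "citfoot_validation_error")
  set.seed(8)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("independent filtering retains the top fraction with ties kept", {
  res <- structure(data.frame(region = letters[1:10], total_count = 10:1,
                              base_mean_a = 1, base_mean_b = 1, log2fc = 0,
                              pval = runif(10)),
                   class = c("differential_result", "data.frame"))
  f <- independent_filter(res, 0.5)
  expect_equal(sum(!f$filtered), 5L)
  expect_equal(res$region[!f$filtered], letters[1:5])
  expect_true(all(is.na(f$qval[f$filtered])))
  expect_equal(f$qval[!f$filtered], bh_adjust(f$pval[!f$filtered]))

  f0 <- independent_filter(res, 0)
  expect_equal(sum(!f0$filtered), 10L)

  res$total_count <- c(10, 9, 8, 7, 6, 6, 6, 3, 2, 1)
  ft <- independent_filter(res, 0.5)
  expect_equal(sum(!ft$filtered), 7L)  # ties at the boundary all retained
})

test_that("the power scan is monotone in FDR and near-zero under the null", {
  g <- gen_counts(n_regions = 800, alpha = 0.2, pi_alt = 0, seed = 30)
  res <- nb_test_all(g$counts)
  scan <- filter_power_scan(res)
  expect_lte(max(scan$rejections), 3)

  ga <- gen_counts(n_regions = 800, alpha = 0.2, pi_alt = 0.05, fold = 6,
                   seed = 31)
  resa <- nb_test_all(ga$counts)
  scana <- filter_power_scan(resa)
  for (f in unique(scana$filter_fraction)) {
    rj <- scana$rejections[scana$filter_fraction == f]
    expect_true(all(diff(rj[order(scana$fdr[scana$filter_fraction == f])]) >= 0))
  }
})

test_that("the independence diagnostic conserves counts and flags abuse", {
  g <- gen_counts(n_regions = 1000, alpha = 0.2, seed = 40)
  res <- independent_filter(nb_test_all(g$counts), 0.5)
  di <- independence_diagnostic(res)
  expect_equal(sum(di$histograms$all), 1000)
  expect_equal(sum(di$histograms$filtered) + sum(di$histograms$retained), 1000)

  # count-independent filter on uniform p-values: KS stays small
  set.seed(41)
  nul <- structure(data.frame(region = as.character(1:5000),
                              total_count = sample(5000), base_mean_a = 1,
                              base_mean_b = 1, log2fc = 0, pval = runif(5000)),
                   class = c("differential_result", "data.frame"))
  din <- independence_diagnostic(independent_filter(nul, 0.5))
  expect_lt(din$ks_statistic, 0.05)

  # adversarial: filtering on the p-value itself depletes the retained
  # histogram near 1
  adv <- nul
  adv$total_count <- rank(-adv$pval)  # low "counts" = high p
  dia <- independence_diagnostic(independent_filter(adv, 0.5))
  tail_bin <- nrow(dia$histograms)
  expect_equal(dia$histograms$retained[tail_bin], 0L)
  expect_gt(dia$ks_statistic, 0.4)
})
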