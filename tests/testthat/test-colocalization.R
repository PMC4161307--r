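# Overlap fractions, summit correlation, composite profiles, sharpness.

test_that("overlap fraction matches a brute-force all-pairs oracle", {
  q <- scored_peaks("chr1", c(0, 100, 300, 900), c(50, 220, 400, 950))
  s <- scored_peaks("chr1", c(40, 210, 390), c(60, 215, 420))
  # brute force: peak 1 hits (40<50), 2 hits (210<220), 3 hits (390<400), 4 misses
  expect_equal(overlap_fraction(q, s)$fraction, 0.75)

  expect_equal(overlap_fraction(q, q)$fraction, 1)
  s2 <- scored_peaks("chrX", c(0, 100), c(50, 200))
  expect_equal(overlap_fraction(q, s2)$fraction, 0)
  expect_error(overlap_fraction(empty_q <- scored_peaks(character(), numeric(), numeric()), s),
               class = "citfoot_degenerate_error")

  set.seed(3)
  for (i in 1:10) {
    q <- random_peaks(40, span = 5e4)
    s <- random_peaks(30, span = 5e4)
    brute <- mean(vapply(seq_len(nrow(q)), function(i) {
      any(q$chrom[i] == s$chrom & q$start[i] < s$end & s$start < q$end[i])
    }, logical(1)))
    expect_equal(overlap_fraction(q, s)$fraction, brute)
    # monotone non-decreasing as the subject grows
    expect_gte(overlap_fraction(q, rbind(s, random_peaks(10, span = 5e4)))$fraction,
               overlap_fraction(q, s)$fraction)
  }
})

test_that("summit overlap mode counts summits inside subject intervals", {
  q <- scored_peaks("chr1", c(0, 100), c(60, 200))          # summits 30, 150
  s <- scored_peaks("chr1", c(25, 155), c(35, 165))
  expect_equal(overlap_fraction(q, s, mode = "summit")$fraction, 0.5)
  expect_equal(overlap_fraction(q, s, mode = "interval")$fraction, 1)
})

test_that("summit correlation is the product-moment coefficient", {
  x <- 1:10
  expect_equal(summit_correlation(x, 2 * x), 1)
  expect_equal(summit_correlation(x, -x), -1)
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 6)
  # direct closed form on the 5 pairs
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(summit_correlation(a, b), r_oracle)
  expect_error(summit_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "citfoot_degenerate_error")
  expect_error(summit_correlation(c(1, 2), c(1, 2)),
               class = "citfoot_degenerate_error")
})

test_that("composite profiles average signal around summits", {
  # single delta of height 8 at the summit
  tr <- coverage_track("chr1", 5000, 5001, 8)
  pr <- composite_profile(tr, "chr1", 5000, window = 100, step = 20)
  expect_equal(nrow(pr), 2 * 100 / 20 + 1)
  expect_equal(pr$value[pr$offset == 0], 8)
  expect_equal(sum(pr$value != 0), 1L)

  # two summits over deltas of heights 4 and 6 -> center mean 5
  tr2 <- coverage_track("chr1", c(1000, 3000), c(1001, 3001), c(4, 6))
  pr2 <- composite_profile(tr2, "chr1", c(1000, 3000), window = 40, step = 20)
  expect_equal(pr2$value[pr2$offset == 0], 5)

  # symmetric triangular coverage -> symmetric profile
  pk <- scored_peaks("chr1", c(900, 4900), c(1100, 5100), score = c(3, 7),
                     summit = c(1000, 5000))
  tr3 <- gen_coverage(pk, shape = "triangular", sigma = 100,
                      round_values = FALSE)
  pr3 <- composite_profile(tr3, "chr1", pk$summit, window = 200, step = 20)
  expect_equal(pr3$value, rev(pr3$value))
})

test_that("composite profile of i.i.d. noise flattens as summits grow", {
  set.seed(9)
  steps <- 20000
  tr <- coverage_track("chr1", seq(0, by = 10, length.out = steps),
                       seq(10, by = 10, length.out = steps),
                       pmax(0, rnorm(steps, 5, 1)))
  pr_small <- composite_profile(tr, "chr1", sample(5000:150000, 20),
                                window = 500, step = 50)
  pr_big <- composite_profile(tr, "chr1", sample(5000:150000, 500),
                              window = 500, step = 50)
  expect_lt(sd(pr_big$value), sd(pr_small$value))
  expect_lt(abs(mean(pr_big$value) - 5), 0.5)
})

test_that("distance to quarter max handles triangle, plateau and Gaussian", {
  pk <- scored_peaks("chr1", 9000, 11000, score = 100, summit = 10000)
  tri <- gen_coverage(pk, shape = "triangular", sigma = 100,
                      round_values = FALSE)
  r <- distance_to_quarter_max(tri, "chr1", 10000)
  expect_equal(r$distance, 75)   # linear flank: 25% of max at exactly 75 bp
  expect_false(r$censored)

  flat <- coverage_track("chr1", 8000, 12001, 100)
  rf <- distance_to_quarter_max(flat, "chr1", 10000, window = 1000)
  expect_true(rf$censored)
  expect_equal(rf$distance, 1000)

  gauss <- gen_coverage(pk, shape = "gaussian", sigma = 60,
                        round_values = FALSE)
  # brute-force scan of the analytic curve
  d_oracle <- which(exp(-(1:1000)^2 / (2 * 60^2)) <= 0.25)[1]
  expect_equal(distance_to_quarter_max(gauss, "chr1", 10000)$distance,
               d_oracle)

  empty <- coverage_track("chr1", 0, 10, 1)
  expect_error(distance_to_quarter_max(empty, "chr1", 5000),
               class = "citfoot_degenerate_error")
})

test_that("one-sided sharpness is never larger than two-sided", {
  # asymmetric peak: sharp left flank, long right shoulder
  tr <- coverage_track("chr1", c(980, 1000, 1001, 1500), c(1000, 1001, 1500, 2000),
                       c(10, 100, 60, 10))
  both <- distance_to_quarter_max(tr, "chr1", 1000, window = 1500)
  either <- distance_to_quarter_max(tr, "chr1", 1000, window = 1500,
                                    sides = "either")
  expect_lte(either$distance, both$distance)
})

test_that("sharpness CDF handles censoring and normalizes", {
  cdf <- sharpness_cdf(c(50, 100, 300, 400), at = 200)
  expect_equal(unname(cdf$at), 0.5)
  expect_equal(cdf$cdf(400), 1)
  all_cens <- sharpness_cdf(rep(1000, 5), at = 200)
  expect_equal(unname(all_cens$at), 0)
})

test_that("narrower kernels give stochastically smaller sharpness distances", {
  set.seed(21)
  pk <- random_peaks(40, chroms = "chr1", span = 1e6)
  pk$score <- runif(40, 50, 150)
  frac200 <- vapply(c(30, 100, 300), function(sig) {
    tr <- gen_coverage(pk, shape = "gaussian", sigma = sig,
                       round_values = FALSE)
    sh <- sharpness(tr, pk, window = 1000)
    unname(sharpness_cdf(sh, at = 200)$at)
  }, numeric(1))
  expect_true(all(diff(frac200) <= 0))
})
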