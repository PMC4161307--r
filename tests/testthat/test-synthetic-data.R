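# Generator determinism, limits, and ground-truth bookkeeping.

test_that("generators are seed-deterministic and leave the RNG untouched", {
  set.seed(123); before <- .Random.seed
  a <- gen_coupled_cistrome(n_a = 100, seed = 7)
  expect_identical(.Random.seed, before)
  b <- gen_coupled_cistrome(n_a = 100, seed = 7)
  expect_identical(a, b)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_peaks(a$peaks_a, f1, "macs-summit")
  write_peaks(b$peaks_a, f2, "macs-summit")
  expect_identical(readLines(f1), readLines(f2))

  expect_identical(gen_fragments(n = 500, seed = 3),
                   gen_fragments(n = 500, seed = 3))
  expect_identical(gen_counts(n_regions = 50, seed = 3),
                   gen_counts(n_regions = 50, seed = 3))
  expect_identical(gen_cohort(n_patients = 30, seed = 3),
                   gen_cohort(n_patients = 30, seed = 3))
  expect_identical(gen_timecourse(seed = 3)$matrix,
                   gen_timecourse(seed = 3)$matrix)
})

test_that("the zero-noise coupled cistrome is perfectly concordant", {
  g <- gen_coupled_cistrome(n_a = 200, noise_sd = 0, a_only_frac = 0,
                            b_only_frac = 0, summit_jitter_sd = 0, seed = 2)
  expect_equal(summit_correlation(g$truth$intensity_a, g$truth$intensity_b), 1)
  expect_equal(overlap_fraction(g$peaks_a, g$peaks_b)$fraction, 1)
  expect_equal(overlap_fraction(g$peaks_b, g$peaks_a)$fraction, 1)
})

test_that("cistrome fractions control the overlap structure", {
  g <- gen_coupled_cistrome(n_a = 1000, a_only_frac = 0.05,
                            b_only_frac = 0.53, seed = 4)
  expect_equal(overlap_fraction(g$peaks_a, g$peaks_b)$fraction, 0.95,
               tolerance = 0.01)
  expect_equal(overlap_fraction(g$peaks_b, g$peaks_a)$fraction, 0.47,
               tolerance = 0.01)
  expect_error(gen_coupled_cistrome(n_a = 1e6, seed = 1),
               class = "citfoot_validation_error")
})

test_that("generated files parse cleanly through the io layer", {
  g <- gen_coupled_cistrome(n_a = 50, seed = 5)
  f <- withr::local_tempfile()
  expect_no_warning({
    write_peaks(g$peaks_a, f, "macs-summit")
    p <- read_peaks(f, "macs-summit")
  })
  expect_equal(nrow(p), 50L)

  fr <- gen_fragments(n = 200, seed = 5)
  expect_no_warning({
    write_fragments(fr, f)
    fr2 <- read_fragments(f)
  })
  expect_equal(fr2$length, fr$length)

  tr <- gen_coverage(g$peaks_a[1:5, ], sigma = 50)
  expect_no_warning({
    write_coverage(tr, f)
    tr2 <- read_coverage(f)
  })
  expect_equal(as.data.frame(tr2), as.data.frame(tr))
})

test_that("coverage kernels scale with depth and vanish beyond 5 sigma", {
  pk <- scored_peaks("chr1", 9000, 11000, score = 100, summit = 10000)
  tr1 <- gen_coverage(pk, sigma = 60, depth = 1, round_values = FALSE)
  tr2 <- gen_coverage(pk, sigma = 60, depth = 2, round_values = FALSE)
  expect_equal(coverage_value(tr2, "chr1", 10000),
               2 * coverage_value(tr1, "chr1", 10000))
  expect_equal(coverage_value(tr1, "chr1", 10000 + 5 * 60 + 10), 0)
  expect_equal(coverage_value(tr1, "chr1", 10000), 100)
})

test_that("zero-noise time courses recover their classes exactly", {
  g <- gen_timecourse(n_per_class = c(early = 20, late = 20),
                      class_peak_time = c(early = 5, late = 40),
                      noise_sd = 1e-6, seed = 8)
  cl <- cluster_timecourses(g$matrix, k = 2)
  expect_equal(mclust::adjustedRandIndex(cl$labels, g$labels), 1)
})

test_that("fragment lengths respect the truncation bounds", {
  fr <- gen_fragments(n = 20000,
                      components = data.frame(mean = c(10, 480),
                                              sd = c(30, 30),
                                              weight = c(0.5, 0.5)),
                      seed = 6)
  expect_true(all(fr$length > 1 & fr$length < 500))
  expect_error(gen_fragments(components = data.frame(mean = 100, sd = 10,
                                                     weight = 0.4)),
               class = "citfoot_validation_error")
})

test_that("count generation honors library-size multipliers and truth flags", {
  g <- gen_counts(n_regions = 3000, libsize_mult = c(1, 1, 2, 1), seed = 9)
  cs <- colSums(g$counts$counts)
  expect_equal(unname(cs[3] / cs[1]), 2, tolerance = 0.1)
  expect_false(any(g$is_alt))

  ga <- gen_counts(n_regions = 2000, pi_alt = 0.05, fold = 4, seed = 10)
  expect_equal(mean(ga$is_alt), 0.05, tolerance = 0.35)
  # alternative regions really are shifted in condition B
  m <- sweep(ga$counts$counts, 2, size_factors(ga$counts), "/")
  lfc <- log2((rowMeans(m[, 3:4]) + 1) / (rowMeans(m[, 1:2]) + 1))
  expect_gt(mean(lfc[ga$is_alt]), mean(lfc[!ga$is_alt]) + 1)
})

test_that("perfectly coupled cohorts give unit marker correlation", {
  g <- gen_cohort(n_patients = 25, latent_cor = 1, area_noise_sd = 0, seed = 11)
  sc <- score_sections(g$sections)
  expect_equal(marker_correlation(sc, "ER", "PAD2")$r, 1)
  # IgG control stays near zero staining
  expect_lt(mean(sc$score[sc$marker == "IgG"]), 0.6)
})

test_that("null cohorts give uniform-ish log-rank p-values", {
  ps <- vapply(1:40, function(s) {
    g <- gen_cohort(n_patients = 80, hazard_ratio = 1, seed = 100 + s)
    with(g$survival, logrank_test(time, event, expression > median(expression)))$pval
  }, numeric(1))
  expect_gt(mean(ps < 0.1), 0)
  expect_lt(mean(ps < 0.1), 0.3)
})
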