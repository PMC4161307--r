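## Differential DNase accessibility with independent filtering.
##
## Region x sample read counts are modeled as negative binomial
## (Var = mu + alpha * mu^2) with median-of-ratios size factors. Each region
## is tested with a conditional exact test on the per-condition count sums,
## low-total regions are removed by an independent filter before
## Benjamini-Hochberg correction, and the filter is accompanied by the
## power-scan and p-value/count independence diagnostics that justify it.

#' Construct a count matrix container
#'
#' @param counts non-negative integer matrix, regions x samples.
#' @param condition factor/character of length `ncol(counts)` with exactly
#'   two levels (e.g. pre/post treatment); the first level is condition A.
#' @param regions optional [scored_peaks]/interval table with one row per
#'   region.
#' @return a `count_matrix` list.
#' @export
count_matrix <- function(counts, condition, regions = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    cf_stop("counts must be non-negative integers",
            class = "citfoot_validation_error")
  }
  condition <- as.factor(condition)
  if (length(condition) != ncol(counts)) {
    cf_stop("condition must have one entry per sample",
            class = "citfoot_validation_error")
  }
  if (nlevels(condition) != 2L) {
    cf_stop("exactly two conditions are required",
            class = "citfoot_validation_error")
  }
  if (!is.null(regions) && nrow(regions) != nrow(counts)) {
    cf_stop("regions must have one row per count row",
            class = "citfoot_validation_error")
  }
  structure(list(counts = counts, condition = condition, regions = regions),
            class = "count_matrix")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over regions (positive in all samples) of
#' the ratio of its count to the row geometric mean.
#'
#' @param counts a `count_matrix` or plain counts matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  allpos <- rowSums(m <= 0) == 0L
  if (!any(allpos)) {
    cf_stop("no region has positive counts in every sample",
            class = "citfoot_degenerate_error")
  }
  lg <- log(m[allpos, , drop = FALSE])
  loggeo <- rowMeans(lg)
  apply(lg, 2L, function(x) exp(stats::median(x - loggeo)))
}

#' Per-region NB dispersion estimates
#'
#' Computes per-region method-of-moments dispersions on
#' size-factor-normalized counts (floored at 0) and a mean-dispersion trend
#' `alpha(mu) = a0 + a1 / mu` fitted by Cox-Reid adjusted NB maximum
#' likelihood across all regions (the adjustment compensates for the
#' per-condition means being estimated from the same few samples). The
#' returned dispersion is the weighted average
#' `shrink_weight * trend + (1 - shrink_weight) * raw`. At the small
#' replicate numbers typical of these designs the per-region estimates
#' carry almost no information and their noise makes the downstream test
#' anti-conservative, so the default is full moderation
#' (`shrink_weight = 1`, i.e. every region uses the fitted trend); the raw
#' estimates remain available via the `"raw"` attribute.
#'
#' With a single sample per condition no within-condition variance exists,
#' so a single pooled dispersion (median of per-region null-difference
#' moment estimates) is used for all regions.
#'
#' @param counts a `count_matrix`.
#' @param factors size factors (default [size_factors]).
#' @param shrink_weight weight on the fitted trend in `[0, 1]` (default 1).
#' @return numeric vector of dispersions `alpha >= 0`, one per region, with
#'   attributes `"raw"` (per-region moment estimates) and `"trend_coef"`
#'   (`a0`, `a1`).
#' @export
estimate_dispersion <- function(counts, factors = size_factors(counts),
                                shrink_weight = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  cond <- counts$condition
  norm <- sweep(m, 2L, factors, "/")
  z <- mean(1 / factors)  # E[Var(K/s)] = mu * mean(1/s) + alpha * mu^2
  if (min(table(cond)) < 2L) {
    # 1 vs 1: pooled blind estimate across regions from the pair difference
    x <- norm[, 1L]; y <- norm[, 2L]
    s <- x + y
    keep <- s > 0
    mu <- s[keep] / 2
    # E[(x - y)^2] ~= mu * (1/f1 + 1/f2) + 2 * alpha * mu^2 under the null
    num <- (x - y)[keep]^2 - mu * sum(1 / factors)
    a <- stats::median(num / (2 * mu^2))
    return(rep(max(0, a), nrow(m)))
  }
  mu <- rowMeans(norm)
  lv <- levels(cond)
  # pooled within-condition variance, so true fold-changes do not inflate alpha
  ss <- rowSums(sapply(lv, function(l) {
    x <- norm[, cond == l, drop = FALSE]
    rowSums((x - rowMeans(x))^2)
  }))
  v <- ss / (ncol(m) - length(lv))
  raw <- ifelse(mu > 0, pmax(0, (v - mu * z) / mu^2), 0)
  if (all(v == 0)) {
    out <- rep(0, nrow(m))
    attr(out, "raw") <- raw
    attr(out, "trend_coef") <- c(a0 = 0, a1 = 0)
    return(out)
  }
  co <- fit_dispersion_trend(m, cond, factors, mu)
  trend <- co[["a0"]] + co[["a1"]] / pmax(mu, 0.1)
  out <- pmax(0, shrink_weight * trend + (1 - shrink_weight) * raw)
  attr(out, "raw") <- raw
  attr(out, "trend_coef") <- co
  out
}

#' Cox-Reid adjusted ML fit of the mean-dispersion trend
#' @noRd
fit_dispersion_trend <- function(m, cond, factors, mu_row) {
  norm <- sweep(m, 2L, factors, "/")
  lv <- levels(cond)
  muhat <- matrix(0, nrow(m), ncol(m))
  for (l in lv) {
    j <- which(cond == l)
    muhat[, j] <- rowMeans(norm[, j, drop = FALSE])
  }
  mu_sf <- sweep(muhat, 2L, factors, "*")  # fitted raw-scale means
  use <- mu_row > 0
  ga <- as.integer(cond)
  nll <- function(par) {
    a0 <- exp(par[1L]); a1 <- exp(par[2L])
    a <- a0 + a1 / pmax(mu_row, 0.1)
    size <- matrix(1 / a, nrow(m), ncol(m))
    ok <- use & mu_sf > 0
    ll <- sum(stats::dnbinom(m[ok], mu = mu_sf[ok], size = size[ok],
                             log = TRUE))
    # Cox-Reid: -0.5 log det(X'WX); the design is group means, so the
    # determinant factorizes over conditions
    w <- mu_sf / (1 + a * mu_sf)
    sw <- t(rowsum(t(w[use, , drop = FALSE]), ga))
    -(ll - sum(0.5 * log(sw[sw > 0])))
  }
  op <- stats::optim(c(log(0.1), log(0.01)), nll)
  c(a0 = exp(op$par[1L]), a1 = exp(op$par[2L]))
}

#' Conditional exact NB test for one region
#'
#' Tests equality of condition means by conditioning on the total count
#' `S = K_A + K_B` of the two per-condition sums: the p-value is the
#' probability, under the null NB model, of all splits of `S` as likely or
#' less likely than the observed one. Above `exact_cutoff` total counts a
#' normal approximation to the conditional law is used.
#'
#' @param k_a,k_b raw counts for the region in condition A / B samples.
#' @param sf_a,sf_b matching size factors.
#' @param alpha NB dispersion for the region.
#' @param exact_cutoff switch to the normal approximation when
#'   `sum(k_a) + sum(k_b)` exceeds this (default 1e5).
#' @return a list: `pval` (two-sided), `log2fc` (B over A, on normalized
#'   means), `base_mean_a`, `base_mean_b`.
#' @export
nb_test <- function(k_a, k_b, sf_a, sf_b, alpha, exact_cutoff = 1e5) {
  ka <- sum(k_a); kb <- sum(k_b); s <- ka + kb
  mean_a <- mean(k_a / sf_a); mean_b <- mean(k_b / sf_b)
  log2fc <- if (mean_a == 0 && mean_b == 0) 0 else log2(mean_b / mean_a)
  if (s == 0) {
    return(list(pval = 1, log2fc = 0, base_mean_a = 0, base_mean_b = 0))
  }
  q <- s / (sum(sf_a) + sum(sf_b))  # pooled per-unit-size-factor mean
  mu_a <- q * sum(sf_a); mu_b <- q * sum(sf_b)
  var_a <- q * sum(sf_a) + alpha * q^2 * sum(sf_a^2)
  var_b <- q * sum(sf_b) + alpha * q^2 * sum(sf_b^2)
  if (s > exact_cutoff) {
    # KA | S approx normal with conditional moments
    mu_c <- mu_a + var_a / (var_a + var_b) * (s - mu_a - mu_b)
    sd_c <- sqrt(var_a * var_b / (var_a + var_b))
    p <- min(1, 2 * stats::pnorm(-abs(ka - mu_c) / sd_c))
    return(list(pval = p, log2fc = log2fc,
                base_mean_a = mean_a, base_mean_b = mean_b))
  }
  lp <- function(x, mu, v) {
    if (v > mu) {
      stats::dnbinom(x, mu = mu, size = mu^2 / (v - mu), log = TRUE)
    } else {
      stats::dpois(x, lambda = mu, log = TRUE)
    }
  }
  a <- 0:s
  logp <- lp(a, mu_a, var_a) + lp(s - a, mu_b, var_b)
  obs <- logp[ka + 1L]
  denom <- logsumexp(logp)
  num <- logsumexp(logp[logp <= obs + 1e-12])
  list(pval = min(1, exp(num - denom)), log2fc = log2fc,
       base_mean_a = mean_a, base_mean_b = mean_b)
}

#' Differential accessibility over all regions
#'
#' Runs [nb_test] per region and assembles the result table used by the
#' filtering and diagnostic functions. No multiple-testing correction is
#' applied here; see [independent_filter].
#'
#' @param counts a `count_matrix`.
#' @param factors size factors (default [size_factors]).
#' @param dispersions per-region dispersions (default
#'   [estimate_dispersion]).
#' @param exact_cutoff passed to [nb_test].
#' @return a `differential_result` data.frame with columns `region`,
#'   `total_count`, `base_mean_a`, `base_mean_b`, `log2fc`, `pval` (and
#'   `qval`/`filtered` once [independent_filter] has run).
#' @export
nb_test_all <- function(counts, factors = size_factors(counts),
                        dispersions = estimate_dispersion(counts, factors),
                        exact_cutoff = 1e5) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  cond <- counts$condition
  ia <- which(cond == levels(cond)[1L])
  ib <- which(cond == levels(cond)[2L])
  res <- lapply(seq_len(nrow(m)), function(i) {
    nb_test(m[i, ia], m[i, ib], factors[ia], factors[ib], dispersions[i],
            exact_cutoff = exact_cutoff)
  })
  out <- data.frame(
    region = if (!is.null(counts$regions)) counts$regions$name else
      sprintf("region_%d", seq_len(nrow(m))),
    total_count = rowSums(m),
    base_mean_a = vapply(res, `[[`, 0, "base_mean_a"),
    base_mean_b = vapply(res, `[[`, 0, "base_mean_b"),
    log2fc = vapply(res, `[[`, 0, "log2fc"),
    pval = vapply(res, `[[`, 0, "pval")
  )
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement (thin validated wrapper around
#' [stats::p.adjust]).
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    cf_stop("p-values must lie in [0, 1]", class = "citfoot_validation_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Independent filtering before multiple-testing correction
#'
#' Regions are ranked by total raw count across all samples — a statistic
#' independent of the test statistic under the null — and the bottom
#' fraction `f` is flagged `filtered`; BH correction is then applied to the
#' retained regions only. Regions tied with the smallest retained total are
#' all retained. Filtered regions carry `qval = NA`.
#'
#' @param result a `differential_result` from [nb_test_all].
#' @param filter_fraction fraction `0 <= f < 1` of regions to remove.
#' @return the result with `filtered` and `qval` columns.
#' @export
independent_filter <- function(result, filter_fraction = 0.5) {
  if (filter_fraction < 0 || filter_fraction >= 1) {
    cf_stop("filter_fraction must lie in [0, 1)",
            class = "citfoot_validation_error")
  }
  n <- nrow(result)
  n_keep <- ceiling((1 - filter_fraction) * n)
  thr <- sort(result$total_count, decreasing = TRUE)[n_keep]
  keep <- result$total_count >= thr
  result$filtered <- !keep
  result$qval <- NA_real_
  result$qval[keep] <- bh_adjust(result$pval[keep])
  result
}

#' Power scan over filter fractions and FDR thresholds
#'
#' Number of BH rejections for every combination of filter fraction and FDR
#' threshold; reproduces the "power versus pre-filter threshold" curve used
#' to choose the filter fraction.
#'
#' @param result a `differential_result` (p-values computed).
#' @param fractions filter fractions to scan (default 0.30-0.70 by 0.10).
#' @param fdr_levels FDR thresholds (default 0.05, 0.10, 0.15, 0.20).
#' @return a data.frame with columns `filter_fraction`, `fdr`, `rejections`.
#' @export
filter_power_scan <- function(result,
                              fractions = seq(0.30, 0.70, by = 0.10),
                              fdr_levels = c(0.05, 0.10, 0.15, 0.20)) {
  grid <- expand.grid(filter_fraction = fractions, fdr = fdr_levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid$rejections <- vapply(seq_len(nrow(grid)), function(i) {
    r <- independent_filter(result, grid$filter_fraction[i])
    sum(r$qval <= grid$fdr[i], na.rm = TRUE)
  }, integer(1))
  grid
}

#' Independence diagnostic for the filter statistic
#'
#' Histograms of unadjusted p-values for all, filtered, and retained
#' regions, plus a two-sample Kolmogorov-Smirnov statistic between the
#' "all" and "retained" p-value distributions. If the filter statistic is
#' independent of the p-value under the null, filtering shifts no mass and
#' the KS statistic is small. Reported for inspection, not as a gate.
#'
#' @param result a filtered `differential_result` (after
#'   [independent_filter]).
#' @param breaks histogram breaks over `[0, 1]` (default 20 equal bins).
#' @return a list: `histograms` (data.frame `bin_lo`, `bin_hi`, `all`,
#'   `filtered`, `retained`), `ks_statistic`, `counts`.
#' @export
independence_diagnostic <- function(result, breaks = seq(0, 1, by = 0.05)) {
  if (is.null(result$filtered)) {
    cf_stop("run independent_filter() before the diagnostic",
            class = "citfoot_validation_error")
  }
  h <- function(p) graphics::hist(p, breaks = breaks, plot = FALSE)$counts
  all_p <- result$pval
  ret_p <- result$pval[!result$filtered]
  fil_p <- result$pval[result$filtered]
  ks <- if (length(ret_p) > 0L) {
    suppressWarnings(stats::ks.test(all_p, ret_p)$statistic)
  } else NA_real_
  list(
    histograms = data.frame(
      bin_lo = utils::head(breaks, -1L), bin_hi = breaks[-1L],
      all = h(all_p),
      filtered = if (length(fil_p)) h(fil_p) else 0L,
      retained = if (length(ret_p)) h(ret_p) else 0L
    ),
    ks_statistic = unname(ks),
    counts = c(all = length(all_p), filtered = length(fil_p),
               retained = length(ret_p))
  )
}
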