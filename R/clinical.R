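## Clinical endpoints: weighted IHC scoring and survival analysis.
##
## Tumor-section DAB staining is graded 0-5 per tumor-cell fraction and
## aggregated to a weighted final score per section area; marker pairs are
## compared by Pearson correlation over matched areas. Survival analysis is
## Kaplan-Meier with a two-group log-rank test, and an expression-threshold
## scan that picks the quantile cutoff minimizing the log-rank p-value —
## with an explicit multiplicity flag, since a scan-minimized p-value is
## optimistically biased.

#' Weighted immunohistochemistry final score
#'
#' `sum(level * fraction(level))` over stain levels 0-5, where `fraction`
#' gives the fraction of tumor cells at each level.
#'
#' @param fractions numeric vector of cell fractions; names are stain
#'   levels (`"0"`..`"5"`). An unnamed length-6 vector is taken as levels
#'   0-5 in order. Must sum to 1 (tolerance 1e-6).
#' @return the weighted score in `[0, 5]`.
#' @export
final_score <- function(fractions) {
  if (is.null(names(fractions))) {
    if (length(fractions) != 6L) {
      cf_stop("unnamed fractions must have length 6 (levels 0-5)",
              class = "citfoot_validation_error")
    }
    names(fractions) <- 0:5
  }
  lev <- suppressWarnings(as.numeric(names(fractions)))
  if (anyNA(lev) || any(lev < 0 | lev > 5)) {
    cf_stop("fraction names must be stain levels 0-5",
            class = "citfoot_validation_error")
  }
  if (abs(sum(fractions) - 1) > 1e-6) {
    cf_stop(sprintf("fractions must sum to 1 (got %.8f)", sum(fractions)),
            class = "citfoot_validation_error")
  }
  sum(lev * fractions)
}

#' Score an IHC section table
#'
#' @param sections data.frame with columns `patient`, `marker`, `area`, and
#'   fraction columns `f0`..`f5`.
#' @return the input with a `score` column ([final_score] per row).
#' @export
score_sections <- function(sections) {
  fcols <- paste0("f", 0:5)
  assert_columns(sections, c("patient", "marker", "area", fcols), "sections")
  sections$score <- vapply(seq_len(nrow(sections)), function(i) {
    final_score(stats::setNames(as.numeric(sections[i, fcols]), 0:5))
  }, numeric(1))
  sections
}

#' Pearson correlation between two markers' section scores
#'
#' Scores are matched on (patient, area); by default every area contributes
#' a point (`pool = "area"`), or areas can be averaged per patient first
#' (`pool = "patient"`).
#'
#' @param scored a scored section table (from [score_sections]).
#' @param marker_a,marker_b marker names to compare.
#' @param pool `"area"` (default) or `"patient"`.
#' @return a list: `r`, `n` (matched points).
#' @export
marker_correlation <- function(scored, marker_a, marker_b,
                               pool = c("area", "patient")) {
  pool <- match.arg(pool)
  a <- scored[scored$marker == marker_a, c("patient", "area", "score")]
  b <- scored[scored$marker == marker_b, c("patient", "area", "score")]
  m <- merge(a, b, by = c("patient", "area"), suffixes = c("_a", "_b"))
  if (pool == "patient") {
    m <- do.call(rbind, lapply(split(m, m$patient), function(d) {
      data.frame(score_a = mean(d$score_a), score_b = mean(d$score_b))
    }))
  }
  list(r = summit_correlation(m$score_a, m$score_b), n = nrow(m))
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param time follow-up times (> 0).
#' @param event logical/0-1 event indicator (TRUE = event, FALSE =
#'   censored).
#' @return a `km_curve` data.frame with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`; the underlying [survival::survfit]
#'   object is attached as attribute `"fit"`.
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0L) {
    cf_stop("km_curve needs at least one record",
            class = "citfoot_degenerate_error")
  }
  if (any(time <= 0)) {
    cf_stop("follow-up times must be positive",
            class = "citfoot_validation_error")
  }
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  attr(out, "fit") <- fit
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a KM curve at given times
#' @param curve a `km_curve`.
#' @param t times at which to evaluate `S(t)` (right-continuous).
#' @return numeric survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  steps <- curve[curve$n_event > 0L, , drop = FALSE]
  vapply(t, function(tt) {
    i <- which(steps$time <= tt)
    if (length(i) == 0L) 1 else steps$surv[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard (O-E)^2/V log-rank with hypergeometric variance at each event
#' time.
#'
#' @param time,event as in [km_curve].
#' @param group two-level grouping vector.
#' @return a list: `chisq`, `pval` (1 df), `n` per group, `obs`/`exp`
#'   event counts per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    cf_stop("logrank_test requires exactly two non-empty groups",
            class = "citfoot_validation_error")
  }
  if (sum(event) == 0L) {
    cf_stop("log-rank test undefined with zero events",
            class = "citfoot_degenerate_error")
  }
  sd <- tryCatch(
    survival::survdiff(survival::Surv(time, as.integer(event)) ~ group),
    error = function(e) NULL
  )
  if (is.null(sd)) {
    # degenerate risk tables (zero hypergeometric variance at every event
    # time) carry no information; then O = E exactly and the statistic is 0
    return(list(chisq = 0, pval = 1,
                n = as.vector(table(group)), obs = NA, exp = NA))
  }
  list(chisq = unname(sd$chisq),
       pval = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       n = as.vector(sd$n), obs = as.vector(sd$obs),
       exp = as.vector(sd$exp))
}

#' Scan expression quantiles for the best survival split
#'
#' Splits the cohort at each quantile of the expression values (ties at
#' the cutoff go to the "low" group), runs the log-rank test for every
#' split with both groups of size at least `min_group`, and reports the
#' quantile with the smallest p-value alongside the full scan table. The
#' minimized p-value is threshold-optimized and therefore optimistically
#' biased; the result carries an explicit `multiplicity_warning` and the
#' scan table so a correction can be applied.
#'
#' @param expression per-patient continuous marker level.
#' @param time,event as in [km_curve].
#' @param quantiles quantile grid (default 0.25-0.75 by 0.05).
#' @param min_group minimum patients on each side of a valid split
#'   (default 10).
#' @return a list: `best_quantile`, `best_cutoff`, `pval`, `chisq`,
#'   `groups` (logical, TRUE = high), `n_low`, `n_high`, `scan` (data.frame
#'   over the grid), `multiplicity_warning`.
#' @export
best_threshold_scan <- function(expression, time, event,
                                quantiles = seq(0.25, 0.75, by = 0.05),
                                min_group = 10) {
  stopifnot(length(expression) == length(time),
            length(time) == length(event))
  scan <- data.frame(quantile = quantiles,
                     cutoff = as.numeric(stats::quantile(expression, quantiles)),
                     n_low = NA_integer_, n_high = NA_integer_,
                     chisq = NA_real_, pval = NA_real_)
  for (i in seq_len(nrow(scan))) {
    high <- expression > scan$cutoff[i]   # ties at the cutoff -> low group
    scan$n_low[i] <- sum(!high); scan$n_high[i] <- sum(high)
    if (sum(high) < min_group || sum(!high) < min_group || sum(event) == 0L) {
      next
    }
    lr <- tryCatch(logrank_test(time, event, high),
                   citfoot_error = function(e) NULL)
    if (!is.null(lr)) {
      scan$chisq[i] <- lr$chisq
      scan$pval[i] <- lr$pval
    }
  }
  if (all(is.na(scan$pval))) {
    cf_stop("no valid split: expression constant or min_group unmet everywhere",
            class = "citfoot_degenerate_error")
  }
  best <- which.min(scan$pval)
  high <- expression > scan$cutoff[best]
  list(best_quantile = scan$quantile[best], best_cutoff = scan$cutoff[best],
       pval = scan$pval[best], chisq = scan$chisq[best], groups = high,
       n_low = scan$n_low[best], n_high = scan$n_high[best], scan = scan,
       multiplicity_warning = paste(
         "p-value minimized over an expression-threshold scan;",
         "it is not corrected for the multiplicity of thresholds tried"))
}
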