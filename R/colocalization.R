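## Cistrome colocalization and peak-shape statistics.
##
## Concordance between two peak sets (e.g. a transcription factor and a
## histone mark) is summarized as the fraction of query peaks intersecting
## subject peaks, the Pearson correlation of summit intensities at matched
## sites, composite (metapeak) profiles centered on summits, and a
## distance-to-quarter-max sharpness statistic that captures how discrete a
## mark's profile is.

#' Fraction of query peaks overlapping a subject peak set
#'
#' A query peak overlaps iff its interval shares at least one base with at
#' least one subject interval (half-open convention). Alternatively,
#' `mode = "summit"` counts a query peak iff its summit lies inside a
#' subject interval.
#'
#' @param query,subject [scored_peaks] tables (assumed non-redundant).
#' @param mode `"interval"` (>= 1 shared base) or `"summit"` (query summit
#'   within a subject interval).
#' @return a list: `fraction` (overlapping / total query), `n_query`,
#'   `n_overlapping`, and `pairs` — a data.frame with one row per
#'   overlapping query peak giving the nearest subject summit and the
#'   summit-to-summit distance.
#' @export
overlap_fraction <- function(query, subject, mode = c("interval", "summit")) {
  mode <- match.arg(mode)
  if (nrow(query) == 0L) {
    cf_stop("overlap fraction is undefined for an empty query set",
            class = "citfoot_degenerate_error")
  }
  if (nrow(subject) == 0L) {
    return(list(fraction = 0, n_query = nrow(query), n_overlapping = 0L,
                pairs = data.frame()))
  }
  qg <- peaks_as_granges(query)
  sg <- peaks_as_granges(subject)
  if (mode == "summit") {
    qg <- GenomicRanges::GRanges(query$chrom,
                                 IRanges::IRanges(query$summit + 1L, width = 1L))
  }
  # disjoint seqlevels are a legitimate zero-overlap case, not a user error
  hits <- suppressWarnings(GenomicRanges::findOverlaps(qg, sg))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- unique(qh)
  pairs <- if (length(ov) > 0L) {
    d <- abs(query$summit[qh] - subject$summit[sh])
    best <- vapply(split(seq_along(qh), qh),
                   function(i) i[which.min(d[i])], integer(1))
    data.frame(query = qh[best], subject = sh[best],
               summit_distance = d[best], row.names = NULL)
  } else {
    data.frame(query = integer(), subject = integer(),
               summit_distance = numeric())
  }
  list(fraction = length(ov) / nrow(query), n_query = nrow(query),
       n_overlapping = length(ov), pairs = pairs)
}

#' Pearson correlation of paired summit intensities
#'
#' @param intensity_a,intensity_b paired numeric intensity vectors (raw
#'   scale), length >= 3.
#' @return the product-moment correlation coefficient.
#' @export
summit_correlation <- function(intensity_a, intensity_b) {
  if (length(intensity_a) != length(intensity_b)) {
    cf_stop("intensity vectors must be paired (equal length)",
            class = "citfoot_validation_error")
  }
  if (length(intensity_a) < 3L) {
    cf_stop("need at least 3 pairs for a correlation",
            class = "citfoot_degenerate_error")
  }
  if (stats::sd(intensity_a) == 0 || stats::sd(intensity_b) == 0) {
    cf_stop("correlation undefined: zero variance in an intensity vector",
            class = "citfoot_degenerate_error")
  }
  stats::cor(intensity_a, intensity_b)
}

#' Composite (metapeak) profile centered on summits
#'
#' Average signal as a function of offset from a set of anchor summits,
#' sampled every `step` bp over `[-window, window]`. Positions beyond
#' chromosome bounds (or any uncovered position) contribute 0.
#'
#' @param track a [coverage_track].
#' @param chrom chromosome of each summit (recycled).
#' @param summits absolute 0-based summit positions (>= 1).
#' @param window half-window in bp.
#' @param step sampling step in bp.
#' @return a `composite_profile` data.frame with columns `offset`, `value`
#'   (mean over summits) and `sem`; attribute `n_summits`.
#' @export
composite_profile <- function(track, chrom, summits, window = 2000, step = 20) {
  if (length(summits) == 0L) {
    cf_stop("composite_profile needs at least one summit",
            class = "citfoot_degenerate_error")
  }
  chrom <- rep_len(as.character(chrom), length(summits))
  offsets <- seq(-window, window, by = step)
  pos <- outer(summits, offsets, `+`)
  vals <- coverage_value(track, rep(chrom, times = length(offsets)),
                         as.vector(pos))
  m <- matrix(vals, nrow = length(summits))
  out <- data.frame(
    offset = offsets,
    value = colMeans(m),
    sem = apply(m, 2L, stats::sd) / sqrt(length(summits))
  )
  attr(out, "n_summits") <- length(summits)
  class(out) <- c("composite_profile", "data.frame")
  out
}

#' Distance from summit to quarter-maximal signal
#'
#' The smallest distance `d >= 0` at which the signal on *both* flanks
#' (`summit - d` and `summit + d`) has dropped to at most 25% of the summit
#' signal; peaks whose flanks never drop within `window` bp are censored at
#' `window`. `sides = "either"` relaxes the rule to one flank.
#'
#' @param track a [coverage_track].
#' @param chrom chromosome name.
#' @param summit absolute 0-based summit position.
#' @param window censoring limit in bp.
#' @param fraction drop threshold relative to summit signal (default 0.25).
#' @param sides `"both"` (default) or `"either"`.
#' @return a list: `distance` (bp), `censored` (logical), `summit_value`.
#' @export
distance_to_quarter_max <- function(track, chrom, summit, window = 1000,
                                    fraction = 0.25,
                                    sides = c("both", "either")) {
  sides <- match.arg(sides)
  s0 <- coverage_value(track, chrom, summit)
  if (s0 <= 0) {
    cf_stop("summit signal is zero: sharpness undefined",
            class = "citfoot_degenerate_error")
  }
  thr <- fraction * s0
  d <- seq_len(window)
  left <- coverage_value(track, chrom, summit - d)
  right <- coverage_value(track, chrom, summit + d)
  ok <- if (sides == "both") left <= thr & right <= thr else
    left <= thr | right <= thr
  hit <- which(ok)
  if (length(hit) == 0L) {
    list(distance = window, censored = TRUE, summit_value = s0)
  } else {
    list(distance = d[hit[1L]], censored = FALSE, summit_value = s0)
  }
}

#' Sharpness statistic over a peak set
#'
#' Applies [distance_to_quarter_max] to every peak; peaks with zero summit
#' signal are skipped with a count.
#'
#' @param track a [coverage_track].
#' @param peaks a [scored_peaks] table.
#' @inheritParams distance_to_quarter_max
#' @return a `sharpness_result` data.frame with columns `name`, `distance`,
#'   `censored`; attribute `n_zero_summit`.
#' @export
sharpness <- function(track, peaks, window = 1000, fraction = 0.25,
                      sides = c("both", "either")) {
  sides <- match.arg(sides)
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    tryCatch(
      c(distance_to_quarter_max(track, peaks$chrom[i], peaks$summit[i],
                                window = window, fraction = fraction,
                                sides = sides)[c("distance", "censored")],
        list(name = peaks$name[i])),
      citfoot_degenerate_error = function(e) NULL
    )
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  res <- res[!vapply(res, is.null, logical(1))]
  out <- data.frame(
    name = vapply(res, `[[`, "", "name"),
    distance = vapply(res, `[[`, 0, "distance"),
    censored = vapply(res, `[[`, FALSE, "censored")
  )
  attr(out, "n_zero_summit") <- skipped
  class(out) <- c("sharpness_result", "data.frame")
  out
}

#' Empirical CDF of sharpness distances
#'
#' Censored peaks contribute mass only at/above their censoring point, so
#' the CDF below the censoring limit is unaffected by them.
#'
#' @param result a `sharpness_result` from [sharpness], or a numeric vector
#'   of distances.
#' @param at convenience cutoffs (bp) at which to report the CDF.
#' @return a list: `cdf` (an [stats::ecdf] function), `at` — named vector of
#'   CDF values at the requested cutoffs, `n`.
#' @export
sharpness_cdf <- function(result, at = 200) {
  d <- if (is.data.frame(result)) result$distance else as.numeric(result)
  if (length(d) == 0L) {
    cf_stop("sharpness_cdf needs at least one peak",
            class = "citfoot_degenerate_error")
  }
  f <- stats::ecdf(d)
  list(cdf = f, at = stats::setNames(f(at), paste0("le_", at, "bp")),
       n = length(d))
}
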