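## Multi-timepoint subpeak consolidation.
##
## ChIP-seq peak callers applied independently at each timepoint of a
## stimulation time course call largely the same sites over and over. This
## module collapses the per-timepoint subpeak calls into one non-redundant
## peak universe, normalizes summit tag counts per timepoint for library
## size, and applies the no-antibody background retention rule.

#' Construct a peak universe
#'
#' @param peaks a [scored_peaks] table of non-redundant peaks.
#' @param timepoints ordered character timepoint labels.
#' @param counts numeric matrix, `nrow(peaks)` x `length(timepoints)`: raw
#'   summit tag counts per timepoint.
#' @param library_sizes optional named numeric vector (total mapped tags per
#'   timepoint).
#' @param intensities optional normalized intensity matrix (filled by
#'   [normalize_intensities]).
#' @return a `peak_universe` list.
#' @export
peak_universe <- function(peaks, timepoints, counts, library_sizes = NULL,
                          intensities = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(peaks) || ncol(counts) != length(timepoints)) {
    cf_stop("counts must be nrow(peaks) x length(timepoints)",
            class = "citfoot_validation_error")
  }
  if (any(counts < 0)) {
    cf_stop("raw summit counts must be non-negative",
            class = "citfoot_validation_error")
  }
  colnames(counts) <- timepoints
  structure(list(peaks = peaks, timepoints = as.character(timepoints),
                 counts = counts, library_sizes = library_sizes,
                 intensities = intensities),
            class = "peak_universe")
}

#' @export
print.peak_universe <- function(x, ...) {
  cat(sprintf("peak_universe: %d peaks x %d timepoints (%s)\n",
              nrow(x$peaks), length(x$timepoints),
              paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  normalized intensities: %s\n",
              if (is.null(x$intensities)) "not yet computed" else "present"))
  invisible(x)
}

#' Collapse redundant subpeaks across timepoints
#'
#' Subpeak calls from all timepoints are pooled; summits on the same
#' chromosome whose pairwise distance is at most `proximity_bp` are grouped
#' by transitive closure, and within each group only the subpeak with the
#' most tag counts at its summit is retained (ties broken toward the
#' leftmost summit). The default `proximity_bp = 80` encodes the rule that a
#' 100 bp window centered on a summit lying within 30 bp of an adjacent
#' subpeak marks redundancy (50 bp half-window + 30 bp margin).
#'
#' The retained peak's per-timepoint raw count is the maximum summit count
#' among its group's members called at that timepoint (0 where a timepoint
#' called no member), a desk-scale stand-in for re-counting tags at the
#' retained summit in each timepoint's alignment.
#'
#' @param subpeaks named list (names = timepoint labels, in time order) of
#'   [scored_peaks] tables; each subpeak must carry `raw_summit_count`.
#' @param proximity_bp redundancy threshold on summit-to-summit distance (bp).
#' @return a [peak_universe], peaks sorted by (chrom, start).
#' @export
deduplicate_subpeaks <- function(subpeaks, proximity_bp = 80) {
  stopifnot(is.list(subpeaks))
  tps <- names(subpeaks)
  if (is.null(tps) || any(!nzchar(tps))) {
    cf_stop("subpeaks must be a named list (names = timepoint labels)",
            class = "citfoot_validation_error")
  }
  pooled <- do.call(rbind, lapply(tps, function(tp) {
    p <- subpeaks[[tp]]
    if (nrow(p) == 0L) return(NULL)
    assert_columns(p, c("chrom", "start", "end", "summit", "raw_summit_count"),
                   sprintf("subpeaks[['%s']]", tp))
    if (anyNA(p$raw_summit_count)) {
      cf_stop(sprintf("subpeaks[['%s']] has NA raw_summit_count", tp),
              class = "citfoot_validation_error")
    }
    cbind(as.data.frame(p), timepoint = tp, stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    return(peak_universe(empty_scored_peaks(), tps,
                         matrix(0, 0L, length(tps))))
  }
  ord <- order(pooled$chrom, pooled$summit, pooled$start)
  pooled <- pooled[ord, , drop = FALSE]
  # transitive closure on a line = chain summits with consecutive gap <= eps
  new_chrom <- c(TRUE, pooled$chrom[-1L] != pooled$chrom[-nrow(pooled)])
  gap <- c(Inf, diff(pooled$summit))
  group <- cumsum(new_chrom | gap > proximity_bp)

  keep_idx <- vapply(split(seq_len(nrow(pooled)), group), function(i) {
    cnt <- pooled$raw_summit_count[i]
    best <- i[cnt == max(cnt)]
    best[which.min(pooled$summit[best])]  # tie -> leftmost summit
  }, integer(1))
  counts <- matrix(0, nrow = length(keep_idx), ncol = length(tps),
                   dimnames = list(NULL, tps))
  grp_of <- split(seq_len(nrow(pooled)), group)
  for (g in seq_along(grp_of)) {
    i <- grp_of[[g]]
    agg <- tapply(pooled$raw_summit_count[i], pooled$timepoint[i], max)
    counts[g, names(agg)] <- agg
  }
  kept <- pooled[keep_idx, , drop = FALSE]
  ord2 <- order(kept$chrom, kept$start, kept$summit)
  kept <- kept[ord2, , drop = FALSE]
  counts <- counts[ord2, , drop = FALSE]
  peaks <- scored_peaks(kept$chrom, kept$start, kept$end, name = kept$name,
                        score = kept$score, strand = kept$strand,
                        summit = kept$summit,
                        raw_summit_count = kept$raw_summit_count)
  peak_universe(peaks, tps, counts)
}

#' Library-size normalize summit counts
#'
#' Converts raw summit tag counts to tags per 10 million mapped reads:
#' `intensity(t) = raw(t) * 1e7 / library_size(t)`. The scale constant is
#' arbitrary (it cancels in every downstream correlation) but fixing one
#' makes intensities comparable across timepoints.
#'
#' @param universe a [peak_universe].
#' @param library_sizes named numeric vector of total mapped tags per
#'   timepoint; defaults to sizes stored in the universe.
#' @return the universe with `intensities` filled; raw counts are preserved.
#' @export
normalize_intensities <- function(universe, library_sizes = universe$library_sizes) {
  if (is.null(library_sizes)) {
    cf_stop("library_sizes must be supplied", class = "citfoot_validation_error")
  }
  if (!all(universe$timepoints %in% names(library_sizes))) {
    cf_stop("library_sizes must be named for every timepoint",
            class = "citfoot_validation_error")
  }
  ls <- as.numeric(library_sizes[universe$timepoints])
  if (any(!is.finite(ls)) || any(ls <= 0)) {
    cf_stop("library sizes must be positive", class = "citfoot_validation_error")
  }
  universe$library_sizes <- library_sizes[universe$timepoints]
  universe$intensities <- sweep(universe$counts, 2L, ls / 1e7, "/")
  universe
}

#' Retain peaks exceeding a no-antibody background
#'
#' A peak is retained iff its normalized intensity at at least one timepoint
#' exceeds the background signal at its summit in an independent no-antibody
#' control track (normalized on the same scale). The number of removed
#' peaks is reported via a message and the `"n_removed"` attribute.
#'
#' @param universe a [peak_universe] with intensities computed.
#' @param background a [coverage_track] of no-antibody control signal.
#' @return the filtered [peak_universe].
#' @export
filter_by_background <- function(universe, background) {
  if (is.null(universe$intensities)) {
    cf_stop("normalize_intensities() must be run before background filtering",
            class = "citfoot_validation_error")
  }
  if (nrow(universe$peaks) == 0L) return(universe)
  bg <- coverage_value(background, universe$peaks$chrom, universe$peaks$summit)
  keep <- apply(universe$intensities, 1L, max) > bg
  n_removed <- sum(!keep)
  message(sprintf("filter_by_background: removed %d of %d peak(s)",
                  n_removed, length(keep)))
  out <- peak_universe(
    peaks = universe$peaks[keep, , drop = FALSE],
    timepoints = universe$timepoints,
    counts = universe$counts[keep, , drop = FALSE],
    library_sizes = universe$library_sizes,
    intensities = universe$intensities[keep, , drop = FALSE]
  )
  attr(out, "n_removed") <- n_removed
  out
}

#' Export a peak universe as a TSV table
#'
#' One row per peak: coordinates, summit, then one raw-count and one
#' intensity column per timepoint.
#'
#' @param universe a [peak_universe].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_universe <- function(universe, path) {
  df <- as.data.frame(universe$peaks)
  for (tp in universe$timepoints) {
    df[[paste0("count_", tp)]] <- universe$counts[, tp]
  }
  if (!is.null(universe$intensities)) {
    for (tp in universe$timepoints) {
      df[[paste0("intensity_", tp)]] <- universe$intensities[, tp]
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
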