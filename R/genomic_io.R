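## Genomic text-format I/O.
##
## Everything in this package is 0-based half-open ([start, end)), the native
## BED convention; summits are absolute 0-based positions. Conversion to
## 1-based display coordinates happens only in print methods.

# ---- scored peaks -----------------------------------------------------------

#' Construct a scored-peak table
#'
#' The pipeline's atom: a genomic interval with a summit position and a raw
#' tag count at the summit. Stored as a plain `data.frame` with class
#' `scored_peaks` so all of base R's table tooling applies.
#'
#' @param chrom character chromosome names.
#' @param start,end 0-based half-open interval bounds (`end > start`).
#' @param name optional peak labels (default `peak_1..n`).
#' @param score optional numeric score column (BED column 5).
#' @param strand optional strand (`"+"`, `"-"`, `"."`); parsed but ignored by
#'   all statistics, which are strand-agnostic.
#' @param summit absolute 0-based summit positions; defaults to the interval
#'   midpoint (floor). Must satisfy `start <= summit < end`.
#' @param raw_summit_count raw tag count at the summit (default `NA`).
#' @return a `scored_peaks` data.frame with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`, `summit`, `raw_summit_count`.
#' @export
scored_peaks <- function(chrom, start, end, name = NULL, score = NA_real_,
                         strand = ".", summit = NULL,
                         raw_summit_count = NA_real_) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(start) == 0L || length(chrom) == 0L) {
    return(empty_scored_peaks())
  }
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (any(!nzchar(chrom))) {
    cf_stop("chrom names must be non-empty", class = "citfoot_validation_error")
  }
  if (any(start < 0)) {
    cf_stop("start positions must be >= 0", class = "citfoot_validation_error")
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1L]
    cf_stop(sprintf("empty or inverted interval at row %d (start=%s, end=%s)",
                    bad, start[bad], end[bad]),
            class = "citfoot_validation_error")
  }
  if (is.null(summit)) summit <- floor((start + end) / 2)
  summit <- rep_len(as.numeric(summit), n)
  if (any(summit < start | summit >= end)) {
    cf_stop("summit must lie within [start, end)",
            class = "citfoot_validation_error")
  }
  df <- data.frame(
    chrom = as.character(chrom),
    start = start,
    end = end,
    name = if (is.null(name)) sprintf("peak_%d", seq_len(n)) else
      rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    summit = as.numeric(summit),
    raw_summit_count = rep_len(as.numeric(raw_summit_count), n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("scored_peaks", "data.frame")
  df
}

empty_scored_peaks <- function() {
  df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   name = character(), score = numeric(), strand = character(),
                   summit = numeric(), raw_summit_count = numeric(),
                   stringsAsFactors = FALSE)
  class(df) <- c("scored_peaks", "data.frame")
  df
}

#' Convert a scored-peak table to `GRanges`
#' @param peaks a `scored_peaks` data.frame.
#' @return a [GenomicRanges::GRanges] with `summit` metadata column.
#' @export
peaks_as_granges <- function(peaks) {
  assert_columns(peaks, c("chrom", "start", "end"), "peaks")
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    # BED half-open -> IRanges 1-based closed
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    summit = if ("summit" %in% names(peaks)) peaks$summit else
      floor((peaks$start + peaks$end) / 2)
  )
}

#' Read peak calls from a BED-style file
#'
#' @param path path to a tab-separated peak file. `track`/`browser`/`#`
#'   lines are skipped.
#' @param dialect `"bed6"` (summit = interval midpoint, floor) or
#'   `"macs-summit"` (10 columns, the 10th being the summit offset from
#'   `start`, narrowPeak-style; column 7 is read back as the raw summit tag
#'   count).
#' @return a [scored_peaks] data.frame.
#' @export
read_peaks <- function(path, dialect = c("bed6", "macs-summit")) {
  dialect <- match.arg(dialect)
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) return(empty_scored_peaks())
  min_cols <- if (dialect == "bed6") 3L else 10L
  fields <- parse_tsv_lines(lines, min_cols, path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- parse_numeric_field(fields, 2L, lines, path)
  end <- parse_numeric_field(fields, 3L, lines, path)
  nm <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_, "")
  score <- if (all(lengths(fields) >= 5L)) parse_numeric_field(fields, 5L, lines, path) else NA_real_
  strand <- vapply(fields, function(f) if (length(f) >= 6L) f[6L] else ".", "")
  if (dialect == "macs-summit") {
    offs <- parse_numeric_field(fields, 10L, lines, path)
    summit <- start + offs
    rsc <- parse_numeric_field(fields, 7L, lines, path)
  } else {
    summit <- NULL
    rsc <- NA_real_
  }
  tryCatch(
    scored_peaks(chrom, start, end,
                 name = if (all(is.na(nm))) NULL else nm,
                 score = score, strand = strand, summit = summit,
                 raw_summit_count = rsc),
    citfoot_validation_error = function(e) {
      cf_stop(sprintf("%s: %s", path, conditionMessage(e)),
              class = "citfoot_validation_error")
    }
  )
}

#' Write peaks to a BED-style file
#'
#' Inverse of [read_peaks]: `read_peaks(write_peaks(p, f), dialect)` returns
#' the same table (for `bed6`, provided summits are interval midpoints).
#'
#' @param peaks a [scored_peaks] table.
#' @param path output path.
#' @param dialect see [read_peaks].
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, dialect = c("bed6", "macs-summit")) {
  dialect <- match.arg(dialect)
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  if (dialect == "bed6") {
    out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                   peaks$name, format_num(score), peaks$strand)
  } else {
    rsc <- ifelse(is.na(peaks$raw_summit_count), 0, peaks$raw_summit_count)
    out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t-1\t-1\t%d",
                   peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                   peaks$name, format_num(score), peaks$strand,
                   format_num(rsc),
                   as.integer(peaks$summit - peaks$start))
  }
  writeLines(out, path)
  invisible(path)
}

# ---- coverage tracks --------------------------------------------------------

#' Construct a per-base coverage track
#'
#' A step-function signal per chromosome: non-overlapping, sorted
#' `(start, end, value)` steps, half-open. Positions not covered by any step
#' have value 0.
#'
#' @param chrom,start,end,value vectors defining the steps (`value >= 0`).
#' @return a `coverage_track` data.frame.
#' @export
coverage_track <- function(chrom = character(), start = numeric(),
                           end = numeric(), value = numeric()) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    if (any(df$end <= df$start)) {
      cf_stop("coverage steps must have end > start",
              class = "citfoot_validation_error")
    }
    if (any(df$value < 0)) {
      cf_stop("coverage values must be non-negative",
              class = "citfoot_validation_error")
    }
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
    ov <- unlist(tapply(seq_len(nrow(df)), df$chrom, function(i) {
      if (length(i) < 2L) return(FALSE)
      df$start[i][-1L] < df$end[i][-length(i)]
    }), use.names = FALSE)
    if (any(ov)) {
      cf_stop("coverage steps overlap within a chromosome",
              class = "citfoot_validation_error")
    }
  }
  class(df) <- c("coverage_track", "data.frame")
  df
}

#' Read a bedGraph file into a coverage track
#' @param path bedGraph path (4 tab-separated columns).
#' @return a [coverage_track].
#' @export
read_coverage <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) return(coverage_track())
  fields <- parse_tsv_lines(lines, 4L, path)
  coverage_track(
    chrom = vapply(fields, `[[`, "", 1L),
    start = parse_numeric_field(fields, 2L, lines, path),
    end = parse_numeric_field(fields, 3L, lines, path),
    value = parse_numeric_field(fields, 4L, lines, path)
  )
}

#' Write a coverage track as bedGraph
#' @param track a [coverage_track].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                     as.integer(track$end), format_num(track$value)),
             path)
  invisible(path)
}

#' Look up coverage values at positions
#'
#' @param track a [coverage_track].
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos 0-based positions.
#' @return numeric vector: the covering step's value, or 0 where no step
#'   covers the position (including positions off any chromosome).
#' @export
coverage_value <- function(track, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  out <- numeric(n)
  if (nrow(track) == 0L) return(out)
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    ti <- which(track$chrom == ch)
    if (length(ti) == 0L) next
    starts <- track$start[ti]; ends <- track$end[ti]; vals <- track$value[ti]
    idx <- findInterval(pos[qi], starts)
    hit <- idx >= 1L & pos[qi] < ends[pmax(idx, 1L)]
    out[qi[hit]] <- vals[idx[hit]]
  }
  out
}

# ---- paired-end fragments ---------------------------------------------------

#' Construct a fragment table
#' @param chrom,start,end fragment spans (half-open; `end - start >= 1`).
#' @return a `fragment_set` data.frame with a `length` column.
#' @export
fragment_set <- function(chrom = character(), start = numeric(),
                         end = numeric()) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  if (nrow(df) > 0L && any(df$length < 1)) {
    cf_stop("fragments must have length >= 1",
            class = "citfoot_validation_error")
  }
  class(df) <- c("fragment_set", "data.frame")
  df
}

#' Read paired-end fragments from a BEDPE file
#'
#' Each concordant pair (both mates on one chromosome) becomes a fragment
#' spanning `min(start1, start2)` to `max(end1, end2)`. Discordant
#' (inter-chromosomal) pairs are dropped; their count is reported via a
#' message and the `"n_discordant"` attribute of the result.
#'
#' @param path BEDPE path (>= 6 tab-separated columns).
#' @return a [fragment_set] with attribute `n_discordant`.
#' @export
read_fragments <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    out <- fragment_set()
    attr(out, "n_discordant") <- 0L
    return(out)
  }
  fields <- parse_tsv_lines(lines, 6L, path)
  c1 <- vapply(fields, `[[`, "", 1L)
  s1 <- parse_numeric_field(fields, 2L, lines, path)
  e1 <- parse_numeric_field(fields, 3L, lines, path)
  c2 <- vapply(fields, `[[`, "", 4L)
  s2 <- parse_numeric_field(fields, 5L, lines, path)
  e2 <- parse_numeric_field(fields, 6L, lines, path)
  concord <- c1 == c2
  n_disc <- sum(!concord)
  if (n_disc > 0L) {
    message(sprintf("read_fragments: dropped %d discordant (inter-chromosomal) pair(s)",
                    n_disc))
  }
  out <- fragment_set(chrom = c1[concord],
                      start = pmin(s1, s2)[concord],
                      end = pmax(e1, e2)[concord])
  attr(out, "n_discordant") <- n_disc
  out
}

#' Write fragments as BEDPE
#'
#' Each fragment is emitted as two abutting synthetic mates covering its
#' span, so `read_fragments(write_fragments(x, f))` reproduces `x`.
#'
#' @param fragments a [fragment_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  mid <- floor((fragments$start + fragments$end) / 2)
  mid <- pmax(mid, fragments$start + 1)  # mate1 non-empty even for length-1
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\tfrag_%d\t0\t+\t-",
                     fragments$chrom, as.integer(fragments$start),
                     as.integer(mid), fragments$chrom, as.integer(mid),
                     as.integer(fragments$end), seq_len(nrow(fragments))),
             path)
  invisible(path)
}

# ---- shared parsing helpers -------------------------------------------------

read_data_lines <- function(path) {
  if (!file.exists(path)) {
    cf_stop(sprintf("file not found: %s", path), class = "citfoot_io_error")
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", raw) & nzchar(trimws(raw))
  list(text = raw[keep], lineno = which(keep))
}

parse_tsv_lines <- function(lines, min_cols, path) {
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  short <- lengths(fields) < min_cols
  if (any(short)) {
    bad <- which(short)[1L]
    cf_stop(sprintf("%s line %d: expected >= %d tab-separated columns, found %d",
                    path, lines$lineno[bad], min_cols, lengths(fields)[bad]),
            class = "citfoot_parse_error")
  }
  fields
}

parse_numeric_field <- function(fields, col, lines, path) {
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
  if (anyNA(x)) {
    bad <- which(is.na(x))[1L]
    cf_stop(sprintf("%s line %d: column %d is not numeric",
                    path, lines$lineno[bad], col),
            class = "citfoot_parse_error")
  }
  x
}

format_num <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
         sub("0+$", "", sprintf("%.10f", x)))
}
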