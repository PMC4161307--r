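## Synthetic-data generators.
##
## Every input the pipeline consumes can be generated with known ground
## truth: coupled cistromes with linearly related intensities, coverage
## tracks of controllable sharpness, kinetic-class time courses, MNase
## fragment-length mixtures, NB count matrices with a null/alternative mix,
## and survival cohorts with expression-dependent hazards. All generators
## take an explicit seed and are deterministic given it; the caller's RNG
## state is left untouched.

default_genome <- function() list(chr1 = 30e6, chr2 = 20e6)

place_summits <- function(n, genome, min_spacing = 1000) {
  caps <- vapply(genome, function(len) floor(len / min_spacing), numeric(1))
  if (n > sum(caps)) {
    cf_stop(sprintf("genome holds at most %d peaks at %d bp spacing, %d requested",
                    sum(caps), min_spacing, n),
            class = "citfoot_validation_error")
  }
  slots <- unlist(lapply(names(genome), function(ch) {
    paste0(ch, ":", seq_len(caps[[ch]]) - 1L)
  }))
  chosen <- sample(slots, n)
  parts <- strsplit(chosen, ":", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    summit = (as.numeric(vapply(parts, `[[`, "", 2L)) + 0.5) * min_spacing,
    stringsAsFactors = FALSE
  )
}

#' Generate a pair of linearly coupled cistromes
#'
#' Peak set A carries log-normal summit intensities; each paired B peak's
#' intensity is `slope * A + e`, `e ~ N(0, noise_sd)`, censored at 0, with
#' its summit jittered around A's. A configurable fraction of A peaks has
#' no B partner, and extra B-only peaks carry independent intensities.
#' When `target_r` is given, `noise_sd` is derived from the population SD
#' of the intensity distribution so the generating correlation among
#' paired peaks is `target_r`.
#'
#' @param n_a number of A peaks.
#' @param slope linear coupling coefficient.
#' @param target_r generating Pearson correlation for paired intensities
#'   (ignored if `noise_sd` is given directly).
#' @param noise_sd SD of the additive intensity noise.
#' @param a_only_frac fraction of A peaks without a B partner.
#' @param b_only_frac fraction of the final B set that is B-only.
#' @param meanlog,sdlog log-normal intensity parameters for A.
#' @param summit_jitter_sd SD (bp) of the paired-summit offset.
#' @param width_a,width_b peak interval widths (bp).
#' @param genome named list chrom -> length (bp).
#' @param min_spacing minimum summit spacing (bp) between distinct sites.
#' @param seed integer seed.
#' @return a list: `peaks_a`, `peaks_b` ([scored_peaks]; intensity in
#'   `score`, rounded to `raw_summit_count`), `truth` (pairing table with
#'   generating intensities) and `params`.
#' @export
gen_coupled_cistrome <- function(n_a = 2000, slope = 2, target_r = 0.92,
                                 noise_sd = NULL, a_only_frac = 0.05,
                                 b_only_frac = 0.53,
                                 meanlog = log(100), sdlog = 0.5,
                                 summit_jitter_sd = 10,
                                 width_a = 200, width_b = 300,
                                 genome = default_genome(),
                                 min_spacing = 2000, seed = 1) {
  with_seed(seed, {
    if (is.null(noise_sd)) {
      sd_a <- sqrt((exp(sdlog^2) - 1) * exp(2 * meanlog + sdlog^2))
      noise_sd <- slope * sd_a * sqrt(1 / target_r^2 - 1)
    }
    n_paired <- round(n_a * (1 - a_only_frac))
    n_b_only <- round(n_paired * b_only_frac / (1 - b_only_frac))
    sites <- place_summits(n_a + n_b_only, genome, min_spacing)
    site_a <- sites[seq_len(n_a), ]
    site_bo <- sites[n_a + seq_len(n_b_only), ]

    int_a <- stats::rlnorm(n_a, meanlog, sdlog)
    paired <- sample(n_a, n_paired)  # which A peaks have a B partner
    int_b_paired <- pmax(0, slope * int_a[paired] +
                           stats::rnorm(n_paired, 0, noise_sd))
    b_summit <- round(site_a$summit[paired] +
                        stats::rnorm(n_paired, 0, summit_jitter_sd))
    int_b_only <- slope * stats::rlnorm(n_b_only, meanlog, sdlog)

    peaks_a <- scored_peaks(
      chrom = site_a$chrom,
      start = round(site_a$summit - width_a / 2),
      end = round(site_a$summit + width_a / 2),
      name = sprintf("A_%d", seq_len(n_a)),
      score = int_a, summit = site_a$summit,
      raw_summit_count = round(int_a)
    )
    b_chrom <- c(site_a$chrom[paired], site_bo$chrom)
    b_sum <- c(b_summit, site_bo$summit)
    b_int <- c(int_b_paired, int_b_only)
    ord <- order(b_chrom, b_sum)
    peaks_b <- scored_peaks(
      chrom = b_chrom[ord],
      start = round(b_sum[ord] - width_b / 2),
      end = round(b_sum[ord] + width_b / 2),
      name = sprintf("B_%d", seq_along(b_sum)),
      score = b_int[ord], summit = b_sum[ord],
      raw_summit_count = round(b_int[ord])
    )
    truth <- data.frame(
      a_index = paired,
      intensity_a = int_a[paired],
      intensity_b = int_b_paired
    )
    list(peaks_a = peaks_a, peaks_b = peaks_b, truth = truth,
         params = list(slope = slope, noise_sd = noise_sd,
                       target_r = target_r, seed = seed))
  })
}

#' Generate a coverage track around peak summits
#'
#' Each peak contributes a kernel of the chosen shape centered on its
#' summit and scaled so the summit value equals `depth * score`; overlaps
#' add. A uniform background can be added over each chromosome's covered
#' span, and values are rounded to integers by default (tag pileups are
#' integral).
#'
#' @param peaks a [scored_peaks] table with intensities in `score`.
#' @param shape `"gaussian"` (SD `sigma`) or `"triangular"` (half-width
#'   `sigma`).
#' @param sigma kernel scale in bp.
#' @param depth multiplicative depth factor (summit value = `depth *
#'   score`).
#' @param background constant background level added everywhere within the
#'   track's span.
#' @param round_values round to integer tag counts (default TRUE).
#' @param seed unused unless future stochastic backgrounds are added;
#'   accepted for interface uniformity.
#' @return a [coverage_track].
#' @export
gen_coverage <- function(peaks, shape = c("gaussian", "triangular"),
                         sigma = 60, depth = 1, background = 0,
                         round_values = TRUE, seed = NULL) {
  shape <- match.arg(shape)
  ext <- if (shape == "gaussian") ceiling(5 * sigma) else ceiling(sigma)
  rows <- list()
  for (ch in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    p <- p[order(p$summit), , drop = FALSE]
    # merge peaks into islands so arrays stay small on sparse genomes
    gap_break <- c(TRUE, diff(p$summit) > 2 * ext + 1)
    isl <- cumsum(gap_break)
    for (g in unique(isl)) {
      q <- p[isl == g, , drop = FALSE]
      lo <- max(0, floor(min(q$summit) - ext))
      hi <- ceiling(max(q$summit) + ext)
      v <- numeric(hi - lo + 1L)
      pos <- lo:hi
      for (i in seq_len(nrow(q))) {
        d <- pos - q$summit[i]
        k <- if (shape == "gaussian") {
          exp(-d^2 / (2 * sigma^2))
        } else {
          pmax(0, 1 - abs(d) / sigma)
        }
        v <- v + depth * q$score[i] * k
      }
      v <- v + background
      if (round_values) v <- round(v)
      r <- rle(v)
      ends <- lo + cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values > 0
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = starts[keep], end = ends[keep],
          value = r$values[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(coverage_track())
  all <- do.call(rbind, rows)
  coverage_track(all$chrom, all$start, all$end, all$value)
}

#' Generate a kinetic-class time-course matrix
#'
#' Each class has a unimodal intensity profile over the timepoints peaking
#' at its designated time (`NA` = flat), scaled by a per-peak log-normal
#' amplitude with multiplicative log-normal noise per entry.
#'
#' @param n_per_class named integer vector: rows per class.
#' @param class_peak_time named numeric vector (same names): the timepoint
#'   (minutes) at which each class peaks, `NA` for a flat class.
#' @param timepoints minutes (default `c(0, 2, 5, 10, 40, 160)`).
#' @param shape_width width of the log-time bump (default 0.8).
#' @param noise_sd SD of the multiplicative log-normal noise (default 0.2).
#' @param amp_meanlog,amp_sdlog per-peak amplitude distribution.
#' @param seed integer seed.
#' @return a list: `matrix` (a [timecourse_matrix]), `labels` (class per
#'   row).
#' @export
gen_timecourse <- function(n_per_class = c(early = 300, late = 150, flat = 150),
                           class_peak_time = c(early = 5, late = 40, flat = NA),
                           timepoints = c(0, 2, 5, 10, 40, 160),
                           shape_width = 0.8, noise_sd = 0.2,
                           amp_meanlog = log(50), amp_sdlog = 0.5, seed = 1) {
  stopifnot(identical(sort(names(n_per_class)), sort(names(class_peak_time))))
  with_seed(seed, {
    rows <- list(); labels <- character()
    for (cl in names(n_per_class)) {
      n <- n_per_class[[cl]]
      pk <- class_peak_time[[cl]]
      base <- if (is.na(pk)) {
        rep(1, length(timepoints))
      } else {
        exp(-(log((timepoints + 1) / (pk + 1)))^2 / (2 * shape_width^2))
      }
      amp <- stats::rlnorm(n, amp_meanlog, amp_sdlog)
      noise <- matrix(stats::rlnorm(n * length(timepoints), 0, noise_sd),
                      nrow = n)
      rows[[cl]] <- amp * matrix(base, nrow = n, ncol = length(timepoints),
                                 byrow = TRUE) * noise
      labels <- c(labels, rep(cl, n))
    }
    m <- do.call(rbind, rows)
    list(matrix = timecourse_matrix(m, timepoints), labels = labels)
  })
}

#' Generate paired-end MNase fragments
#'
#' Fragment lengths are drawn from a Gaussian mixture, rounded to integers
#' and truncated by rejection to the open interval (1, 500); midpoints are
#' placed uniformly within the given peak intervals (one peak chosen
#' uniformly per fragment) or uniformly over the genome.
#'
#' @param n number of fragments.
#' @param components data.frame with columns `mean`, `sd`, `weight`
#'   (weights sum to 1).
#' @param peaks optional [scored_peaks]; `NULL` places midpoints
#'   genome-wide.
#' @param genome named list chrom -> length, used when `peaks` is `NULL`.
#' @param seed integer seed.
#' @return a [fragment_set] with attribute `components` recording the
#'   truth.
#' @export
gen_fragments <- function(n = 50000,
                          components = data.frame(mean = 147, sd = 10,
                                                  weight = 1),
                          peaks = NULL, genome = default_genome(), seed = 1) {
  if (abs(sum(components$weight) - 1) > 1e-8) {
    cf_stop("component weights must sum to 1",
            class = "citfoot_validation_error")
  }
  if (any(components$sd <= 0)) {
    cf_stop("component SDs must be positive",
            class = "citfoot_validation_error")
  }
  with_seed(seed, {
    comp <- sample.int(nrow(components), n, replace = TRUE,
                       prob = components$weight)
    len <- round(stats::rnorm(n, components$mean[comp], components$sd[comp]))
    bad <- which(len <= 1 | len >= 500)
    while (length(bad) > 0L) {
      len[bad] <- round(stats::rnorm(length(bad), components$mean[comp[bad]],
                                     components$sd[comp[bad]]))
      bad <- bad[len[bad] <= 1 | len[bad] >= 500]
    }
    if (is.null(peaks)) {
      chrom <- sample(names(genome), n, replace = TRUE,
                      prob = as.numeric(unlist(genome)))
      mid <- floor(stats::runif(n, 250, as.numeric(unlist(genome))[
        match(chrom, names(genome))] - 250))
    } else {
      pk <- sample.int(nrow(peaks), n, replace = TRUE)
      mid <- floor(stats::runif(n, peaks$start[pk], peaks$end[pk]))
      chrom <- peaks$chrom[pk]
    }
    start <- pmax(0, mid - floor(len / 2))
    out <- fragment_set(chrom = chrom, start = start, end = start + len)
    attr(out, "components") <- components
    out
  })
}

#' Generate an NB count matrix with a null/alternative mix
#'
#' Per-region means are log-normal (a low-count-heavy tail), counts are
#' negative binomial with dispersion `alpha`; a fraction `pi_alt` of
#' regions has its condition-B mean multiplied by `fold`.
#'
#' @param n_regions number of regions.
#' @param n_rep replicates per condition (conditions `A` = pre, `B` =
#'   post).
#' @param meanlog,sdlog per-region mean distribution.
#' @param alpha NB dispersion (0 = Poisson).
#' @param pi_alt fraction of true positives.
#' @param fold fold-change applied to condition B at true positives.
#' @param libsize_mult per-sample library-size multipliers (length
#'   `2 * n_rep`).
#' @param seed integer seed.
#' @return a list: `counts` (a [count_matrix] with region intervals),
#'   `is_alt` (logical truth per region).
#' @export
gen_counts <- function(n_regions = 2000, n_rep = 2, meanlog = log(20),
                       sdlog = 1.5, alpha = 0.2, pi_alt = 0, fold = 4,
                       libsize_mult = NULL, seed = 1) {
  n_samp <- 2L * n_rep
  if (is.null(libsize_mult)) libsize_mult <- rep(1, n_samp)
  stopifnot(length(libsize_mult) == n_samp)
  with_seed(seed, {
    mu <- stats::rlnorm(n_regions, meanlog, sdlog)
    is_alt <- stats::runif(n_regions) < pi_alt
    cond <- rep(c("A", "B"), each = n_rep)
    m <- matrix(0L, n_regions, n_samp)
    for (j in seq_len(n_samp)) {
      mu_j <- mu * libsize_mult[j] * ifelse(is_alt & cond[j] == "B", fold, 1)
      m[, j] <- if (alpha > 0) {
        stats::rnbinom(n_regions, mu = mu_j, size = 1 / alpha)
      } else {
        stats::rpois(n_regions, lambda = mu_j)
      }
    }
    colnames(m) <- paste0(cond, rep(seq_len(n_rep), 2L))
    regions <- scored_peaks(chrom = "chr1",
                            start = (seq_len(n_regions) - 1L) * 1000,
                            end = (seq_len(n_regions) - 1L) * 1000 + 200,
                            name = sprintf("region_%d", seq_len(n_regions)))
    list(counts = count_matrix(m, cond, regions = regions), is_alt = is_alt)
  })
}

#' Generate a clinical cohort: IHC sections and survival records
#'
#' A latent per-patient level drives both the marker staining scores
#' (pairwise latent correlation `latent_cor` between informative markers;
#' the IgG control stays near zero) and exponential survival, with a
#' configurable hazard ratio between low- and high-expression patients
#' (high expression protective for `hazard_ratio > 1`). Censoring is
#' independent uniform.
#'
#' @param n_patients cohort size.
#' @param n_areas section areas imaged per patient.
#' @param markers informative marker names (plus an `IgG` control).
#' @param latent_cor target pairwise score correlation between informative
#'   markers.
#' @param expression_dist `"normal"` or `"bimodal"` (two well-separated
#'   modes; the high mode is the protective group).
#' @param hazard_ratio hazard of the low-expression group relative to the
#'   high group.
#' @param base_hazard event hazard (per month) in the high group.
#' @param censor_max upper bound of the uniform censoring time (months).
#' @param area_noise_sd SD of the per-area staining noise on the 0-5 scale.
#' @param seed integer seed.
#' @return a list: `sections` (IHC table with `f0`..`f5`), `survival`
#'   (data.frame `patient`, `expression`, `time`, `event`), `truth`
#'   (latent levels and high/low assignment).
#' @export
gen_cohort <- function(n_patients = 200, n_areas = 2,
                       markers = c("ER", "PAD2", "H3R26Cit"),
                       latent_cor = 0.7,
                       expression_dist = c("normal", "bimodal"),
                       hazard_ratio = 3, base_hazard = 0.01,
                       censor_max = 120, area_noise_sd = 0.3, seed = 1) {
  expression_dist <- match.arg(expression_dist)
  with_seed(seed, {
    if (expression_dist == "bimodal") {
      high <- stats::runif(n_patients) < 0.5
      z <- stats::rnorm(n_patients, ifelse(high, 2, -2), 0.5)
    } else {
      z <- stats::rnorm(n_patients)
      high <- z > stats::median(z)
    }
    # cor(marker_i, marker_j) = rho^2 * 1.1^2 / (1.1^2 + area_noise_sd^2) on
    # the score scale; de-attenuate so the configured correlation is what
    # matched section scores actually show
    rho <- min(1, sqrt(latent_cor * (1.1^2 + area_noise_sd^2) / 1.1^2))
    zs <- scale(z)[, 1L]
    sections <- do.call(rbind, lapply(c(markers, "IgG"), function(mk) {
      lat <- if (mk == "IgG") {
        stats::rnorm(n_patients, 0, 1)  # uncorrelated control
      } else {
        rho * zs + sqrt(1 - rho^2) * stats::rnorm(n_patients)
      }
      level <- if (mk == "IgG") {
        pmin(pmax(0.2 + 0.1 * lat, 0), 5)
      } else {
        pmin(pmax(2.5 + 1.1 * lat, 0), 5)
      }
      do.call(rbind, lapply(seq_len(n_areas), function(a) {
        la <- pmin(pmax(level + stats::rnorm(n_patients, 0, area_noise_sd),
                        0), 5)
        lo <- pmin(floor(la), 5)
        w_hi <- la - lo
        f <- matrix(0, n_patients, 6L, dimnames = list(NULL, paste0("f", 0:5)))
        for (i in seq_len(n_patients)) {
          f[i, lo[i] + 1L] <- 1 - w_hi[i]
          if (lo[i] < 5) f[i, lo[i] + 2L] <- w_hi[i]
        }
        cbind(data.frame(patient = seq_len(n_patients), marker = mk,
                         area = a, stringsAsFactors = FALSE),
              as.data.frame(f))
      }))
    }))
    hz <- base_hazard * ifelse(high, 1, hazard_ratio)
    t_event <- stats::rexp(n_patients, hz)
    t_cens <- stats::runif(n_patients, 0, censor_max)
    surv <- data.frame(
      patient = seq_len(n_patients),
      expression = z,
      time = pmax(pmin(t_event, t_cens), 1e-6),
      event = t_event <= t_cens
    )
    list(sections = sections, survival = surv,
         truth = data.frame(patient = seq_len(n_patients), latent = z,
                            high = high))
  })
}
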