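# citfoot

Downstream analysis of transcription-factor / histone-mark ChIP-seq time
courses and paired-end MNase ChIP-seq, built around the question of how a
histone modification written at a transcription factor's binding sites
(here: H3R26 citrullination at estrogen-receptor sites) relates to factor
binding, chromatin accessibility, nucleosome structure, and — through the
writer enzyme's expression — patient survival.

The package is aimed at computational epigenomics analysts who have peak
calls, coverage tracks, fragment files and count tables in hand and want
the downstream statistics as tested, reusable functions rather than
one-off scripts. Every stage also runs on the package's own synthetic
data with known ground truth, so the whole pipeline is verifiable
offline.

## What it computes

* **Peak consolidation** — per-timepoint subpeak calls are pooled,
  summits within a proximity threshold (default 80 bp, transitive
  closure) are collapsed to the subpeak with the most summit tags,
  intensities are normalized to tags per 10⁷ mapped reads per timepoint,
  and peaks must beat a no-antibody control at ≥ 1 timepoint to survive.
* **Colocalization** — overlap fractions between two cistromes, Pearson
  correlation of paired summit intensities, composite (metapeak)
  profiles `v(o) = mean_s track(s + o)`, and a peak-sharpness statistic:
  the smallest `d` with `signal(summit ± d) ≤ 0.25 · signal(summit)` on
  both flanks, censored at a window, summarized as an empirical CDF.
* **Kinetics** — agglomerative Euclidean clustering of per-peak,
  max-normalized intensity time courses; mean ± SEM signal curves;
  histograms of the (earliest) timepoint of maximum per peak.
* **Differential accessibility** — negative-binomial counts
  (`Var = μ + αμ²`) with median-of-ratios size factors, a Cox–Reid
  ML mean-dispersion trend, a conditional exact test on per-condition
  count sums, *independent filtering* by total count before
  Benjamini–Hochberg, plus the power-scan (filter 30–70%) and
  p-value/count independence diagnostics that justify the filter.
* **Nucleosome footprints** — MNase fragment lengths (strictly
  `1 < L < 500`) assigned to peaks by midpoint; 1 bp-resolution length
  distributions; kernel-smoothed mode (the protection size); pre/post
  treatment mode-shift report with a two-sample KS test.
* **Clinical endpoints** — weighted IHC DAB scores
  `Σ level × fraction(level)`, cross-marker Pearson correlations,
  Kaplan–Meier curves, two-group log-rank tests, and an
  expression-quantile threshold scan that reports the best split with an
  explicit multiplicity warning.
* **Synthetic data** — seed-deterministic generators for coupled peak
  sets, coverage tracks of controllable sharpness, kinetic-class time
  courses, fragment-length mixtures, NB count matrices with planted
  positives, and survival cohorts with expression-dependent hazards.

See `vignettes/citfoot-methods.Rmd` for the models, parameter defaults
and design rationale.

## Worked example

```r
library(citfoot)

# two coupled cistromes at the default study conditions
cc <- gen_coupled_cistrome(n_a = 2000, seed = 1)
ov <- overlap_fraction(cc$peaks_a, cc$peaks_b)
r  <- summit_correlation(cc$truth$intensity_a, cc$truth$intensity_b)

# MNase protection before/after treatment
pre  <- gen_fragments(n = 50000, components = data.frame(mean = 155, sd = 10, weight = 1), seed = 2)
post <- gen_fragments(n = 50000, components = data.frame(mean = 125, sd = 10, weight = 1), seed = 3)
ms <- mode_shift_report(lengths_at_peaks(filter_fragment_lengths(pre),  NULL, "pre-E2"),
                        lengths_at_peaks(filter_fragment_lengths(post), NULL, "post-E2"))

# differential accessibility with independent filtering
g   <- gen_counts(n_regions = 2000, alpha = 0.2, pi_alt = 0.05, fold = 4, seed = 4)
res <- independent_filter(nb_test_all(g$counts), filter_fraction = 0.5)
```

Printed results:

```
overlap: 95.0% of A peaks hit a B peak
summit intensity correlation r = 0.919
protection mode: 155 bp -> 126 bp (shift -29 bp), KS p = 0
differential regions at FDR 0.15: 59 (of 1004 retained by the filter)
```

The overlap and correlation recover the generator's planted concordance
(95% paired peaks, generating r = 0.92); the footprint modes recover the
planted 155 → 125 bp protection-size shift to within 1 bp with an
overwhelming distribution-level KS signal; and the NB analysis finds a
subset of the 5% planted fold-change-4 regions at FDR 0.15 after
filtering out the uninformative low-count half.

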