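---
title: "citfoot: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{citfoot: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`citfoot` implements the downstream computational analyses used to
characterize the relationship between a DNA-binding transcription factor
(estrogen receptor, ER) and a histone mark deposited at its binding sites
(citrullinated H3 arginine 26, H3R26Cit) in hormone-stimulated breast
cancer cells, together with the clinical endpoints that connect the
enzyme writing the mark (PAD2) to patient survival. Every stage consumes
standard genomic text formats (BED, bedGraph, BEDPE, TSV) and every stage
can be driven by the package's own synthetic-data generators, so the full
pipeline is testable without any external data.

All genomic coordinates inside the package are 0-based half-open (the
native BED convention); summits are absolute 0-based positions. This is
applied uniformly — interval overlap, coverage lookup, fragment midpoints —
so no per-module conversions exist.

# Peak consolidation

ChIP-seq peaks called independently at each timepoint of a stimulation
time course (0, 2, 5, 10, 40, 160 min) re-discover the same sites.
`deduplicate_subpeaks()` pools all subpeak calls and groups summits on the
same chromosome whose pairwise distance is at most `proximity_bp`,
taking the transitive closure (on a line this reduces to chaining
consecutive summits). Within a group only the subpeak with the most tags
at its summit survives; count ties break to the leftmost summit so output
is deterministic.

The default `proximity_bp = 80` encodes the redundancy geometry of a
100 bp window centered on a summit coming within 30 bp of an adjacent
subpeak: 50 bp half-window plus the 30 bp margin. A stricter
summit-to-summit reading (30 bp) is available by setting
`proximity_bp = 30`; the parameter exists precisely because the geometry
admits both readings.

After consolidation, `normalize_intensities()` converts summit tag counts
to tags per 10 million mapped reads per timepoint. Any library-size
scaling is equivalent up to a constant, which cancels in every downstream
correlation; fixing one unit keeps intensities comparable across
timepoints. `filter_by_background()` then retains a peak only if its
normalized intensity at at least one timepoint exceeds an independent
no-antibody control track at the summit.

The retained peak's per-timepoint count is the maximum summit count among
its group's members called at that timepoint (0 where a timepoint called
no member). With full alignment data one would re-count tags at the
retained summit in every timepoint; at desk scale the group maximum is the
faithful stand-in, and the synthetic generators produce subpeaks whose
counts are defined exactly this way.

# Colocalization and peak shape

`overlap_fraction()` counts a query peak as overlapping if its interval
shares at least one base with a subject interval (half-open); a
summit-in-interval mode is available for comparisons anchored on summits.
`summit_correlation()` is the plain product-moment correlation of paired
raw summit intensities and refuses degenerate input (fewer than 3 pairs,
zero variance) rather than returning `NaN`.

`composite_profile()` averages coverage in `step`-bp offsets (default 20)
over a `±window` (default 2000 bp) centered on a summit set — the
metapeak. Positions beyond any coverage step contribute 0, so profiles
near chromosome ends are attenuated rather than dropped.

Peak sharpness is quantified by `distance_to_quarter_max()`: the smallest
`d ≥ 0` at which the signal on *both* flanks (`summit ± d`) has dropped to
at most 25% of the summit signal. Two-sided is the default because a
"narrow peak" claim is symmetric; a one-sided mode (`sides = "either"`)
is provided. Peaks whose flanks never drop within `window` (default
1000 bp) are censored at the window and flagged; in `sharpness_cdf()`
censored peaks contribute mass only at or above the censoring point, so
cumulative fractions below it are unaffected. Raw step-function coverage
is used without smoothing: at the depths the statistic is meant for, the
25% crossing is insensitive to single-base noise, and smoothing would blur
exactly the discreteness the statistic measures.

# Kinetics

`cluster_timecourses()` performs agglomerative clustering with Euclidean
distance on per-row max-normalized intensity profiles, cut at `k`
clusters. Max-normalization makes clusters reflect kinetic *shape* rather
than amplitude, which is what a time-course heatmap groups visually; the
un-normalized mode is one flag away. Complete linkage is the default for
compact, balanced clusters; `k` defaults to 5 but is always user-set in
practice since no statistical model selects it here (deliberately out of
scope). Row order for heatmap export is the dendrogram leaf order.

`argmax_timepoint()` assigns each peak the earliest timepoint achieving
its maximum — ties go early deliberately, which is conservative for any
"the mark is maximal early" claim — and returns a histogram that always
sums to the row count.

# Differential accessibility

Region × sample read counts are modeled as negative binomial with
variance `mu + alpha * mu^2`. Library depth is normalized by
median-of-ratios size factors. Each region is tested by a conditional
exact test: conditioning on the total `S = K_A + K_B` of the two
per-condition count sums, the p-value is the probability of all splits of
`S` as likely or less likely than the observed one under the null
(moment-matched NB laws for each sum). Above `exact_cutoff` total counts
(default 1e5) a normal approximation to the conditional law takes over.

Dispersion is estimated in two layers: per-region method-of-moments
values (floored at 0) and a mean-dispersion trend `a0 + a1/mu` fitted by
Cox–Reid-adjusted maximum likelihood over all regions. The adjustment
matters: without it, profiling out per-condition means fitted from 2
samples each halves the apparent dispersion. By default every region is
assigned its trend value (`shrink_weight = 1`, full moderation). This was
a deliberate choice made after measuring the alternative: with two
replicates per condition the raw per-region estimates carry roughly one
degree of freedom, and mixing their noise into the test made it
anti-conservative (empirical type-I ≈ 0.06 at nominal 0.05), whereas full
moderation is calibrated. The weight is exposed for designs with enough
replicates to make per-region information worth using, and the raw
estimates ride along as an attribute. With a single sample per condition
a pooled dispersion is estimated from the per-region pair differences.

Independent filtering ranks regions by *total raw count across all
samples* — a statistic independent of the test statistic under the null —
flags the bottom fraction `f` (default 0.5), and applies
Benjamini–Hochberg only to the retained regions. Regions tied with the
smallest retained total are all retained, so the cut never splits an
equivalence class. The companion diagnostics are first-class outputs:
`filter_power_scan()` tabulates rejections over a grid of filter
fractions (0.30–0.70) and FDR thresholds, reproducing the
power-versus-threshold curve that justifies `f = 0.5` (power rises to
about 50% filtering, then over-filtering discards true positives);
`independence_diagnostic()` compares the unadjusted p-value histograms of
all/filtered/retained regions and reports a two-sample KS statistic
between "all" and "retained" — for inspection, not as a gate. The default
FDR threshold for reporting is 0.15.

# Nucleosome footprints

Paired-end MNase fragments carry the length of the DNA span protected by
the bound particle (~147 bp for an intact nucleosome). Only concordant
pairs with strict bounds `1 < length < 500` enter the analysis. A
fragment belongs to a peak set if its midpoint falls inside a peak
interval (half-open); midpoint assignment is unambiguous and standard for
MNase, with a full-containment mode by flag. Fragments are pooled across
peaks unweighted, so deep peaks contribute proportionally to their
fragment yield.

The protection-size distribution is a 1 bp-resolution histogram over
2–499 bp. Its mode is taken after convolution with a Gaussian kernel of
bandwidth 2 bp: a raw 1 bp argmax is noisy at moderate depth, while 2 bp
smoothing stabilizes the mode without displacing it (recovery is within
±1 bp at 20,000+ fragments across bandwidths 1–4).
`mode_shift_report()` compares two conditions by their modes and adds a
two-sample Kolmogorov–Smirnov test, because a 30 bp mode shift claim
deserves a distribution-level significance summary even though modes alone
suffice to describe it.

# Clinical endpoints

Immunohistochemistry DAB staining is scored 0–5 per fraction of tumor
cells; `final_score()` is the fraction-weighted sum, a number in [0, 5].
Marker pairs are compared by Pearson correlation over section areas
matched on (patient, area); pooling areas is the default and a per-patient
average is a flag, since both conventions are defensible.

Survival uses the Kaplan–Meier product-limit estimator and the two-group
log-rank test (delegated to the `survival` package; both are checked
against hand risk-table oracles in the test suite). Degenerate risk
tables — zero hypergeometric variance at every event time — carry no
information; observed equals expected there, and the statistic is
reported as 0 rather than an error.

`best_threshold_scan()` splits the cohort at each quantile of a
continuous expression marker (grid 25%–75% in 5% steps, both groups at
least `min_group = 10`), reports the split minimizing the log-rank
p-value, and *always* attaches a multiplicity warning plus the full scan
table: a scan-minimized p-value is optimistically biased, and the package
reproduces the procedure without endorsing the uncorrected number. The
test suite demonstrates the selection effect directly — on null cohorts
the mean scan-minimized p is roughly half the fixed-median-split p. Ties
at the cutoff go to the low group, making the split deterministic.

# Synthetic data: what it does and does not emulate

Each generator is seed-deterministic (the caller's RNG state is restored)
and emits objects/files that parse through the package's own I/O layer.

* `gen_coupled_cistrome()` — two peak sets with linearly coupled
  intensities (`B = slope·A + ε`, censored at 0), summit jitter, and
  controllable one-sided peak fractions. Defaults emulate the study's
  concordance structure: 95% of A peaks have a B partner, 53% of B peaks
  are B-only, and the generating correlation is 0.92. When a target
  correlation is given, the noise SD is derived from the population SD of
  the log-normal intensity law.
* `gen_coverage()` — per-peak Gaussian or triangular kernels of
  controllable width, scaled to peak intensity, with optional uniform
  background and integer rounding (tag pileups are integral).
* `gen_timecourse()` — kinetic classes as unimodal bumps in log-time
  peaking at designated minutes plus a flat class, log-normal amplitudes,
  multiplicative noise. The default mix (300 early / 150 late / 150 flat)
  reflects a time course in which most mark-bearing sites peak early.
* `gen_fragments()` — fragment lengths from a Gaussian mixture, rounded
  and rejection-truncated to (1, 500); midpoints uniform within peaks or
  genome-wide. Component SD defaults to 10 bp, a tightly digested
  mononucleosome ladder.
* `gen_counts()` — NB counts with log-normal region means (the
  low-count-heavy tail that motivates independent filtering), dispersion
  `alpha = 0.2`, and a configurable true-positive fraction with a
  fold-change applied post-treatment.
* `gen_cohort()` — a latent per-patient level drives both marker staining
  (with the configured pairwise score correlation, de-attenuated for
  area-level noise) and exponential survival with a hazard ratio between
  expression halves; censoring is independent uniform.

What the generators deliberately do not model: mappability and GC bias,
read-level sequence artifacts, spatial autocorrelation between
neighboring regions, replicate-level batch effects, non-proportional
hazards, and inter-marker antibody efficiency differences. Passing tests
on synthetic data therefore demonstrate the correctness and calibration
of the *statistics*, not robustness to every artifact of real
sequencing data.

# Numerical choices and degenerate inputs

* Tie-breaks are all deterministic: dedup winner → leftmost summit;
  time-of-maximum → earliest timepoint; distribution mode → smallest
  length; expression ties at a survival cutoff → low group.
* Empty peak/fragment/cohort inputs raise classed errors
  (`citfoot_degenerate_error`) rather than propagating `NaN`.
* The exact NB test enumerates all splits of `S` in log space with a
  log-sum-exp reduction; all-zero regions return p = 1 and fold-change 0.
* Coverage queries outside any step return 0, which also implements the
  "positions beyond chromosome bounds contribute 0" rule for composite
  profiles.

# Problem sizes

The shipped tests run the statistics at sizes chosen to make their
guarantees sharp but cheap: 200 random dedup instances up to 500 subpeaks
against an O(n²) oracle; 50 cistrome seeds of 2,000 peaks for correlation
recovery; 2,000-region count matrices for calibration, power and
diagnostics; 50,000 fragments for mode recovery and the 155→125 bp shift;
exhaustive-style small-cohort survival checks plus 40-seed null scans.
The whole suite completes in well under a minute on one CPU.

# Known limitations

* The consolidation step does not re-center summits after grouping; the
  winning subpeak's summit is used as called.
* The exact NB test conditions on moment-matched sums rather than the
  joint likelihood of all replicates; with many replicates a GLM-based
  test would use more information.
* `best_threshold_scan()` reports the optimized p-value uncorrected
  (matching the procedure it reproduces); the scan table is provided so
  users can apply a correction.
* The 1-vs-1 pooled dispersion assumes most regions are null; strong
  global signal inflates it, which is conservative.
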