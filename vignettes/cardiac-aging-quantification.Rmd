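---
title: "Quantifying cardiac aging phenotypes: models, parameters and design choices"
author: "cardioage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac aging phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

cardioage quantifies the phenotypic readouts of murine cardiac-aging
studies: surface-ECG conduction and repolarization intervals, per-nucleus
telomere fluorescence from quantitative FISH, echocardiographic derived
metrics, lifespan statistics, and two-group microarray differential
expression with gene-set enrichment. Every input type has a synthetic
generator with analytic ground truth, so the whole pipeline is testable
end-to-end without animal data. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not establish.

## The synthetic beat model and its ground truth

A simulated beat is the sum of five Gaussian deflections (P, Q, R, S, T)
placed at fixed offsets relative to the R peak; beats are laid down at a
jittered RR series, and sinusoidal baseline wander, optional mains
interference and white noise are added. Gaussians were chosen because every
landmark then has a closed form: a wave's onset/offset is defined at
center &minus;/+ 3&sigma; (99.7% of the deflection mass), and the time at which a
Gaussian T wave has declined by 90% of its peak-to-baseline amplitude is
exactly

> t90 = t_peak + sigma * sqrt(2 * log(10)) = t_peak + 2.1460 * sigma.

Default morphology (`ecg_wave_defaults()`): P 0.15 mV at &minus;28 ms
(&sigma; 4 ms), Q &minus;0.15 mV at &minus;6 ms (&sigma; 1.5 ms), R 1 mV at 0
(&sigma; 2 ms), S &minus;0.3 mV at +5 ms (&sigma; 1.5 ms), T 0.3 mV at
+28 ms (&sigma; 8 ms). These give PR = 40 ms, QRS = 20 ms and QT
&asymp; 55.7 ms — mid-range values for an anesthetized adult mouse — at the
2 kHz sampling rate typical of rodent telemetry and the noise conditions
used throughout the validation (white noise sd 0.05 mV, 0.3 mV wander at
0.3 Hz). What the generator deliberately does not emulate: respiratory
coupling beyond sinusoidal wander, T-wave alternans, ectopy, electrode
motion artifacts, and non-Gaussian wave asymmetry. Recovery results on
synthetic records therefore demonstrate correctness of the measurement
chain under its stated model, not robustness to every artifact class of
real telemetry.

## ECG measurement chain

`ecg_analyze()` runs band-pass (0.5–250 Hz Butterworth, forward–backward),
baseline-wander removal (zero-phase high-pass, default 1.5 Hz), wavelet
R detection, adaptive segmentation, delineation and interval/HRV summaries.

**Zero phase everywhere.** Every filter stage is either a forward–backward
IIR pass or a centered symmetric FIR, so no stage shifts fiducial times;
the test suite checks that a symmetric pulse's energy centroid moves by
less than one sample through each stage.

**R detection.** Undecimated (à trous) coiflet-4 detail coefficients are
computed at a dyadic scale matched to the murine QRS band
(`level = round(log2(fs / 125))`, i.e. 62.5–125 Hz at 2 kHz). The squared
detail magnitude is thresholded at a fraction (default 0.2) of the median
per-second block maximum — robust to amplitude drift and to a few
artifact-dominated blocks — and local maxima closer than a refractory
period of `0.5 × running-median RR` (floored at 30 ms) are pruned, keeping
the larger peak. Each surviving maximum is refined to sub-sample precision
by the vertex of the parabola through the three samples around it. Because
the analysis filters of a coiflet are only near-symmetric, the transform's
small group delay is measured at run time by pushing a Gaussian reference
pulse of the expected QRS width through the identical code path, and
subtracted; no hand-tuned alignment constants exist.

**Adaptive windows.** The P window is
`[R − 0.45·RR_prev, R − 0.05·RR_prev]` and the T window
`[R + 0.08·RR_next, R + 0.52·RR_next]`, clipped against a ±4 ms QRS guard
band and against the neighboring beat's windows (the fractions sum to less
than 1, so consecutive windows stay disjoint). Windows scale per beat with
the local RR, which is what keeps the chain usable across the 350–650 bpm
range.

**Baseline level.** The isoelectric reference is the median of the pooled
PQ segments (default 16–10 ms before each R) over *all* beats of the
record. A per-beat window median is biased at high heart rates — at RR
&asymp; 90 ms the P wave occupies most of the P window — while the PQ
segment is flat, and pooling across ~100 beats averages its noise to a
negligible level. Residual drift has already been removed by the high-pass,
so a record-level constant is appropriate.

**Fiducials.** P and Q onsets use a finite-difference slope threshold: the
smoothed wave's derivative is scanned back from the peak slope to where it
falls below a fraction (default 0.3) of that peak slope. S end is the first
crossing of the baseline after the S trough; T peak is the extremum of the
smoothed T window; T90 is the first decline to 10% of the peak-to-baseline
amplitude (the standard murine convention of "repolarized by 90%"; the
alternative reading, decline *to* 90%, is available via
`delineate_params(t90_mode = "to")`).

Two numerical devices make these estimators accurate:

1. *Gaussian self-calibration.* Low-pass smoothing broadens waves, which
   biases slope-threshold onsets and amplitude-crossing offsets. At run
   time the delineator pushes clean Gaussian pulses spanning &sigma; =
   0.6–18 ms through the actual smoothing kernel and measurement code,
   building a monotone map from measured offset to the true 3&sigma; /
   T90 convention, and applies it per beat. The correction is exact for
   Gaussian waves by construction and removes the need for any
   cutoff-dependent fudge factors.
2. *Isotonic crossing estimation.* Under correlated noise a raw "first
   crossing below the level" fires systematically early (a first-passage
   bias). All crossings are therefore located on the isotonic (monotone)
   regression of the relevant flank, which leaves clean flanks untouched
   and removes the bias on noisy ones.

**Measurement smoothing cutoffs.** The conventional 20 Hz Kaiser-window
FIR low-pass is the default of the exposed smoothing op
(`ecg_smooth_wave()`), and remains appropriate for display. For
*measurement*, murine P and T waves (&sigma; ~ 4–8 ms) carry substantial
energy above 20 Hz: a 20 Hz cutoff broadens them several-fold, and
although the self-calibration removes the resulting bias, the noise
amplification of deconvolving a heavy blur is irreducible. The delineator
therefore defaults to 70 Hz for P/T and 150 Hz around the QRS
(`delineate_params()`), which preserves morphology while still averaging
noise. All cutoffs are configurable.

**QC.** Any beat missing a wave, or whose landmarks violate
`P onset < Q onset < R < S end < T peak < T90`, is rejected with a reason
and excluded from summaries — never silently repaired. HRV is summarized
as SDNN and RMSSD, the minimal standard RR-variability pair.

Validation sizes: 20 records × 10 s across 350–650 bpm for interval
recovery (median |error| of PR/QRS/QT within 2 ms, R sensitivity/PPV
≥ 99%), chosen to exercise the full murine rate range at a few thousand
beats total.

## Q-FISH quantification

The imaging model: nuclei are non-overlapping discs (rejection-sampled
positions with a 3 px margin) with a uniform planted Cy3 intensity,
occupying a contiguous run of z sections at full intensity; DAPI marks all
nuclei and PCM1 is high only in cardiomyocyte nuclei; every voxel gets
Poisson shot noise; values are clipped to the 16-bit range. The noise-free
maximum projection of a nucleus equals its planted value, so the recorded
truth is exactly what an ideal pipeline should measure. Not emulated:
overlapping/touching nuclei, 3-D PSF blur, chromatic shift, bleaching, and
autofluorescent lipofuscin — per-nucleus recovery on these stacks shows
the measurement chain is unbiased, not that segmentation handles dense
tissue.

The measurement chain is maximum projection per channel; background
subtraction on Cy3; Otsu threshold on DAPI; 8-connected component labeling
with a minimum area (default 50 px) to drop debris; per-nucleus mean Cy3
(in arbitrary units of fluorescence, auf) and mean PCM1, with
cardiomyocyte classification by threshold on the latter (Otsu over the
per-nucleus means by default, a fixed threshold or an explicit manual
selection list — mirroring manual selection on real data — as overrides).

Numerical choices worth recording:

- *Background estimator.* The default is the image median rather than a
  low percentile. Under shot noise the projected background is the maximum
  of z Poisson draws; a p5 estimator sits in that distribution's lower
  tail and systematically under-subtracts, inflating per-nucleus means.
  With nuclei occupying a minority of the field the median estimates the
  background's central level, and its upward shift under projection
  largely cancels the same shift inside nuclei. The percentile is a
  parameter (`subtract_background(probs = )`).
- *Labeling.* Connected components are computed by column-run union-find
  under 8-connectivity; labels are renumbered 1..K and measurement is
  invariant to label order. Masks are applied read-only: intensity images
  are never modified.
- *No nucleus splitting.* The generator guarantees non-overlap; real
  overlapping nuclei would need watershed splitting and are a documented
  limitation.

Distribution comparisons use the exact rank-sum test (below); the
telomere shortening rate is `(mean_young − mean_old) / Δage` in auf per
month. Validation sizes: recovery on a default 256² stack (40 nuclei,
15 sections); detection power for a planted 20% intensity reduction on
100 seeded pairs of 384² stacks with 200 nuclei per group.

## Echocardiographic and metabolic metrics

All deterministic arithmetic, unit-annotated, exact against hand
computation: fractional shortening `100·(LVIDd − LVIDs)/LVIDd`; Teichholz
volume `V(D) = 7.0/(2.4 + D)·D³` (µl, D in mm) and the ejection fraction
derived from it; the cubed M-mode LV mass
`1.05·((LVIDd + LVPWd + IVSd)³ − LVIDd³)·0.8` with the corrected value
`0.8 × mass` (both reported, as both are conventionally quoted); OGTT area
under the curve by the trapezoidal rule (mg·min/dl); leptin/adiponectin
and heart-weight/body-weight ratios. Non-physiological inputs (LVIDs ≥
LVIDd) warn rather than error, since real M-mode traces occasionally
produce them.

## Lifespan statistics

Kaplan–Meier estimation and the logrank test are delegated to the
`survival` package and re-exposed as tidy tables; the test suite holds
them against independent brute-force oracles (direct product-limit
computation; direct O−E/V summation with hypergeometric variance).
Censoring is supported even though full-mortality cohorts are the common
case. "Maximum lifespan" has no standard definition; the default estimate
is the mean of the top decile of event times (the usual choice in aging
studies), with the single longest survivor available as an alternative,
and percent differences are reported against a named reference group.
The Gompertz cohort generator defaults (shape 0.01/day; rates 1.9e−6 and
1.25e−7) give a control mean lifespan near 800 days and a ~34% higher
mean in the long-lived group, i.e. a realistically sized longevity effect
at realistic murine lifespans. Null calibration uses 1000 seeded
identical-parameter cohorts of 50 animals per group.

## Transcriptome stage

The stage consumes a *normalized* expression matrix (vendor normalization
such as SST-RMA is upstream and out of scope). Fold change is the
linear-scale group-mean ratio (log2 input exponentiated first); the
per-gene p-value is an unpaired equal-variance two-sample t test on the
log2 values — equivalent to two-group one-way ANOVA — with Welch as an
option, and no multiple-testing correction, matching common
fold-change-screen practice; the screen is the FC and p cutoffs jointly.
The DE filter is inclusive (`FC ≥ fc_min` or `≤ 1/fc_min`, `p ≤ p_max`).
Published array screens quote either 1.5 or 2 as the fold-change cutoff;
the default is 2, the value the quoted transcript counts correspond to,
and the cutoff is an explicit argument. Enrichment is the one-sided
Fisher exact test (hypergeometric upper tail) per gene set against the
tested universe, with Benjamini–Hochberg adjustment reported alongside
the raw p — adjustment applies to enrichment only, and is labeled as
such. Heatmaps are row z-scores (constant rows excluded with a warning)
with agglomerative average-linkage clustering on Euclidean distance
(distance configurable) for rows and columns, plus per-category mean
z-score matrices. The planted-effect validation uses 2000 genes, 100
planted at |log2FC| = 2, residual sd 0.1, n = 3 per group, 100 seeds.

## Statistical core

Group comparisons are gated on Shapiro–Wilk normality (α = 0.05 per
group): two groups use the unpaired Student t test, three or more one-way
ANOVA with Tukey HSD (Tukey–Kramer under unequal n); if any group fails
the gate the comparison falls back to a rank test (exact Wilcoxon or
Kruskal–Wallis) with an explicit warning, so the gate is never a dead
end. The Wilcoxon rank-sum p-value is exact by full enumeration of rank
assignments whenever `choose(n + m, n) ≤ 1e5` — valid under ties via
midranks, with the two-sided p as twice the smaller tail capped at 1 —
and otherwise uses the tie- and continuity-corrected normal
approximation. Significance markers follow the conventional
\*/\*\*/\*\*\* thresholds at 0.05/0.01/0.001.

## Determinism and the demo

Every generator is a pure function of its arguments and an explicit
integer seed; nothing depends on ambient RNG state. `run_demo()` builds
synthetic cohorts (two genotypes × two ages), runs every stage, writes
all readouts as CSV/JSON together with a provenance sidecar (package
version + config hash), and is bit-identical across runs with the same
seed; each stage derives its own sub-seed, so perturbing one stage's seed
perturbs only that stage's outputs.

## Known limitations

- The delineator assumes locally Gaussian-like wave flanks for its
  calibration; grossly asymmetric or biphasic T waves would need a
  different correction model.
- Q-FISH quantification does not split touching nuclei and quantifies
  per-nucleus mean intensity, not per-telomere spots or absolute kb.
- The DE stage models two groups only; multi-factor designs belong in
  dedicated modeling packages.
- The rank-test enumeration budget (1e5 assignments) bounds exactness to
  small samples; beyond it the normal approximation is used and agrees to
  within 0.01 by n = m = 20.
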