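---
title: "Fusing functional and effective EEG connectivity: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing functional and effective EEG connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfuse)
```

## The problem

Group differences in scalp EEG can live in two distinct kinds of coupling:
*functional* connectivity — undirected statistical dependence such as phase
synchronization — and *effective* connectivity — directed, Granger-causal
influence of one region's signal on another's. A classifier built on one
view alone can miss what the other sees. `eegfuse` implements both
estimators on a common wavelet decomposition, fuses them into one feature
table, and validates the whole chain on synthetic cohorts with known ground
truth.

The intended data are feedback-locked event-related recordings: one
`epoch_set` per subject (channels x samples x trials), cleaned and epoched
upstream. Preprocessing — filtering, re-referencing, artifact rejection —
is deliberately out of scope; inputs are assumed analysis-ready, and the
container records no reference scheme. Sample `i` maps to time
`(i - onset)/fs`; every window in the package is half-open `[t0, t1)`, which
removes off-by-one ambiguity from all window averages (a 1.2 s statistical
window at 256 Hz contains exactly 307 samples).

## Time-frequency decomposition

`build_wavelet_bank()` pairs 50 linearly spaced center frequencies
(3.9–40 Hz) with 50 linearly spaced cycle counts (3–11.4), so temporal
resolution tightens with frequency: the time-domain SD of each wavelet is
`cycles / (2 pi f)`. Wavelets are unit-energy, truncated at 3.5 SD, and
applied as same-length zero-padded convolution, so a 768-sample epoch yields
a 50 x 768 complex matrix per trial and channel. Edge samples are
contaminated by the padding; the statistical grid is therefore restricted to
−0.2…1.0 s, keeping the margins out of every test while the full-length map
is still available for display.

Group maps are compared pixelwise with pooled-variance two-sample t tests
(the plain "t-test", not Welch). Pixels with two-sided `p < 0.01` form
clusters under 4-neighborhood connectivity (adjacent in time or in
frequency, same t sign); the cluster statistic is its pixel count. The null
distribution collects the largest cluster over random relabelings of the
subjects, and observed clusters are kept iff their size exceeds the
`(1 - alpha)` percentile of that null (family-wise alpha 0.05 by default).
Two implementation details are worth stating because conventions vary:

* clusters are formed separately for positive and negative t, the usual
  neurophysiology practice, so opposite-signed effects never merge;
* permutations are drawn against a canonical content-ordering of the pooled
  maps, which makes the test exactly label-symmetric — swapping the two
  group arguments flips the sign of the t map and changes nothing else.

## PLI

For a channel pair the phase difference at a pixel is the argument of
`coef_a * Conj(coef_b)`; the phase lag index is the absolute trial mean of
its sign, with `sgn(0)` contributing 0. A consistent nonzero lag gives 1;
instantaneous mixing of independent sources (volume conduction) gives
sign-balanced differences and a value near the `|mean of M signs|` null
band, which is why PLI is preferred over coherence here. The matrix is
averaged over the bank frequencies inside the theta band, inclusive ends
(4–7 Hz keeps 4 of the 50 frequencies), and the samples with
`0.1 <= t < 0.6` s; averaging jointly over the pixel set or frequency-then-
time is identical for an arithmetic mean. The same wavelet coefficients
feed the power analysis and PLI, so there is exactly one filter definition
in the package.

## MVAR and PDC

Each subject's windowed trials are treated as independent realizations of
one stationary MVAR process. Per trial the window is mean-centered per
channel and lag covariances `R(m) = <X(n) X'(n + m)>` are computed with an
unbiased divisor (the number of contributing pairs — at 128-sample windows
the biased variant visibly shifts small-lag estimates); the ensemble
average over trials enters the multivariate Yule–Walker system
`C(k) = sum_r A_r C(k - r)`, `k = 1..p`, solved as one symmetric
block-Toeplitz system (equivalent to the Levinson–Wiggins–Robinson
recursion on well-conditioned inputs; the package refuses systems with
condition estimates above 1e12 rather than returning garbage). The
innovation covariance is `C(0) - sum_r A_r C(r)'`, symmetrized.

The order is chosen by `BIC(p) = ln det(Sigma_W) + p N^2 ln(n_eff)/n_eff`
with `n_eff` the total windowed sample count across trials; ties go to the
smaller order. The published analysis of the clinical dataset fixed order
9; `pipeline_config(mvar = list(order = 9))` reproduces that choice, while
`"auto"` takes the median of per-subject BIC optima.

PDC at frequency `f` uses `A(f) = I - sum_r A_r exp(-2 pi i f r / fs)` and
normalizes each column by its Euclidean norm, so `sum_i PDC(i,j,f)^2 = 1`
exactly — the package asserts this identity to 1e-10 on every fitted model.
Band averages use a 0.25 Hz grid over 4–7 Hz (13 points); halving the step
changes band means by less than 1e-3 on test models.

Edge significance comes from surrogate data: per surrogate, every channel
of every trial has its Fourier phases independently randomized (Hermitian
symmetry preserved, so amplitude spectra are exact), the MVAR is refitted
and the band PDC recomputed; the per-edge threshold is the `(1 - alpha)`
empirical quantile. Independence per channel is essential — it is what
destroys cross-channel causal structure while preserving each channel's
spectrum. Thresholded matrices (sub-threshold edges zeroed) are the default
feature source; `surrogate = list(enabled = FALSE)` feeds raw band averages
instead, since the original analysis does not state which variant entered
classification.

## Feature fusion and classification

For `N` channels the table holds `N(N-1)/2` PLI features then `N(N-1)` PDC
features in fixed row-major order (190 + 380 = 570 at 20 channels).
Features are ranked by the two-class Fisher score
`F = (mu1 - mu2)^2 / (s1^2 + s2^2)` with unbiased class variances; the
degenerate cases need a rule, so equal means with zero variances score 0
and distinct means with zero variances are capped at 1e12.

Three strategies mirror the published design: top-N PLI (N = 1..50), top-N
PDC, and all splits `L = n + m` (L = 2..50) of top-n PLI plus top-m PDC.
Classification is a LOOCV linear SVM (`C = 1`, the libsvm default, since no
value is published), features standardized by each training fold's mean and
SD. Two ranking policies are provided: the default recomputes Fisher scores
inside every training fold, so the held-out subject never informs
selection; `rank_mode = "whole_data"` ranks once on the full table,
mirroring the common published practice (which leaks the test subject into
selection and typically inflates accuracy). Reported "selected features"
are the full-data ranking at the winning size — the final-model convention.
Sensitivity and specificity treat the patient-like group as positive
(clinical convention); AUC pools the per-subject decision values across
folds.

Significance of an accuracy uses the modified permutation test: each
permutation shuffles every feature column independently (destroying
feature–label *and* feature–feature alignment), reruns the full LOOCV, and
records the null accuracy. The default p is add-one-smoothed,
`(1 + #{null >= observed}) / (1 + n_perm)`, so it can never be exactly zero;
the raw ratio is available for fidelity to the original definition. Group
differences of the winning features use two-sample rank-sum tests —
the groups are independent, so the signed-rank variant would be
inapplicable — with Benjamini–Hochberg correction across the selected set.

## The synthetic generator: what it emulates, and what it does not

`simulate_two_group_study()` builds cohorts in which the truth is known:

* a shared stationary background MVAR model (default: order-2 per-channel
  resonances near 5.5 Hz plus a weak ring of lag-1 cross couplings, unit
  innovation covariance, 20-channel montage, 256 Hz);
* per-subject heterogeneity as additive Gaussian coefficient jitter
  (SD 0.02 by default), the simplest mechanism that produces realistic
  between-subject variance; stationarity is enforced by halving the jitter
  on retry, and generation fails loudly rather than emitting an unstable
  subject;
* group effects as directed lag-1 coefficient deltas applied to one group
  only — ground truth for PDC;
* superposed narrow-band oscillator pairs whose phase lag is consistent
  (Gaussian jitter) in the strongly coupled group and uniform in the other —
  ground truth for PLI; superposition rather than replacement lets one
  dataset carry both kinds of truth at once;
* optional instantaneous mixing to emulate volume conduction;
* the epoch geometry of the target recordings: 48 trials of 768 samples at
  256 Hz with onset at sample 385, 30 subjects per group by default.

Everything is a deterministic function of the seed, and the planted truth
travels in the manifest bundle, never into any estimator. The generator
does **not** attempt head-model forward simulation, ERP waveform morphology,
non-stationarity within epochs, or realistic noise spectra; passing tests on
these cohorts demonstrates that the estimators recover the kinds of
structure they target, not that clinical accuracies transfer.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle where one
exists and against calibration simulations elsewhere; the sizes below were
chosen to make each check sharp at desk scale.

* **Analytic oracles.** Yule–Walker fits are checked against covariances
  generated in closed form from a known VAR(1) (Lyapunov equation for
  `C(0)`, `C(m) = A C(m-1)`), recovery to 1e-6; PDC against hand
  substitution of the bivariate example `A_1 = [[0.5, 0], [0.3, 0.5]]` at
  `f = 0` (entry `0.3/sqrt(0.34)`), to 1e-12.
* **Recovery.** A 3-channel order-2 model estimated from 100 trials x 500
  samples recovers all coefficients within 0.05; BIC recovers a generating
  order of 3 in at least 90% of 50 runs at 30 trials x 400 samples.
* **Calibration.** The cluster test is run on 100 null cohorts (10 + 10
  maps, 200 permutations); its family-wise false-positive rate must fall in
  the binomial 95% band around 0.05. The classifier permutation test is run
  on 100 pure-noise cohorts of 12 subjects (200 permutations). With 12
  subjects the LOOCV accuracy lives on a 13-point lattice, so the
  permutation p is exactly valid but *conservative* at small alpha — a
  property of the procedure, not a bug. Its uniformity is therefore checked
  at quantiles the lattice can resolve (0.25 and 0.5, binomial bands), plus
  an upper bound at 0.05 guarding against anti-conservativeness.
* **End-to-end ordering.** Twenty-five seeded studies at 20 + 20 subjects on
  a 10-channel montage, 48 trials of 1.5 s, with moderate planted effects —
  directed deltas of 0.08 on two edges (patient group), one theta pair with
  0.9 rad phase jitter in the control group versus uniform lag in patients,
  oscillator amplitude 1.0 — chosen by pilot so single-strategy accuracies
  land in a non-saturated 65–100% range. The fused strategy must match or
  beat both single-estimator strategies in at least 80% of runs. Selection
  grids are reduced (N, L up to 8) to keep each study near fifteen seconds.

`scripts/acceptance.R` recomputes all of these quantities from scratch at a
caller-supplied seed.

## Numerical choices and degenerate inputs

* Exact zeros in phase differences contribute `sgn(0) = 0`; they are
  measure-zero in floating point but arise exactly for duplicated channels.
* Zero pooled variance in a t-test pixel gives `t = 0` when means agree
  (identical groups produce an all-zero map, not NaNs).
* Zero training-fold SD during standardization is replaced by 1, leaving a
  constant feature constant instead of dividing by zero.
* All-identical feature values in the group comparison give `p = 1` by
  convention.
* Estimated MVAR models that are marginally non-stationary warn rather than
  fail — finite-sample fits of near-unit-radius processes land there
  routinely — while *simulation* from an unstable model is an error.
* Surrogate thresholds below 100 draws and permutation nulls below 100 are
  refused as unstably quantiled.

## Known limitations

* PDC here is the classic column-normalized variant; generalized (noise-
  weighted), renormalized, and DTF alternatives are out of scope, as are
  time-varying (adaptive) MVAR estimators.
* The MVAR window is treated as stationary; the 0.1–0.6 s post-onset window
  is short enough that this is conventional, but genuinely transient
  dynamics are averaged.
* Whole-dataset feature ranking (`rank_mode = "whole_data"`) reproduces a
  common published workflow but is optimistically biased; the default
  within-fold mode is the defensible estimate.
* Accuracies obtained on synthetic cohorts say nothing quantitative about
  clinical data; they validate machinery, not effect sizes.
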