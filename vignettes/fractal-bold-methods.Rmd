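---
title: "Fractal scaling analysis of BOLD fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal scaling analysis of BOLD fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalbold)
```

## The signal model

A temporal fractal is a time series with no dominant time scale: its
one-sided power spectral density follows a power law,

$$|A(f)|^2 \propto c \cdot f^{-\beta},$$

so the log-log spectrum is a straight line with slope $-\beta$. The
spectral index $\beta$ determines the signal class: $\beta < 1$ is
fractional Gaussian noise (fGn), a stationary process with constant
variance; $\beta > 1$ is fractional Brownian motion (fBm), nonstationary
with variance growing over time. The classical Hurst exponent is
class-dependent — $H = (\beta+1)/2$ for fGn, $H = (\beta-1)/2$ for fBm,
both in $(0, 1)$ — which means two processes of different class can share
an $H$ while their spectral indices differ by exactly 2. To avoid that
ambiguity the pipeline reports the *extended* Hurst exponent

$$H' = \frac{\beta + 1}{2} \in (0, 2),$$

which maps fGn to $(0, 1)$ and fBm to $(1, 2)$ in one scale. `classical_hurst()`
is provided for interoperability with the class-conditional convention.

## The estimator

`estimate_hurst()` composes two steps:

1. **Welch PSD** (`welch_psd()`): the series is cut into 8 segments with
   50% overlap — segment length $L = \lfloor 2N/9 \rfloor$, the exact
   arithmetic for 8 half-overlapping windows; a 900-frame run at
   TR = 1 s gives $L = 200$ and a frequency resolution of 0.005 Hz.
   Each segment is mean-removed, Hann-tapered, and its one-sided
   periodogram density accumulated; the DC bin is excluded.
2. **Log-log slope** (`fit_scaling()`): ordinary least squares of
   $\log_{10}$ power on $\log_{10}$ frequency over the band from
   0.01 Hz (BOLD below that is dominated by scanner drift and residual
   physiology) up to the Nyquist bin. $\beta$ is the negative slope;
   the intercept is reported in base 10 at $f = 1$ Hz.

Only the window count and overlap are prescribed by the estimation
tradition this follows; the taper, per-segment mean removal and the upper
band edge are configuration choices exposed as arguments. Numerical
conventions: the band test uses a $10^{-12}$ frequency tolerance so a bin
landing exactly on 0.01 Hz is kept; bins with nonpositive power inside
the band are excluded with a warning, and fewer than 4 usable bins is an
error; a constant series is an error (zero spectrum has no slope), never
$H = 0$. The class boundary $\beta = 1$ is assigned to fBm — the
conservative choice for anything downstream that treats fBm as
"variance may grow". Scaling a series by $k$ leaves $\beta$, $H'$ and the
class unchanged and shifts the intercept by $2\log_{10} k$ (asserted in
the tests).

`voxelwise_hurst()` applies the estimator to every in-mask voxel of a 4D
volume, vectorized across voxels (one FFT call per segment batch), so the
result cannot depend on voxel order. Out-of-mask and constant voxels are
`NaN` sentinels; ROI reductions (`roi_mean()`) skip sentinels and report
how many they skipped.

## Companion measures

ALFF (`alff()`) is the amplitude-spectrum sum over the full-length
discrete-Fourier bins inside 0.01–0.08 Hz, with amplitudes scaled
$2|X_k|/n$ so a bin-aligned sinusoid of amplitude $a$ contributes $a$;
"bandpass filtering" is frequency-domain band selection, and no Welch
averaging is involved. Temporal SD (`temporal_sd()`) is the sample
standard deviation. Spatial smoothing (`smooth_gaussian()`, default
5 mm FWHM, applied before the maps) is separable per-axis Gaussian
convolution with $\sigma$ converted to voxel units per axis and reflect
padding — documented because map edges feed ROI means; the kernel is
truncated at $4\sigma$ and renormalized, so constants are exactly
preserved and interior mass is conserved.

A note on ALFF comparisons at fixed variance: when two series are
normalized to equal variance, a steep power-law series holds much of its
power *below* the 0.01 Hz band edge, so its in-band amplitude sum exceeds
white noise clearly in the mean but not in nearly every paired draw. The
positive voxelwise association between $H'$, ALFF and SD seen in real
BOLD arises because variance itself grows with low-frequency power — the
phantom reproduces it for that reason (below), not through per-voxel
variance normalization.

## Motion quality control

Framewise displacement uses the Power convention,
$\mathrm{FD}_t = \sum_i |\Delta d_i| + r \sum_j |\Delta \theta_j|$ with
head radius $r = 50$ mm (configurable); the tradition names FD without
fixing a formula, so the convention is configuration, not a fidelity
claim. Exclusion removes a subject if *any* run's mean FD exceeds
0.15 mm strictly — a run at exactly the threshold stays. Motion matching
(`motion_match()`) then iteratively removes the included subject with the
greatest rest-condition mean FD (ties broken by ascending subject id, so
the algorithm is deterministic) until a paired two-sided t-test on
per-subject condition means is no longer significant at $\alpha = 0.05$;
per-subject condition FD is the unweighted mean over that condition's
runs. The removal order is logged. Degenerate cases: identical all-zero
differences terminate with $p = 1$; a constant nonzero difference cannot
be matched by removal and errors; fewer than 3 remaining subjects errors.

## Inference

`network_stats()` reduces the 4 runs per condition to subject-level
means, then runs a two-sided paired Student's t-test per region with the
fixed sign convention movie minus rest, and the paired Cohen's
$d = \bar{d}/s_d$. Identically zero differences return $p = 1, d = 0$ by
convention rather than `NaN`. The Holm step-down correction is applied
over the seven-network family only; the whole-gray-matter test is a
single planned comparison and is reported uncorrected (both raw and
"adjusted" columns carry its raw value). Holm is delegated to
`stats::p.adjust`; the test suite checks it against an independent
sequential-rejection oracle.

## Reliability

`icc_2_1()` implements ICC(2,1) — two-way random effects, absolute
agreement, single measures — from the mean squares of the two-way
decomposition:

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

with runs as raters. Absolute agreement matters: a constant added to one
run lowers the ICC, a global constant does not (both asserted).
Interpretation bands are poor < 0.4, fair 0.4–0.59, good 0.6–0.74,
excellent ≥ 0.75; the conventional printed bands leave 0.74–0.75
ambiguous and this package assigns 0.75 upward to excellent. Confidence
intervals resample *subjects* with replacement (1,000 replicates,
percentile method); replicates with degenerate tables are dropped and
counted. For the between-condition ICC difference, one subject resample
is applied to both condition tables per replicate — sharing the resample
preserves the within-subject pairing, which is the point of comparing
conditions on the same cohort; the difference is significant iff the
percentile CI excludes 0. Subjects missing any run are dropped listwise
per condition by `rater_table()`.

## Stimulus features

Brightness is the per-frame mean luminance (Rec. 601 weights
0.299/0.587/0.114 for 3-channel input — the upstream extraction tools do
not document their exact weights, so this is flagged as a convention).
Audio RMS and zero-crossing rate use 1.0 s windows with 1.0 s hop by
default, chosen so the feature series has a sampling rate commensurate
with TR; window starts follow a floor convention. ZCR counts strict sign
changes with zero treated as positive (touching zero is not a crossing),
giving values in $[0, 1]$. All three series feed `feature_hurst()`, the
same estimator as the BOLD data.

## What the synthetic generator emulates

`synthesize_power_law()` uses spectral synthesis: independent complex
Gaussian Fourier coefficients with amplitude $\propto f^{-\beta/2}$,
Hermitian symmetry, zero DC (the $f = 0$ amplitude is undefined under a
power law), inverse FFT, exact rescale to the requested sample variance.
This matches the PSD-based estimator's own model directly; exact-
covariance fGn synthesis (Davies–Harte circulant embedding) would be a
reasonable alternative for time-domain estimators but is not needed
here. Everything is bit-reproducible given a seed.

The phantom (`phantom_design()` / `phantom_roi_hurst()`) emulates the
study conditions this pipeline is built for: ~900-frame runs at TR = 1 s,
4 runs in each of rest and movie-watching, 24 subjects by default, and a
16×16×8 voxel grid as a desk-scale stand-in for a whole-brain
acquisition, with a 512-voxel labelled core (64 voxels per region: one
non-network gray-matter region plus the seven canonical networks) inside
a white-noise background. Rest-condition $H'$ levels sit in the 0.69–1.24
range observed for cortical BOLD, and the default movie-minus-rest
effects are +0.014 in non-network gray matter, +0.096 visual, +0.022
somatomotor, +0.026 dorsal attention, −0.012 frontoparietal, −0.010
default network, and zero in ventral attention and limbic.

Variance components, and why each exists:

* **Subject jitter** (`subject_beta_sd = 0.05` on $\beta$, i.e. 0.025 on
  $H'$), shared across a subject's runs and conditions — between-subject
  variance, without which test-retest ICC is undefined.
* **Run jitter** (`run_beta_sd = 0.03` on $\beta$) — run-to-run state
  variability. With 64-voxel ROIs the pure estimation noise of a region
  mean is only ~0.004 in $H'$, which alone would push ICC near 1; a
  run-level component of this size places ICC in the good band
  (~0.6–0.75) that test-retest studies of $H$ report, and is the
  realistic attribution (arousal and vigilance drift between runs).
* **White-noise admixture** (`noise_fraction = 0.05` amplitude fraction
  per voxel) — breaks exact power-law behavior the way residual thermal
  noise does. The level is deliberately low: the estimator's response to
  $\beta$ flattens visibly once the white floor reaches the upper fit
  band (at an amplitude fraction of 0.2 the recovered region effects
  shrink several-fold at the high-$H'$ end), and heavily cleaned,
  smoothed BOLD is not white-noise dominated.
* **Variance scaling**: voxel spectra share a common high-frequency
  density instead of a common variance, so SD and ALFF grow with $H'$
  across voxels as they do in real data.

All jitters are drawn from a single RNG stream per design; per-run
derived seeds are used only for the bulk voxel-noise streams. (Drawing
each run's few jitter values under its own consecutive-integer seed left
detectable correlation between streams, which masqueraded as spurious
condition effects in null regions — a cautionary note worth keeping in
the record.)

The generator does *not* emulate hemodynamic response shapes, spatial
autocorrelation of noise, physiological confounds, or condition-specific
motion artifacts. Passing tests on the phantom therefore show that the
estimator chain and inference are correct under the stated signal model
at desk scale — not that real acquisitions satisfy that model.

Motion tables (`synthesize_motion()`) are built backwards from the FD
target: the FD series itself is generated as a power-law process scaled
to the target mean (coefficient of variation 0.4, floored at 5% of the
mean so FD stays positive), then split across the six parameter channels
with random nonnegative weights and signs so the Power-convention FD of
the table reproduces it exactly; default targets (mean FD 0.12 mm,
`fd_beta = 0.2`, hence FD-trace $H'$ near 0.5–0.6) mirror compliant
adult cohorts. Stimulus arrays (`synthesize_stimulus()`) put a power-law
brightness course on uniform frames (default $\beta = 1.588$, i.e.
$H' \approx 1.29$) and amplitude-modulate a white audio carrier with a
power-law one-second envelope (default $\beta = 0.68$, $H' \approx 0.84$);
the ZCR of a white carrier is not separately controllable and sits near
the uncorrelated level.

## Problem sizes and runtime choices

The test suite and the analysis scripts run everything at the scale the
generator defaults define: estimator calibration at $n = 900$ with 200
realizations per target index; phantom cohorts of 24 subjects × 8 runs
on the 16×16×8 grid (about 20–25 s per cohort, all-voxel Welch included);
reliability simulations at 200 subjects × 4 raters; bootstraps at 400–1,000
replicates. The heavy loops are vectorized across voxels and segments via
matrix FFTs (`mvfft`), which is what makes whole-cohort simulation
practical in plain R.

## Known limitations

* The estimator's small positive bias at steep slopes (~0.02 in $H'$ at
  $\beta = 2$, from segment-level leakage) is characterized in
  `analysis/01_estimator_calibration.R` but not corrected.
* The Welch band uses linearly spaced bins, so the OLS slope is
  effectively weighted toward high frequencies; that matches the method
  being modelled, but log-binned or weighted variants would behave
  differently at very low $\beta$ resolution.
* `motion_match()` assumes the condition gap is carried
  disproportionately by high-rest-FD subjects; a uniform offset across
  subjects cannot be matched by removal and ends in an error by design.
* ICC bootstrap CIs are percentile-method only; BCa would shift
  coverage slightly for skewed ICC distributions.
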