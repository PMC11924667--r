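---
title: "Systemic-physiology-augmented fNIRS: correction models and test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systemic-physiology-augmented fNIRS: correction models and test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spafnirs)
```

## The problem

Continuous-wave fNIRS measures cortical oxy- and deoxyhemoglobin (HbO, HbR)
concentration changes optically through the scalp. At the single-subject
level, the evoked cortical response is small compared with hemodynamic
fluctuations of non-neural origin: superficial (scalp) blood flow and systemic
physiology — heart rate, respiration, SpO2, skin conductance, peripheral
perfusion, temperature — all modulate the optical signal. In auditory
paradigms the problem is compounded by the depth of auditory cortex and by
stimulus-evoked autonomic reactions that are time-locked to the task itself.

`spafnirs` implements a single-subject analysis in which the same multi-session
recording is fit with six GLM nuisance-correction models and the resulting
beta estimates are compared on accuracy (RMSE, recovery of known simulated
amplitudes) and on test-retest reliability (ICC(3,k) across sessions):

| label | nuisance regressors |
|---|---|
| `none` | — |
| `physio` | six conditioned peripheral signals |
| `ss` | short-channel means (one per chromophore) |
| `ss_physio` | union of the two |
| `ss_physio_lag` | per-channel lag-optimized physiology + short channels |
| `ss_tcca` | selected tCCA components + short channels |

Every design also contains a speech column, a silence (control) column — both
the canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 6) convolved
with a 3 s boxcar — and an intercept. No drift terms are added because the GLM
is fit on the unfiltered signal and estimated by plain OLS (no pre-whitening
or pre-coloring), so slow structure is deliberately left to the nuisance
regressors.

## The two preprocessing paths

Raw dual-wavelength intensities are converted to optical density
(`OD = -ln(I/mean(I))`), channels with a scalp coupling index below 0.7 are
pruned (the SCI is the inter-wavelength correlation of FIR high-passed OD,
cutoff 1.35 Hz, transition bandwidth 0.1 Hz, computed at the native 5.1 Hz
rate — at the 0.6 Hz analysis rate that cutoff would not exist), and OD is
inverted to HbO/HbR with the modified Beer-Lambert law (partial pathlength
factor 0.1, as configured for this montage; extinction coefficients from the
standard Gratzer/Prahl tabulation at 760/850 nm, converted to natural-log,
mm, µM units since the tabulated source is not named in the protocol).

* **GLM path**: resampling to 0.6 Hz with an anti-aliasing low-pass at 80% of
  the target Nyquist, and *nothing else* — no bandpass, no motion correction,
  no short-channel subtraction. A test asserts the GLM input is bit-for-bit
  the resampled MBLL output.
* **Block-averaging path**: TDDR motion correction (robust Tukey-biweight
  reweighting of the temporal derivative, tolerance 1e-9 on the location
  estimate), least-squares short-channel subtraction (reference = mean of
  surviving short channels per chromophore; the protocol does not specify
  nearest-channel vs mean, and the mean is the lower-variance choice), then a
  0.02–0.4 Hz zero-phase bandpass. This path stays at the native rate: the
  0.4 Hz band edge exceeds the 0.3 Hz Nyquist of the analysis rate, so the
  band and the 0.6 Hz grid are mutually exclusive by construction. Epochs of
  −1 to +15 s around each onset are baseline-corrected on the pre-onset
  interval and averaged with a 1.96 × SEM confidence band (the normal
  approximation; the source protocol does not state its CI method).

## Physiology conditioning, lags, tCCA

The six peripheral signals arrive at 500 Hz. GSR is low-passed at 5 Hz at the
native rate; each signal is then anti-alias decimated (block means to an
intermediate ~10 Hz grid, low-pass at 80% of the target Nyquist), linearly
interpolated onto the fNIRS analysis axis, and z-scored.

The lag model searches delays of 0–30 s per channel and signal, maximizing the
signed Pearson correlation between the delayed regressor and the channel on
their overlapping support, with ties broken toward the smaller lag. The grid
step defaults to one analysis-rate sample (1/0.6 ≈ 1.67 s) because the GLM
operates on that grid; a finer sub-sample search is available through
`lag_config(step = )`. A signed maximum is used (an absolute-value option
exists) since the sign of a nuisance coupling is carried by its beta.

The tCCA model embeds delayed copies of each physiology signal (0–30 s at the
analysis-rate step, mirroring the lag-search range) after a 0.5 Hz low-pass at
the native rate, and computes a ridge-regularized CCA (ridge 1e-8; the
embedded copies are nearly collinear) against the full long-channel matrix,
both chromophores. Components with canonical correlation ≥ 0.3 enter the
design. **Selection is cross-validated by default**: with ~114 embedded
regressors and only 720 analysis samples, the largest *in-sample* canonical
correlation between independent data sets is ≈ 0.65 purely from overfitting,
so thresholding it would admit spurious components on every run. The weights
are therefore fit on the first half of the recording and the selection
correlation is evaluated on the second half; under independence this
correlation is approximately N(0, 1/√360) and essentially never crosses 0.3,
while a genuinely shared component still validates at ρ ≈ 1
(`tcca_config(validate = "insample")` restores the literal in-sample rule).
With the default synthetic coupling gains the validated correlations sit
around 0.1, so the tCCA model typically reduces to the short-channel model —
a conservative, honest outcome on these study conditions.

## Denoising and reliability

Denoised series are `Y_filtered = Y_raw − Σ β_g X_g` over the selected
nuisance groups, with betas always taken from the richest simultaneous fit
containing those groups (`ss_physio` for the physiology/short-channel
variants, `ss_physio_lag` and `ss_tcca` for theirs); stimulus and intercept
contributions are never subtracted. Because the groups were estimated jointly
by OLS with an intercept, denoising can only reduce per-channel variance, and
refitting a stimulus-only GLM on the denoised series reproduces the
full-model stimulus betas exactly — both are asserted in tests.

Reliability is ICC(3,k) — two-way mixed model, consistency, average across
raters — with sessions as targets, ROIs as raters, and speech-condition
ROI-level betas (inverse-standard-error-weighted channel averages) as
ratings: `ICC = (BMS − EMS)/BMS`. Bands are left-closed: poor < 0.40, fair
[0.40, 0.60), good [0.60, 0.75), excellent [0.75, 1.00]. Session variances use
the n−1 sample variance. Model RMSEs are compared by paired t-tests with Holm
correction (a deliberately simple stand-in for estimated-marginal-means post
hocs, whose model structure is not specified in the protocol). Beta
significance uses one-sample t-tests at the Bonferroni-corrected α = 0.0025.

## What the synthetic generator emulates

`sim_config()` defaults encode the study conditions: 10 sessions of 20
minutes at 5.1 Hz; 38 long (30 mm) and 8 short (8 mm) channels over six ROIs
(left/right inferior frontal gyri as no-response controls, left/right primary
and secondary auditory cortices active); 20 speech trials of 5.18–7.31 s and
20 six-second silence trials with 15–30 s inter-stimulus intervals; six
physiology signals at 500 Hz.

Choices made where the protocol is silent, and their rationale:

* **Speech-trial durations** are drawn from a scaled Beta(2, b) on
  [5.18, 7.31] with b solved so the mean is exactly the stated 6.1 s — a
  uniform draw on that range would average 6.245 s and could not reproduce the
  stated mean. Schedules are rejection-sampled until they fit the session with
  a 10 s lead-in and a 16 s tail (so every −1..+15 s epoch is usable),
  slightly truncating the upper ISI tail.
* **Evoked responses** use the same unit-peak HRF ⊗ 3 s-boxcar kernel as the
  GLM design, so true betas are recoverable in µM and parameter-recovery tests
  are exact; duration-dependent response shapes in real data are *not*
  emulated. Evoked HbR is −1/3 of HbO (a typical empirical ratio; not stated
  in the protocol). Default speech amplitude: 1 µM HbO in the four auditory
  ROIs, 0 elsewhere; the control condition evokes nothing.
* **Superficial component**: 0.01–0.5 Hz band-limited noise common to all
  channels with per-channel gains jittered ±20%, SD 2 µM in HbO — twice the
  evoked amplitude, reflecting that systemic fluctuations exceed the evoked
  response. Short channels contain only this component plus noise.
* **Physiology waveforms** are qualitative: heart rate dips at speech onsets;
  SpO2 and GSR rise with 4 s and 2 s delays; PPG is a cardiac-band oscillation
  whose amplitude rises with the stimulus; respiration and temperature drift
  slowly. They reproduce the block-average phenomenology needed to exercise
  the regressors, not real waveform morphology.
* **Couplings**: each z-scored signal enters every long channel with gain
  0.2 µM per z-unit at the signal-specific transit lags reported for this
  paradigm (5.50, 28.17, 18.83, 0.67, 20.83, 10.00 s).
* **Session-to-session variability** is a single additive shift per session on
  the active-ROI betas, SD 0.5 µM. The protocol reports no true-amplitude
  variability, so this is exposed as a free parameter; 0.5 µM (half the mean
  response) is consistent with the large single-subject session spread
  reported for this kind of recording.
* **Wavelength noise** is shared between wavelengths by construction (it is
  injected at the concentration level), so the default SCI is ≈ 1 and no
  channels are pruned; `intensity_noise_sd` adds independent optical noise
  when pruning behaviour itself is under test.

Passing tests on these data therefore demonstrate the *machinery* — linear
algebra, filtering, epoching, selection and reliability statistics — under
known ground truth; they do not certify performance on real optode physics,
motion artifacts beyond step/spike repair, or real autonomic dynamics.

## Numerical choices and degenerate inputs

* OLS via QR; rank deficiency is an error naming the collinear columns.
* SCI on constant series is `NA` → pruned; pruning everything is an error.
* A constant series is returned unchanged by TDDR; zero respiration samples
  mask the pulse-respiration quotient with a warning; an all-zero design
  column is an error.
* Zero between-session variance makes ICC undefined → returned as `NA` with a
  diagnostic rather than a number.
* Schedules that cannot fit all trials at the minimum ISI raise a
  schedule-infeasible error before any sampling.
* Lags are applied by shifting the regressor forward in time (physiology
  precedes its cortical echo) and correlating on the overlapping support;
  integer-sample shifts are exact index shifts.

## Problem sizes used by the test suite

The packaged experiments run at the full default scale where the property
being checked demands it (the structural-count and recovery checks use the
complete 10-session, 46-channel configuration; recovery uses 100 replicate
datasets) and at reduced scale (3 sessions, 8 channels, 7-minute recordings,
50 Hz physiology) for unit-level properties, keeping the whole suite
desk-sized. `scripts/acceptance.R` reruns the full default comparison, a
25-replicate recovery experiment, a 10,000-draw type-I simulation and a
grid-lag recovery check, and writes every quantity it computes to JSON.

## Known limitations

* No SNIRF/HDF5 reader-writer: session bundles use a documented plain-text
  layout (`write_session_bundle()`); montage geometry beyond source-detector
  separation and ROI labels is not modelled.
* One lag per channel and signal (no multiple or time-varying lags), matching
  the modelled protocol; kernel or dynamically re-estimated CCA is out of
  scope.
* The generator's physiology is stylized; tCCA behaviour on real recordings —
  where shared physiological subspaces are stronger — will select more
  components than it does on the default synthetic couplings.
* Epochs are pooled across sessions for block averages (within-session
  averaging first is available by using `extract_epochs()` per session), and
  the epoch grid covers the −1..+15 s window to the nearest native sample.
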