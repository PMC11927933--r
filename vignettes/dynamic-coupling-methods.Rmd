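---
title: "Dynamic coupling of alpha power and DMN connectivity: methods and design"
author: "dyncouple"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic coupling of alpha power and DMN connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyncouple)
```

## The analysis in one paragraph

`dyncouple` quantifies how tightly the moment-to-moment fluctuations of EEG
alpha (8–12 Hz) power and fMRI functional connectivity (FC) between
default-mode-network (DMN) hubs move together, and whether that coupling
changes after an intervention delivered between a *pre* and a *post*
resting-state session. For each session it builds two timeseries on a common
sliding-window grid — windowed BOLD correlation per ROI pair, and
window-smoothed normalized alpha power — correlates them (Pearson, then
Fisher Z), and finally compares the per-subject *post − pre* change in
coupling between an active and a sham group with a two-sample "double
contrast", corrected across the DMN pair family by Benjamini–Hochberg FDR,
with one-tailed within-group follow-ups for surviving pairs.

## The sliding-window grid

Both modalities are epoched at the fMRI repetition time (TR = 1.8 s; one EEG
epoch per volume, centred on the volume onset). The analysis grid is a
Gaussian tapered sliding window:

* window length 60 epochs = 108 s;
* Gaussian taper FWHM 27.78 epochs (σ = FWHM / (2√(2 ln 2)) ≈ 11.8 epochs),
  peak 1 at the window centre;
* step 1 epoch (1 TR), so neighbouring windows overlap by 59 TR = 106.2 s;
* a 306-epoch session therefore yields 306 − 60 + 1 = 247 windows.

The 108 s window corresponds to a frequency threshold of roughly 0.01 Hz
(1/108 s ≈ 0.009 Hz), the conventional lower edge of resting-state BOLD
fluctuations; we report this correspondence but do not assert a particular
formula behind it. Within each window, FC is the *taper-weighted* Pearson
correlation of the two ROI series (the taper acts as observation weights,
the standard dynamic-FC convention; plain unweighted windows are available
via `weighted = FALSE`, since the original description is ambiguous on this
point). The EEG power series uses the same taper as a normalized weighted
average of per-epoch power, so both series live on exactly the same 247
window centres. No hemodynamic response convolution is applied to the power
series — its amplitudes are left undistorted, and hemodynamic delay is
handled instead by an explicit lag parameter (below).

## EEG band power

Per-epoch spectra use multitaper estimation with K = 3 discrete prolate
spheroidal (Slepian) tapers, paired with the standard time–bandwidth product
NW = 2 (the usual K = 2NW − 1 convention when only the taper count is given),
giving a spectral bandwidth of about NW/T ≈ 1.1 Hz for a 1.8 s epoch. Tapers
are computed from the classical symmetric tridiagonal eigenproblem and
cached. Epochs are mean-centred before tapering; no further detrending is
applied (1.8 s epochs are too short for drift removal to matter, and the
choice is documented here so results are bit-stable).

Band power is the mean one-sided PSD over the band's frequency bins, with
band membership inclusive at both edges (8 ≤ f ≤ 12 for alpha, matching the
inclusive "8–12 Hz" convention; theta 4–7 Hz, low beta 13–17 Hz), divided by
the mean PSD over the global spectrum (1–40 Hz) of the same epoch. The ratio
makes power dimensionless and invariant to any rescaling of the raw signal.
Alpha power is pooled (arithmetic mean) across the right occipitoparietal
channels P4, P6, P8, PO4, PO8, O2 after normalization.

Implementation note: the per-epoch spectra for all channels and epochs are
evaluated as one dense cosine/sine transform restricted to the frequency
bins the bands actually need; when the global band covers most of the
spectrum, its summed power is obtained exactly through Parseval's identity
(total tapered power minus the few complement bins). Both shortcuts are
tested to agree with the direct per-epoch estimator at double precision.

## BOLD cleanup

ROI-level cleanup mirrors the standard post-extraction chain: per-ROI
standardization (mean 0, SD 1 — "whitening" is interpreted as variance
normalization, not temporal prewhitening, since the source phrase is
ambiguous; the step is configurable), temporal bandpass 0.01–0.08 Hz, and
nuisance regression with the Friston 24-parameter motion set (six motion
parameters, their one-scan lags, and both squared; lagged rows at t = 1 are
zero-filled). The bandpass is a zero-phase (forward–backward) Butterworth
design of order 4 — the common resting-state default when no particular
filter is prescribed — and the order is recorded in the output provenance.
Edge transients are suppressed by odd-reflection padding before filtering.
Whether filtering should precede regression is not fixed by the method; the
default order is centre → bandpass → regress and is configurable and logged. With no
confound table supplied the regression step runs intercept-only, keeping the
stage exercised but neutral for synthetic data.

## Coupling and lags

For each band, pair, and lag ℓ ∈ {0…5} TRs, the coupling is the ordinary
(unweighted) Pearson correlation between `power[t]` and `fc[t + ℓ]` over the
overlapping windows — the fMRI series is shifted *later* than the EEG
series, reflecting hemodynamic sluggishness; negative lags are rejected by
default. The taper's job ends once the two series are built. Coupling r is
mapped to z = atanh(r); |r| = 1 is treated as an error rather than ±∞
(it arises only in synthetic edge cases). Windows with degenerate
(constant) signal become missing values and propagate by pairwise deletion;
more than 5% missing windows is a hard error.

A control variant subtracts from each intra-DMN coupling the mean coupling
of the extra-DMN pairs (every DMN hub × every ECN/SN hub), removing any
global association between alpha power and connectivity fluctuations
(`adjusted_coupling()`, `adjust_coupling_records()`).

## Group statistics

Per subject, pair, band and lag: Δz = z(post) − z(pre). The double contrast
is a pooled-variance two-sample Student t test of Δz, active versus sham
(Welch is substituted, and flagged, when a median-centred Levene check
rejects homogeneity at 0.05). Within each band × lag, the p values of the 10
DMN-hub pairs form one FDR family; the correction is *not* pooled across
bands or lags, since each band-and-lag combination is its own analysis over
the DMN hub pairs.
Surviving pairs are unpacked with one-sample, one-tailed t tests per group;
follow-ups are deliberately left uncorrected (they are protected by the
significant double contrast, and further correction would inflate type-II
error). Follow-up directions are read from the sign of each group's mean Δz
and recorded in the output — the convention is data-driven, as in the source
analysis. Shapiro–Wilk normality and Levene homogeneity diagnostics are
reported per contrast; they flag, never block.

## The synthetic-data generator

No recordings are distributed with the study, so the package ships a
generator that reproduces the *statistical structure* the analysis assumes,
with known ground truth:

* **Latent state.** One slow state s(t) per session: white noise low-pass
  filtered (exact frequency-domain truncation) below 0.02 Hz — inside the
  0.01–0.08 Hz analysis band, slow enough to survive the 108 s window — and
  re-standardized.
* **BOLD.** Twelve ROI series (5 DMN, 4 ECN, 3 SN hubs) drawn per TR from a
  correlation matrix with base correlation 0.25 everywhere and
  ρ(t) = 0.25 + m·β·s(t) on the target pairs vPCC–lAG and vPCC–rAG, where β
  = 0.5 and m is the group × session multiplier (active: pre 0, post 1;
  sham: pre 0, post −0.25, a slight drift mirroring the sham group's
  observed decline). ρ is clipped to ±0.99 (clips are counted and reported);
  mixing uses a per-TR Cholesky factor with an eigenvalue-clipping
  nearest-PSD fallback when the two shared-node target pairs make the matrix
  indefinite. Gaussian measurement noise (SD 0.2) is added and the series
  are band-limited to 0.01–0.08 Hz by the package's own filter.
* **EEG.** Each epoch of the six pooled channels carries a 10 Hz sinusoid
  with amplitude a₀(1 + γ·s(t)), γ = 0.5, floored at 0.05·a₀ (floored epochs
  are counted), random phase per channel and epoch. All channels add a 1/f
  background synthesized as a random-phase surrogate (deterministic harmonic
  amplitudes ∝ 1/√f, independent uniform phases; Gaussian-like by
  aggregation across harmonics), plus theta (5.5 Hz) and low-beta (15 Hz)
  rhythms whose amplitudes follow slow envelopes *independent* of s(t).

The band-specific background rhythms are essential, not decoration: because
every band is normalized by the same 1–40 Hz denominator, the alpha
modulation leaks — with opposite sign — into every other band's normalized
power. If theta and beta power carried no intrinsic slow variability of
their own, that leaked component would dominate after window smoothing and
*any* generator would fail frequency specificity. With realistic intrinsic
band fluctuations (envelope SD 0.3) and a modest alpha share of global
power (a₀ = 4 µV against a 10 µV 1/f background and 10/8 µV rhythms), the
leaked artifact stays an order of magnitude below the direct alpha effect.

Effect sizes were fixed by a small design probe before the validation
suites were written: with the defaults above, a single active-post session
yields coupling z ≈ 0.66 ± 0.30 across subjects, putting the expected
double-contrast t near 5 at n = 16 per group — a clearly detectable effect
of the magnitude such studies report, while sham sessions drift slightly
negative.

What the generator does *not* emulate: hemodynamic response convolution,
scanner and gradient/ballistocardiogram artifacts, head motion (confound
columns are zero by default), block-concatenation seams (each phase is one
continuous 306-epoch session), and non-stationarities other than the single
latent state. Passing tests therefore demonstrate the pipeline's
correctness and calibration under the assumed structure, not robustness to
every artifact of real recordings.

## Validation suites and problem sizes

* **Null calibration.** 500 complete zero-effect studies (16 + 16 subjects,
  306 epochs; all multipliers zero, groups generatively identical) are run
  through the entire pipeline; the rejection rate of the target pair's raw
  double-contrast p at α = 0.05 must fall in the 95% binomial band
  [0.031, 0.069].
* **Recovery and specificity.** 100 studies with the default injected
  effect: both target pairs must survive BH-FDR across the 10 DMN pairs in
  a majority of studies, group mean changes must match the injected
  directions, and the same contrasts on theta/beta power and on non-target
  pairs must stay quiet. A 3-level β grid (0.1/0.3/0.5, 100 sessions each)
  must give positive, monotonically increasing mean coupling.
* **Oracle equivalences.** Weighted Pearson with uniform weights against
  plain `cor()` (1000 random instances, 10⁻¹²), BH against a brute-force
  step-up, multitaper peak location against an FFT periodogram, regression
  residual orthogonality.

The replication suites synthesize EEG at 80 Hz on the six pooled channels
(the package default is 250 Hz with two distractor channels). The choice is
scientifically neutral: the per-epoch spectral resolution is 1/TR ≈ 0.56 Hz
regardless of the sampling rate, 40 Hz remains below Nyquist, and all
band-power statistics are rate-invariant; the leaner rate simply keeps the
suites fast.

One distributional fact worth knowing when interpreting single sessions:
with a 60-epoch Gaussian window and 1-TR steps, the 247-point series retain
roughly nine effective degrees of freedom, so the *null* coupling r between
unrelated session pairs has SD ≈ 0.33 — individual-session couplings of
±0.5 are unremarkable, which is why all inference runs on group contrasts
of Fisher-Z values.

## Numerical choices and degenerate inputs

* Correlations are clipped to [−1, 1] after floating-point round-off;
  |r| ≥ 1 raises an error at the Fisher-Z step rather than yielding ±∞.
* Zero weighted variance inside a window makes that window's FC missing
  (logged); a fully constant ROI is an error naming the ROI.
* An all-zero epoch has an all-zero PSD; normalization then fails with an
  explicit division-by-zero error naming the channel and epoch.
* The Gaussian taper is evaluated on the discrete epoch grid with centre
  (L−1)/2; for even L the discrete maximum is marginally below 1 (0.9991
  for the default scheme) while the continuous peak is exactly 1.
* Filter edge effects are suppressed by odd-reflection padding (135 samples
  at order 4); passband amplitude at 0.05 Hz is preserved to within 1%.
* All randomness flows through explicit integer seeds; a fixed seed makes
  study bundles and pipeline output tables bit-identical across runs.

## Known limitations

* The sliding-window estimator is the only dynamic-connectivity method
  implemented (no DCC/HMM alternatives), by design.
* Phase-based EEG–fMRI coupling and voxelwise analyses are out of scope.
* The pooled-vs-Welch decision is made per contrast from a diagnostic test;
  with n = 16 + 16 and equal group sizes the two variants rarely differ
  materially.
* The generator's latent state drives both modalities linearly; recovery
  results say nothing about strongly nonlinear coupling regimes.
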