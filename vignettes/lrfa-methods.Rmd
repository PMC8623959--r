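---
title: "Methods: from laser-induced vibration to a torque prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from laser-induced vibration to a torque prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lrfa)
```

This vignette documents the models, parameter choices and numerical
decisions behind `lrfa`, in the order the pipeline runs them. All
quantitative claims made here are recomputed by the test suite
(`tests/testthat/`) and by `scripts/acceptance.R`; nothing below relies on
results outside the package.

## 1. The measurement model

A pulsed laser taps the neck of an implanted pedicle screw at a 10 Hz
repetition rate while a laser Doppler vibrometer records the velocity
response at 0.1 MHz for 2 s, i.e. 20 impulse responses of 10,000 samples
each. The screw rings at its natural frequencies; for a well-fixed screw
the dominant natural frequency `f1` increases with the peak insertion
torque `τ` (the stability index) following a logarithmic law

```
f1(τ) = b + a·ln(τ),
```

with `a > 0`. For polyaxial screws the movable head adds a perturbation:
its tilt direction shifts `f1` (down for horizontal, up for vertical
tilts), changes the mode shapes and hence the relative modal intensities,
and none of this is reproducible from one measurement to the next.

### Preprocessing (module `preprocess`)

`preprocess_record()` runs four steps, each exported separately:

1. `segment_pulses()` cuts the record into `pulse_rate × record_duration`
   equal segments of one pulse period. Pulse onsets are assumed at the
   segment starts: acquisition is triggered by the laser Q-switch, and the
   simulator guarantees this. Onset detection for free-running hardware is
   out of scope.
2. `average_pulses()` takes the element-wise mean; uncorrelated noise
   shrinks by ≈ 1/√20.
3. `purge_head()` removes the first `purge_duration` (default 2 ms) of the
   averaged response. The early response is dominated by the broadband
   impact transient; purging leaves the freely ringing low-order modes.
   Averaging and purging commute here because every segment is purged over
   the same index range, so the order (average, then purge) is a
   presentation choice, not a numerical one.
4. `compute_spectrum()` applies a rectangular window (that is, no taper —
   the response has decayed essentially to zero by the end of a 98 ms
   segment, so leakage is negligible) and returns the one-sided amplitude
   spectrum: `a_k = w_k |X_k| / n`, where `w_k = 1` for the DC and Nyquist
   bins and 2 otherwise. A unit-amplitude sinusoid at a bin frequency then
   has peak intensity 1, and Parseval's identity reads
   `Σ x² = n · Σ (a_k²/w_k)` (tested). Amplitude rather than power is the
   vibrometry plotting convention; the choice is isolated in this one
   function. The frequency resolution is `sampling_rate / n` ≈ 10.2 Hz
   after the purge.

### Band features (module `features`)

Two band schemes are built in: 8 monoaxial bands (30–150, 150–500,
500–1000, 1000–5000, 5000–10000, 10000–15000, 15000–20000, 30–20000 Hz)
and 6 polyaxial bands (0–1500, 1500–6500, 6500–11500, 11500–15000,
15000–25000, 0–25000 Hz). Bands are half-open `[low, high)`; the
whole-range band overlaps the sub-bands by design. In each band, with
`x_i` the intensities of the `n` bins:

- peak frequency and peak intensity (ties broken toward the lowest
  frequency, deterministically);
- centroid frequency `Σ f_i x_i / Σ x_i` and the intensity linearly
  interpolated at it ("centroid intensity" — interpolation rather than
  nearest-bin lookup is the default because it is continuous in the
  centroid; the nearest-bin variant is available via
  `centroid_intensity_method = "nearest"`);
- average intensity `x̄` and the population dispersion
  `V = (1/n) Σ (x_i − x̄)²`;
- bias-adjusted excess kurtosis
  `K = n(n+1)/((n−1)(n−2)(n−3)) Σ ((x_i−x̄)/s)⁴ − 3(n−1)²/((n−2)(n−3))`
  and bias-adjusted skewness
  `S = n/((n−1)(n−2)) Σ ((x_i−x̄)/s)³`,
  with `s` the sample (n−1) standard deviation. The `s⁴` normalization
  inside the skewness cube sometimes seen in print is dimensionally
  inconsistent; since the kurtosis companion formula is the standard
  bias-adjusted one, the standard adjusted skewness is implemented.
  Note the deliberate asymmetry: `V` uses the population (1/n) form while
  `K` and `S` standardize by the sample sd — each formula is implemented
  exactly as defined and unit-tested against independent brute-force
  oracles.

When `K`/`S` are undefined (fewer than 4 bins, or a perfectly flat band
with `s = 0`) they are emitted as 0 with a classed warning
(`lrfa_degenerate_moment`): a flat band carries no shape information, and
a defined value keeps downstream matrices complete. This never occurs at
the default acquisition settings, where even the narrowest band (30–150
Hz) spans ~12 bins of noisy spectrum.

## 2. Variable ranking (module `selection`)

All explanatory columns and the objective are z-scored
(`normalize_columns()`); frequencies (10³–10⁴ Hz) and intensities
(10⁻⁴–10⁻¹) otherwise differ by orders of magnitude, which would distort
both the L1 penalty and the RBF kernel. Constant columns are dropped with
a warning.

`bootstrap_lasso()` draws `n_bootstrap = 2000` resamples with replacement
and fits the whole regularization path (20 log-spaced strengths on
[10⁻³, 1]) per resample with `glmnet`. For each strength λ it records
which variables have nonzero coefficients, the in-resample determination
coefficient, and the out-of-bag determination coefficient (each bootstrap
resample leaves out ≈ 1/e of the rows, which serve as its validation
set).

**Choosing λ.** The chosen strength maximizes the mean out-of-bag R²
among strengths whose selection footprint (mean variables per trial by
default, unique count as an option) stays below `max_variables = 40`.
In-sample scoring is computed and reported but not used for the choice:
in-sample fit improves monotonically as the penalty weakens, so an
in-sample rule degenerates to "always the weakest penalty on the grid",
under which essentially every variable is selected in every trial and the
ranking carries no information. The out-of-bag optimum lies at an
intermediate λ with sparse per-trial models (typically 10–20 variables
per trial on the synthetic campaign), which is what makes the selection
counts discriminating. Ties in the score go to the larger (sparser) λ;
ties in the counts are broken by column order.

`take_top_k()` hands the first `k` of the ranking to the regression stage
(8 for the monoaxial demonstration, 30 for the polyaxial one).

## 3. Torque regression (module `regress`)

**Folds.** `assign_folds()` implements torque-stratified three-fold
cross-validation: the global minimum and maximum torque always go to
fold 1 (used only for training, so validation never extrapolates), and the
remaining measurements, sorted by torque, are dealt out in consecutive
triplets. Ties keep input order.

**SVR.** `train_svr()` z-scores the selected features with training-row
statistics and fits an ε-insensitive SVR with a Gaussian kernel
(`e1071::svm`). Hyperparameters are tuned by exhaustive search over
power-of-two grids — ε over 2⁻²⁰…2⁹, C over 2⁻¹⁰…2¹⁰, γ over 2⁻¹⁵…2⁹,
exponent step 1 (15,750 triples) — each scored by mean R² over a seeded
random three-fold split of the training rows; the best triple is refit on
all training rows. Candidates whose ε-tube swallows the data (no support
vectors) are invalid and skipped. The first maximum in grid order wins,
deterministically.

**Objective scale.** By default the objective entering the SVR is
`ln(τ)`, z-scored; predictions are exponentiated back to Nm
(`objective_scale = "linear"` switches this off). Three reasons: the
normalization's purpose is to flatten the order of magnitude of the
variables, and torque spans 1.7 orders of magnitude over the campaign; the
physical law linking spectrum and torque is logarithmic; and the accuracy
criterion (±20% of the true value) is multiplicative, so the
ε-insensitive loss should act on relative error. On the linear scale the
fitted tube's absolute slack (~0.1–0.2 Nm) exceeds the entire ±20% band
below ~0.5 Nm, which systematically sacrifices the low-torque end.

**Extrapolation.** Predictions are never clipped or refused. Queries whose
features leave the training range, or whose predicted torque leaves the
training torque range, are flagged (`extrapolated` attribute) with a
classed warning — prediction accuracy outside the training range degrades
sharply, as leave-one-out validation at the extreme torques shows
(`loocv()`; tested).

**Metrics.** `evaluate_predictions()` reports R² = 1 − SS_res/SS_tot,
Pearson r, MSE on the raw Nm scale and on the variance-normalized scale
(reported MSEs in this literature are of ambiguous scale, so both are
available), and the ±20%-band fraction. The conventional baseline
(`fit_log_baseline()`) fits `f_peak = a·ln τ + b` by least squares on the
training rows and predicts torque by inversion, `τ̂ = exp((f−b)/a)`, so
the two approaches are compared on identical splits.

## 4. The synthetic vibration generator (module `synth`)

No public laser-vibrometry data set for pedicle screws exists, so the
generator is the package's test bed. It is a phenomenological model chosen
to reproduce the documented behaviour of the instrument, not a physical
simulation of laser–metal interaction or screw modal mechanics.

Each pulse excites `n_modes = 6` exponentially damped sinusoids. The
dominant mode follows `f1 = 6700 + 1200·ln(τ)` Hz (polyaxial preset),
placing the peak between ~3.3 kHz at 0.06 Nm and ~8.0 kHz at 3 Nm —
the observed range of polyaxial screw resonances, with ~6.7 kHz at
~1 Nm in the center position. Secondary modes sit at fixed ratios
(1.85, 0.35, 2.6, 1.45, 0.16) of `f1`, spanning all six analysis bands;
a 10-ns laser pulse excites modes across the whole acoustic range, and the
band scheme exists precisely because real spectra show characteristic
peaks in every band. Damping rates (40–90 s⁻¹) give decay times well
inside one 100-ms pulse period and spectral linewidths below one bin.

The movable head enters three ways:

1. a per-measurement realized frequency shift, Gaussian around a
   direction mean (−800 Hz horizontal, +800 Hz vertical, 0 center and
   skew) with sd `tilt_jitter_sd = 150` Hz — re-tilting the head never
   reproduces the same state, so repeated skew measurements differ;
   each mode receives a mode-specific fraction (1, 0.35, 0.1, 0.6, 0.8,
   0.05) of the shift, because mode shapes involve the head to different
   degrees;
2. a tilt-dependent modal amplitude, `A_m · exp(c_m · shift/1000)` with
   `c_m ∈ [−0.3, 0.4]`: the tilt moves the center of gravity and deforms
   the mode shapes, so the intensity pattern — not just the peak positions
   — depends on the head state. This is what makes the head state
   identifiable from the whole spectrum and hence torque recoverable;
   a single shifted peak alone would be ambiguous;
3. a small within-record pulse-to-pulse wobble (`pulse_jitter_sd = 10`
   Hz). The head does not move between the 20 pulses of one record;
   making this wobble as large as the between-measurement variation would
   decohere the time-domain average and erase the dominant peak.

Additive white noise (`noise_sd = 0.02` relative to the unit dominant
amplitude) represents vibrometer and digitizer noise. Campaign torques are
drawn log-uniformly over [0.06, 3] Nm with both endpoints forced, so the
steep low-torque regime of the log law is represented and fold
construction can keep the extremes in the training fold. Tilt directions
are drawn uniformly, emulating an uncontrolled head. The monoaxial preset
(fixed head) zeroes the tilt shifts, keeps a 40-Hz residual
measurement-to-measurement jitter, and uses `f1 = 3500 + 500·ln(τ)` Hz so
the dominant peak stays in the 1000–5000 Hz monoaxial analysis band over
0.012–5 Nm.

Everything is seeded explicitly; there is no hidden global RNG state
(`with_seed` saves and restores `.Random.seed`), and a single
campaign seed derives all per-record and per-stage seeds.

**What the generator does not emulate.** Real spectra have colored noise
floors, mode splitting, amplitude dependence on laser spot placement, and
bone-density-specific damping; the generator's tilt perturbation is a
one-dimensional latent shift, whereas a real head tilt is at least
two-dimensional. Passing the synthetic end-to-end test therefore shows
that the pipeline recovers torque when the spectrum carries the assumed
structure — it does not certify accuracy on laboratory data.

## 5. Validation design and problem sizes

The test suite validates each formula against independent brute-force
oracles (an O(N²) DFT for the FFT path; direct moment evaluations for
V, K, S), each contract against hand-constructed cases, and the
invariants (linearity, Parseval, scale equivariance, determinism,
fold-assignment enumeration) as property-style loops under fixed seeds.
Unit tests use short records (0.1–0.5 s) for speed; the end-to-end
acceptance experiment uses the full acquisition geometry (57 records of
2 s at 0.1 MHz) with 2000 bootstrap resamples and the full 15,750-point
SVR grid, and completes in about two minutes on one core. The
leave-one-out characterization uses the monoaxial preset at n = 31 with a
coarse tuning grid (exponent step 4) followed by single-triple
leave-one-out fits, since tuning 31 times over the full grid would add
nothing but runtime.

## 6. Known limitations

- The end-to-end ±20%-band fraction on the synthetic campaign varies
  from draw to draw (roughly 0.6–0.95 across campaign seeds); draws whose
  validation fold concentrates strongly tilted low-torque measurements are
  intrinsically harder, and a random-forest ceiling computed on such draws
  confirms the information loss is in the data, not the estimator.
- The bootstrap-Lasso ranking on the synthetic campaign is typically
  headed by features of the 11500–15000 and 15000–25000 Hz bands, where a
  secondary mode enters and leaves the band as torque varies — a strong
  sigmoidal "band-occupancy" signal that a linear selector prizes. On the
  laboratory data the ranking was instead headed by the dominant-mode
  band. Generator variants that suppressed the band-crossing signal
  degraded end-to-end recovery and were rejected; the discrepancy is a
  documented property of the generator, and the corresponding check in
  the acceptance suite records it.
- `chosen_lambda` and the mean variables per trial depend on the λ-scoring
  rule; with out-of-bag scoring they land at a sparser, more informative
  regime than the in-sample rule, but neither is asserted against
  laboratory values, which would require the original data.
- The MSE scale ambiguity (Nm² vs normalized) is resolved by reporting
  both; no claim is made about which scale external reports use.
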