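# lrfa

Machine-learning diagnosis of orthopedic implant stability from
laser-induced vibration spectra.

## The problem

Laser resonance frequency analysis (L-RFA) excites a structure's natural
vibrations with a pulsed laser and records the response with a laser
Doppler vibrometer. For pedicle screws — spinal implants whose initial
fixation strength is measured by the peak insertion torque τ (Nm) — the
dominant resonance frequency rises with stability following a logarithmic
law,

    f_peak = a · ln(τ) + b,

so a single measured peak frequency can in principle be inverted into a
torque estimate. That works for **monoaxial** screws (fixed head). For
**polyaxial** screws, whose movable head tilts in an uncontrolled direction
at every measurement, the head perturbs the natural modes: the dominant
peak shifts down for a horizontal tilt, up for a vertical tilt, varies from
run to run even at a nominally identical tilt, and the single-peak
calibration collapses (errors of ±1000 Hz at fixed torque).

`lrfa` implements the whole-spectrum analysis chain that recovers the
stability information anyway:

1. **Preprocessing** — a 2-s record sampled at 0.1 MHz containing 20 pulse
   responses is segmented, averaged, the first 2 ms after each pulse purged,
   and transformed with a rectangular-window FFT into a one-sided amplitude
   spectrum.
2. **Band features** — in each analysis band (8 bands for monoaxial,
   6 for polyaxial screws) eight variables are extracted: peak frequency,
   peak intensity, centroid frequency, centroid intensity, average
   intensity x̄, dispersion V = (1/n)Σ(xᵢ−x̄)², bias-adjusted excess
   kurtosis K, and bias-adjusted skewness S — 64 (monoaxial) or 48
   (polyaxial) explanatory variables.
3. **Bootstrap-Lasso ranking** — L1-regularized regression on 2000
   bootstrap resamples; variables ranked by how often they receive nonzero
   coefficients at a regularization strength chosen by out-of-bag
   determination coefficient under a selection-footprint cap.
4. **SVR prediction** — an ε-insensitive support vector regression with a
   Gaussian (RBF) kernel on the top-ranked variables, hyperparameters
   (ε, C, γ) tuned by exhaustive grid search over power-of-two grids
   (2⁻²⁰–2⁹, 2⁻¹⁰–2¹⁰, 2⁻¹⁵–2⁹) with internal three-fold
   cross-validation, validated on torque-stratified folds that keep the
   extreme torques in the training fold.

Because no public data set of laser-induced screw vibrations exists, the
package ships a **synthetic vibration simulator**: each laser pulse excites
a sum of exponentially damped sinusoid modes whose dominant frequency
follows the logarithmic torque law; a movable head adds a tilt-dependent
frequency shift, tilt-dependent modal amplitudes, and run-to-run variation.
The entire pipeline is developed and validated against this simulator.

It is aimed at researchers in implant biomechanics and vibration-based
nondestructive testing who want a reproducible, testable reference
implementation of the band-feature / bootstrap-Lasso / SVR diagnosis
scheme.

## Worked example

Simulate one polyaxial-screw measurement at 1.05 Nm with the head in the
center position, preprocess it, and extract the feature vector:

```r
library(lrfa)

cfg <- sim_config("polyaxial")
rec <- simulate_record(1.05, "center", cfg, seed = 7)
dim(rec)
#> [1] 200000      2          # 2 s at 0.1 MHz

sp <- preprocess_record(rec)  # segment -> average -> purge 2 ms -> FFT
attr(sp, "resolution")
#> [1] 10.20408               # Hz per bin (9800 samples after the purge)
sp$frequency_hz[which.max(sp$intensity)]
#> [1] 7102.041               # dominant peak, Hz

ft <- build_feature_table(list(sp), torques = 1.05,
                          scheme = band_scheme("polyaxial"))
length(explanatory_columns(ft))
#> [1] 48                     # 6 bands x 8 features
```

The dominant peak sits near 7.1 kHz: the closed-form mode frequency at
1.05 Nm is 6700 + 1200·ln(1.05) ≈ 6759 Hz, and this particular draw of the
realized head-tilt shift moved it up by ~340 Hz — the polyaxial
disturbance the machine-learning stage has to see through.

The full synthetic campaign — 57 measurements over 0.06–3 Nm with random
head tilts, bootstrap-Lasso selection of 30 variables, SVR trained on
folds 1+2 and validated on fold 3 — runs in about two minutes:

```r
demo <- run_full_demo(seed = 1)
glance(demo)          # held-out metrics + baseline comparison
tidy(demo$selection)  # selection-frequency table
autoplot(demo$evaluation)  # predicted vs true with the ±20% band
```

At seed 1 this prints a held-out R² of 0.990 with 15 of 18 validation
points (83%) inside the ±20% accuracy band, while the conventional
log-fit baseline, inverted to predict torque on the same split, fails
badly (negative R²) because the tilt-shifted peak frequency alone no
longer identifies torque.

A command-line wrapper with `simulate`, `preprocess`, `features`,
`select`, `train`, `predict`, `evaluate` and `full-demo` subcommands is
installed at `inst/scripts/lrfa`; every run writes a `manifest.yaml` with
the configuration hash and seed.

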