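---
title: "Quantifying carbaryl from an enzyme-ISFET biosensor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying carbaryl from an enzyme-ISFET biosensor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

An ion-sensitive field-effect transistor (ISFET) coated with
acetylcholinesterase (AChE) reports the hydrolysis of acetylcholine as a
gate--source potential shift, because the reaction releases protons at
the gate dielectric. Carbaryl, an N-methyl carbamate insecticide,
inhibits AChE; the more carbaryl present, the smaller the signal
response. Two quantities describe a measurement:

* $\Delta V_{gs}^{\mathrm{w/o}}$ — the *reference* signal response of the
  sensor with substrate but no pesticide (mV), and
* $\Delta V_{gs}^{\mathrm{carb}}$ — the response after carbaryl
  incubation (mV).

The assay readout is the percent enzyme inhibition

$$I = \left|\frac{\Delta V_{gs}^{\mathrm{w/o}} - \Delta V_{gs}^{\mathrm{carb}}}
{\Delta V_{gs}^{\mathrm{w/o}}}\right| \times 100,$$

which is linear in $\ln c$ over the sensor's working range
($10^{-6}$–$10^{-4}$ M). Two practical complications motivate this
package:

1. **Temperature drift.** Both the enzyme kinetics and the transistor
   itself respond to solution temperature, so a single inhibition
   calibration line at 25 °C mispredicts field readings taken at
   20–35 °C.
2. **Sensor-to-sensor variation.** Enzyme immobilization differs between
   sensors, shifting the reference signal; a model trained on one
   sensor's data needs a per-sensor offset correction.

The package answers both with a pair of small feed-forward regression
networks: a *two-input* network mapping (signal response, temperature)
to concentration, and a *single-input* network mapping temperature to
the expected reference signal, used to compute a per-sensor calibration
voltage. `run_pipeline()` executes the whole scheme end to end.

## The response simulator

No public data accompany this assay, so the package includes a
parametric generator (`sim_params()`, `generate_dataset()`,
`generate_blanks()`) calibrated to the sensor's printed empirical
behaviour. It is an *empirical* simulator: it reproduces the printed
calibration relations and their noise structure, not the device physics
(no site-binding model, no drain-current curves).

The constants and their defaults:

| parameter | default | units | origin |
|---|---|---|---|
| `ph_slope`, `ph_intercept` | 49.86, 418.98 | mV/pH, mV | printed pH sensitivity line |
| `ref_mean_25c`, `ref_sd` | 45.35, 1.6 | mV | printed reference mean/SD at 25 °C |
| `inhib_slope`, `inhib_intercept` | 6.6098, 134.62 | %/ln(M), % | printed inhibition line |
| `matrix_offset_range` | (2.68, 3.24) | % | printed extract-vs-buffer inhibition gap |
| `mv_per_percent` | 0.45 | mV/% | printed signal equivalence |
| `ref_temp_coeff` | 0.3 | mV/°C | stand-in (see below) |
| `inhib_temp_coeff` | 0.4 | %/°C | stand-in (see below) |
| `signal_noise_sd` | 0.2 | mV | stand-in (see below) |
| `temp_noise_sd` | 0.1 | °C | stand-in (see below) |

Four values are deliberate stand-ins. The temperature dependence of the
reference signal and of the inhibition line is shown only graphically in
the source material, never as numbers, so the two temperature
coefficients are configurable linear coefficients about 25 °C at
magnitudes that produce visible but modest drift over the 20–35 °C span
(a few mV, a few percent) — the pipeline must and does work for any
values including zero. Likewise no noise variance is printed anywhere;
0.2 mV signal noise and 0.1 °C thermistor noise are what we consider a
realistic noise floor for a bench multimeter setup of this kind, and
they are fixed once as the package's study conditions.

Three structural choices deserve a note:

* **Which spread applies where.** The 1.6 mV `ref_sd` describes the
  variability of *blank reads* (and, implicitly, of differently coated
  sensors); it drives `reference_signal()` draws, the blank corpus of
  the reference model and the limit-of-detection arithmetic. It is *not*
  added to every carbaryl reading: within one sensor's measurement
  series the per-reading scatter is the much smaller `signal_noise_sd`,
  and `carbaryl_signal()` therefore scales the *expected* reference at
  the given temperature. Conflating the two spreads would bury the
  concentration signal under 1.6 mV of per-row noise that the real
  instrument does not show within a series.
* **Extrapolated inhibition line.** The inhibition line is printed for
  $10^{-6}$–$10^{-4}$ M but the measurement design spans
  $10^{-7}$–$10^{-3}$ M; the generator extrapolates the line and then
  clamps inhibition into [0, 100] %, after the temperature and matrix
  adjustments.
* **Matrix offset as a draw.** Only the 2.68–3.24 % range of the
  extract inhibition deficit is known, so each extract reading draws its
  offset uniformly from that range.

What the generator does **not** emulate: day-scale sensor aging and
drift, interfering compounds (organophosphates such as chlorpyrifos also
inhibit AChE and would read as carbaryl), pH and ionic-strength effects
of real vegetable matrices, and any nonlinearity of the temperature
response. Tests passing against this generator therefore demonstrate
that the *algorithmic pipeline* recovers what the calibration relations
encode; they are not evidence about untested chemistry.

## Preprocessing

`minmax_normalize()` rescales every feature and the target to [0, 1] by
column minima/maxima (the inverse is `denormalize()`). Three decisions:

* **Training-set parameters everywhere.** Normalization parameters are
  fitted on the training split only and applied unchanged to held-out
  data — the standard leakage-free convention. (Fitting the test split
  with its own extrema is possible by calling `fit_norm_params()` on it
  explicitly, but nothing in the package does so.)
* **Target scale.** Concentration is regressed as $\log_{10} c$
  (`target_transform = "log10"`). The design spans four decades; on the
  raw molar scale the bottom four of five levels collapse into the
  lowest tenth of the unit interval and the network would effectively
  see a one-level problem. A raw-scale mode (`"identity"`) is retained
  for comparison.
* **Out-of-range values are clipped**, with a warning, rather than
  rejected: a field reading a fraction of a millivolt outside the
  calibration range is still worth a prediction. Degenerate (constant)
  columns are an error when fitting, except where a constant is
  legitimate — a noise-free blank corpus with no temperature drift — in
  which case `degenerate = "constant"` carries the constant through
  normalization and back exactly.

`awgn_augment()` replicates each measurement row `factor` times and adds
independent zero-mean Gaussian noise to the signal and temperature
*features only* — targets are never touched. The default corpus is the
5 × 4 × 10 factorial (200 rows) augmented ×10 to 2000 rows, then split
80/20 stratified by nominal temperature (1600/400 overall, 400/100 per
temperature). Augmentation happens *before* the split, matching the
stated order of the source protocol; note that this lets augmented
siblings of one source row straddle the split, which makes held-out
metrics partly a memorization test and inflates them relative to truly
independent readings. This is a property of the protocol being
reproduced, and it is why the package also reports end-to-end recovery
on fresh noiseless readings.

## The networks and their training

Both networks are plain feed-forward regressors written in base R
matrix algebra — the regression scheme is the package's subject, so no
neural-network library stands behind it:

* two-input concentration model: layers 2–20–16–1;
* single-input reference model: layers 1–10–5–1.

Hidden layers apply $\tanh$; the output node applies ReLU (predictions
are non-negative, matching targets normalized into [0, 1]). Training is
*full-batch* gradient descent on the mean squared error with learning
rate 0.01 — deliberately unaccelerated: no momentum, no Adam, no
mini-batches, no regularization, because the reproduced protocol
specifies none. Gradients are exact backpropagation
($\partial\tanh/\partial z = 1-\tanh^2 z$; ReLU subgradient 0 at 0),
verified in the test suite against central finite differences at
relative tolerance $10^{-5}$.

Numerical choices where the protocol is silent:

* **Initialization.** Weights and biases start uniform(−0.5, 0.5)
  (scaled by `init_scale`). A single-ReLU-output network has a failure
  mode at init: if the output pre-activation is negative on every
  training row, no gradient ever flows and training returns the
  constant-zero predictor. Roughly half of raw draws land there for
  these architectures, so `nn_train()` rejects and redraws an
  initialization until at least 5 % of training rows activate the
  output. The redraw consumes the seeded RNG stream deterministically,
  so results remain bit-reproducible.
* **Stopping.** Training stops at the epoch cap (5000 for the
  concentration model, 3000 for the reference model), when the training
  MSE reaches `mse_stop_threshold` (0.01 for the reference model), or
  when the held-out MSE has risen for `patience = 20` consecutive
  epochs — our operationalization of "stop on divergence", which is
  stated without a window in the source protocol.
* **Returned parameters.** The parameters with the lowest recorded
  held-out MSE are returned, not the last-epoch parameters.
* **ReLU containment.** An absurdly large learning rate does not
  diverge to infinity: an overshoot drives the output pre-activation
  negative, where the gradient is zero, and training freezes. The
  non-finite-loss guard therefore fires mainly on pathological inputs;
  it aborts with advice to reduce the learning rate.

Model files are JSON (`save_model()` / `load_model()`) with numbers at
17 significant digits, so a reloaded model reproduces predictions
bit-identically; the normalization parameters and the target-transform
tag travel inside the file, making prediction self-contained — a saved
model plus one blank reading is all a deployed device needs.

## Signal compensation

The deployment correction has three parts (`calibration_state()`):

1. **Reference model** — the 1–10–5–1 network fitted to blank reads
   across temperatures (`fit_reference_model()`), predicting the
   population reference signal at any temperature in range.
2. **Calibration voltage** — `calibration_voltage()` returns
   `measured_blank − predicted_reference(T)`, averaged over the blank
   reads supplied (triplicate by default). The comparison is an
   additive offset in mV, not a ratio: every correction in this scheme
   is expressed in millivolts. `compensate_signal()` subtracts it.
3. **Matrix correction** — extract-diluted samples inhibit 2.68–3.24 %
   *less* than buffer-diluted ones at the same concentration, so their
   signal reads *higher*; to reuse the buffer-trained model,
   `compensate_signal()` lowers the input by the signal equivalent of
   the gap, so that a corrected extract reading matches the buffer
   reading encoding the same inhibition.
   `matrix_correction_from_inhibition_gap()` converts the gap at
   0.45 mV/% (1.206–1.458 mV over the printed range; midpoint 1.332 mV
   when the gap for a sample is unknown). The 0.45 figure is itself the
   inhibition equation inverted at the reference mean
   (45.35/100 ≈ 0.45), a consistency the test suite asserts.

Temperature is always a *measured* input (the thermistor channel), never
inferred from the signal. In the synthetic evaluation the corpus *is*
the population-reference sensor (true calibration voltage zero), so the
held-out metrics are computed without routing test rows through
compensation; compensation is exercised by its own invariance property —
for a sensor offset by δ ∈ [−3, 3] mV, calibrating on its blank and
compensating its readings reproduces the unoffset sensor's predictions
exactly, because the reference-model error cancels in the difference.

## Assay arithmetic

`percent_inhibition()` implements the absolute-ratio readout;
`lod_check()` the three-sigma detection criterion
(3 × SD + minimum-concentration signal, required to stay below the
reference; at the printed inputs 3 × 1.6 + 28.78 = 33.58 mV — the exact
arithmetic is reported, not a rounded value); `fit_line()` fits
calibration lines by ordinary least squares via `stats::lm()` and
reports $R^2 = 1 - SS_{res}/SS_{tot}$; `sensitivity_acceptable()` is the
inclusive 45–55 mV/pH qualification band. `evaluate_metrics()` computes
MSE, MAE, the population variance of the targets and the
variance-form coefficient of determination
$R^2 = (\mathrm{Var}(y) - \mathrm{MSE})/\mathrm{Var}(y)$ — reported
unclamped (it can be negative, with a warning) because that is the
formula being reproduced. Metrics are computed on the normalized target
scale and reported both raw and ×100 ("percent of the unit interval"),
alongside the same metrics on the $\log_{10}$-molar scale, because the
percent convention for normalized-scale errors is ambiguous in the
source material; emitting both lets the reader pick.

## Problem sizes and runtime

The study conditions are fixed by the defaults: 200-row factorial,
×10 augmentation, 1600/400 split, 5000/3000-epoch caps, blank corpus
4 × 50 reads augmented ×10. One full `run_pipeline()` at these sizes
takes well under a minute on a single core; the test suite shares one
such run across files, and its smaller plumbing tests use reduced
replicates and epoch caps chosen purely to exercise the code paths.

## Known limitations

* The simulator is calibrated to printed empirical relations; nothing
  here validates against a physical sensor, and the temperature
  coefficients and noise magnitudes are documented stand-ins.
* Augment-then-split sibling leakage (above) means held-out metrics
  overstate accuracy on genuinely new readings; the noiseless-recovery
  check is the more honest end-to-end figure, and its residual bias
  (up to roughly ten percent in concentration at 5000 epochs) is
  finite-convergence bias of plain gradient descent, not noise.
* Interferent chemistry is out of scope: organophosphate co-exposure
  would be read as carbaryl.
* The ppm conversion of a molar detection limit requires carbaryl's
  molar mass (201.22 g/mol), an external constant not produced by this
  package's data.
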