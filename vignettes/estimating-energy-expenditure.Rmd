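---
title: "Estimating walking energy expenditure from GRF and EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating walking energy expenditure from GRF and EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitwatts)
```

## The estimation problem

Indirect calorimetry measures metabolic power from breath-by-breath gas
exchange, but each condition of interest needs minutes of steady-state
breathing before the estimate settles. gaitwatts implements the alternative
this package is built around: data-driven models that map one gait cycle (or
one fixed four-second window) of ground reaction force (GRF) and
electromyography (EMG) signals to metabolic power in Watts, so that energy
expenditure can be tracked at roughly one-second resolution once a model has
been trained on calorimetry-labeled data.

The pipeline has five stages, each its own module:

1. **Conditioning** (`filter_grf()`, `process_emg()`): 4th-order Butterworth
   filters — 30 Hz low-pass for forces; 30–500 Hz band-pass, full-wave
   rectification, 6 Hz low-pass envelope for EMG, normalized per muscle by
   the envelope maximum during the subject's normal walking trial.
2. **Segmentation** (`detect_heel_strikes()`, `segment_gait_cycles()`,
   `segment_fixed_windows()`): gait cycles run from one right heel strike to
   the next; fixed windows take 4 s of data and block-average every 32
   samples, turning 8000 samples at 2000 Hz into 250 time steps.
3. **Features** (`bin_cycle()`, `assemble_features()`): each channel of a
   cycle is averaged into 30 bins; a 22-channel recording therefore becomes
   a 660-element vector. Every cycle of a condition inherits the condition's
   steady-state power as its label.
4. **Ground truth** (`brockway_power()`, `steady_state_ee()`): per-breath
   metabolic power from the Brockway equation,
   `W = (16.58 vo2 + 4.51 vco2) * 1000 / 60` with rates in L/min, averaged
   over all breaths in the final two minutes of a condition.
5. **Models and evaluation** (`fit_ee_linear()`, `fit_ee_mlp()`,
   `fit_ee_rnn()`, `run_use_case()`): ordinary least squares, a feedforward
   network, and a two-layer LSTM over fixed windows, evaluated by
   cross-validation under the use cases described below.

## Evaluation protocol

Three use cases mirror how such models are deployed:

* **novel condition** — some subject-specific data exists; each fold holds
  out a random ~10% of all (subject, condition) pairs.
* **novel subject** — leave-one-subject-out; the held-out subject's entire
  condition set is estimated. Variants restrict inputs to vertical GRF plus
  EMG (`subject_vertical_force`, emulating pressure insoles and wearable
  electrodes) or skip all conditioning except EMG rectification
  (`raw_subject`).
* **both novel** — one subject *and* a set of condition ids are removed from
  training; only those conditions of the held-out subject are estimated.

In every case the fold count equals the subject count. Percent error is the
per-condition mean absolute error scaled by the condition's measured power,
averaged over test conditions and then folds; RMSE and MAE are normalized by
the mean test-subject mass (W/kg).

Ordering quality matters for applications such as exoskeleton assistance
optimization, where the model only needs to rank conditions. For every pair
of a subject's conditions the first value is classified as greater than,
within, or less than a relative threshold of the second (4.2% by default —
the accepted error of two-minute calorimetry protocols), for estimates and
measurements separately; `ordering_accuracy()` reports the percentage of
matching outcomes, and `ordering_confusion()` tallies measured-rank versus
estimated-rank as a row-stochastic matrix.

### Design choices in the protocol

Several details of the protocol are genuinely open and were fixed as
follows:

* The ordering threshold is applied **relative to the second member** of
  each pair (`|v1 - v2| <= 0.042 * v2`); the reference value is exposed as
  an argument.
* Condition-level estimates are the **mean of per-sample estimates**; no
  pre-averaging happens before error metrics, which always see individual
  cycles or windows.
* Percent error averages condition-first, then across folds; this matches a
  per-condition reading of the error definition. A sample-first average is
  available through `compute_metrics(average = "sample_first")`.
* Both-novel folds re-sample their held-out condition ids per fold, seeded,
  rather than fixing one set for all folds.
* Hyperparameter selection for the networks follows a two-phase idea
  (validation split inside training via `validation_frac`, after which the
  final model is what early stopping retained); the cross-validation folds
  never see test data during training — fold disjointness is asserted on
  every fold.

## Models

The linear model is exact OLS on the binned features with an intercept —
no regularization, no feature selection. When a fold's design matrix is
rank-deficient (more features than cycles) the minimum-norm least-squares
solution is used and a warning logged.

The feedforward network uses 3 hidden ReLU layers (defaults 512 units,
the midpoint of a 300–1000 band; 3–4 layers are the intended design),
linear output, dropout and L2 weight decay, and trains with mean absolute
error under Adam. The recurrent model stacks two LSTM layers of size 64
over the 250-step windows, reads the final hidden state through a linear
head, trains with mean squared error and is evaluated in MAE. Both are
implemented directly with batched matrix algebra in R; one integer seed
drives initialization, shuffling and dropout, making fits bit-reproducible.
Inputs and labels are column-standardized internally and the scalers travel
with the fitted object. Optimizer settings (Adam, learning rate 1e-3,
batch 64, early stopping on a 10% in-training holdout) are package
defaults, all overridable per fit.

## The synthetic data generator

No public accession exists for the kind of instrumented-treadmill data this
method consumes, so the package ships a generator
(`synthetic_config()`, `generate_dataset()`) that emulates two instrumented-treadmill
protocols: **assisted** walking (22 channels: 3-axis GRF for
both feet plus 8 muscles on both legs; 9 assistance levels, 0–40 J/cycle)
and **incline-load** walking (14 channels: 3-axis GRF both feet, 8 muscles
on one leg; 4 loads × 3 inclines = 12 conditions). Defaults are typical
laboratory conditions: 2000 Hz sampling, ~0.93 Hz stride rate, masses
77.5 ± 5.6 kg (assisted) or 68.8 ± 11.5 kg (incline-load), and
energy-expenditure coefficients placing the assisted conditions around
240–345 W and the incline-load grid around 185–890 W.

The signal model is deliberately simple but analytically controlled:

* Vertical GRF is a per-stride stance waveform — a sharp onset step at 12%
  of peak followed by two raised-cosine bumps — scaled by
  `1.15 (1 + load) · mass · g`, with exactly zero swing. The onset sample of
  every stance is recorded as the planted heel strike; additive force noise
  is clamped at six standard deviations, so the 30 N detection threshold
  can only ever be crossed at the planted samples and strike recovery is
  exact by construction.
* Shear forces are phase-locked low-amplitude sinusoids inside stance.
* EMG is a raised-cosine activation burst per muscle, phase-locked to the
  stride with compact support away from stride boundaries, amplitude scaled
  up by incline and load and down by assistance, multiplied by a 30–500 Hz
  band-limited noise carrier plus additive wideband noise. Raised-cosine
  bursts (rather than, say, Gaussian bells) keep the signal exactly zero
  between bursts, which makes the trial edges silent and edge-padding
  transients vanish.
* Two *context strides* of EMG activation, without GRF stance and hence
  without heel strikes, pad each end of a trial so that every detected gait
  cycle has the same filter context.
* Breaths invert the Brockway equation at a fixed respiratory exchange
  ratio of 0.85 with multiplicative noise per breath.
* Subject heterogeneity enters as mass variation plus an additive
  per-subject power offset (default sd 25 W) — the minimal structure that
  makes novel-subject estimation measurably harder than novel-condition,
  as observed in practice.

True condition power follows
`P = mass (base + c_i · incline + c_l · load) + c_a · work + offset`, which
is strictly increasing in incline and load — so ordering statistics have a
well-defined truth.

### Planted-linear validation mode

With `planted_linear = TRUE` the generator switches to a validation mode in
which the label is an exact affine function of the binned features: all
noise defaults to zero, masses are equal, the cadence is unjittered,
subject offsets are disabled and the EMG carrier becomes a deterministic
sinusoid. Under these conditions every trial's cycle structure is
identical, each trial's features are affine in the condition's assistance
level, and any least-squares interpolant predicts held-out pairs exactly —
so OLS achieves test MAE below 1e-6 W on every use-case split, with
training R² = 1. This is a correctness oracle for the whole pipeline
(filters, segmentation, binning, labeling, splits), not a realism claim.

### What the generator does not emulate

Real gait data has inter-stride waveform variability, soft-tissue and
impact artifacts, crosstalk between EMG channels, drifting electrode
impedance, non-stationary metabolic transients and imperfect
heel-strike detectability. Passing tests on synthetic data therefore
demonstrate that the algorithms are implemented correctly and behave as
designed under controlled conditions; they do not certify accuracy levels
on laboratory recordings.

## Numerical choices

* All Butterworth filters are applied **zero-phase** (forward–backward), the
  standard choice in gait analysis where cross-channel timing matters; the
  effective magnitude response is squared, which the filter tests take into
  account. Whether to filter causally is genuinely open; zero-phase was
  chosen and is documented here as a caveat for comparing attenuation
  figures.
* Zero-phase filtering pads by odd reflection, with the pad length sized
  from the filter's slowest pole so startup transients decay below 1e-14;
  the forward–backward pass itself is applied in the frequency domain
  (multiplication by |H(ω)|²), which matches the two-pass time-domain
  filter to rounding at a fraction of the cost.
* The heel-strike detector is a rising 30 N threshold crossing with a 0.5 s
  refractory period — 30 N sits far above the filtered noise floor and far
  below bodyweight; 0.5 s excludes within-stance chatter at walking
  cadences.
* The EMG normalizer is the maximum of the **processed envelope** of the
  baseline trial (the raw rectified maximum is the other defensible
  reading); the choice is recorded here and implemented in
  `compute_emg_normalizer()`.
* Bin boundaries use `round(b·L/30)` with half-up rounding, partitioning by
  sample count (not normalized-time interpolation); bins tile the segment
  exactly and widths differ by at most one sample, so bin-width-weighted
  means conserve the channel mean exactly.
* Fixed windows are non-overlapping and a trailing partial window is
  discarded.
* Breath averaging is unweighted over breaths in the final two minutes —
  not time-weighted.
* Brockway constants are 16.58 and 4.51 kJ/L with the urinary-nitrogen term
  dropped (unmeasurable from gas exchange alone; ~1% of steady-state
  walking power).

## Problem sizes used in the shipped checks

The test-suite and `scripts/acceptance.R` run entirely on generated data at
desk scale, chosen once: validation datasets use 6 subjects × 9 assisted
conditions at 20–40 s per trial (roughly 700–1950 gait cycles, 660
features), and the incline-load checks use 6 subjects × 12 conditions at
8–30 s per trial. The use-case-hierarchy check averages five generator
seeds with the subject offset sd set to 8% of mean condition power. At
these sizes OLS sits at 3–4 samples per feature — enough for the error
hierarchy to emerge clearly, while small enough to run on a single CPU in
minutes. Network checks use reduced widths (64-unit layers; 8–16-unit
LSTMs) for the same reason; the architectural defaults keep the full-size
design.

## Known limitations

* The LSTM is trained in full batches over 250 steps without gradient
  clipping or sequence truncation; very long windows or aggressive learning
  rates can destabilize it (training aborts on non-finite loss).
* `fit_ee_linear()` on rank-deficient designs returns the minimum-norm
  interpolant, which is the stated behavior but a poor estimator; the
  warning should be taken seriously.
* The generator's EMG carrier is stationary within a trial; it does not
  model fatigue or electrode drift.
* Heterogeneous channel sets across trials of one dataset are rejected
  rather than reconciled.
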