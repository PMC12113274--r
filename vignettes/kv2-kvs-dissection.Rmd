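---
title: "Dissecting Kv2 and Kv2/KvS conductances by paired inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting Kv2 and Kv2/KvS conductances by paired inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvsdissect)
```

## The problem

Kv2.1 and Kv2.2 delayed-rectifier channels dominate the sustained
voltage-gated K^+^ conductance of many excitable cells. The ten "silent"
KvS subunits (Kv5.x, Kv6.x, Kv8.x, Kv9.x) do not form channels on their
own but co-assemble with Kv2 subunits into heterotetramers with distinct
gating. Whether a given cell's Kv2 conductance is carried by Kv2-only
channels or Kv2/KvS heteromers cannot be decided from kinetics alone.

Two selective inhibitors make the distinction operational:

* **RY785**, a central-cavity pore blocker, blocks Kv2-only channels with
  KD ≈ 6 nM but is roughly three orders of magnitude weaker on Kv2/KvS
  heteromers (IC50 in the µM range).
* **GxTX** (guangxitoxin-1E), a tarantula toxin that traps Kv2 voltage
  sensors in their resting state, inhibits both Kv2-only and Kv2/KvS
  channels at a saturating 100 nM dose.

Recording the same cell under baseline, 1 µM RY785, and
1 µM RY785 + 100 nM GxTX therefore decomposes its delayed-rectifier
current into:

* **Kv2-like** = baseline − RY785 (the RY785-sensitive component),
* **KvS-like** = RY785 − RY785+GxTX (RY785-resistant yet GxTX-sensitive),
* **residual** = whatever remains in both drugs.

This package implements that subtraction analysis — tail-current
measurement, percent inhibition, fractional KvS-like conductance, G–V and
kinetics fits — together with a synthetic whole-cell voltage-clamp
generator that stands in for raw patch-clamp recordings.

## Models

All currents are built from closed-form gating expressions evaluated
forward, per channel population:

* **Conductance–voltage (Boltzmann).**
  \(f(V) = A\,[1 + e^{-(V - V_{1/2}) z F / (R T)}]^{-1}\) with temperature
  fixed at 295 K (RT/F ≈ 25.4 mV). The inactivation direction negates the
  exponent so availability falls with voltage.
* **Activation time course.**
  \(I(t) = A\,(1 - e^{-t/\tau_{act}})^{\sigma}\); the sigmoidicity σ
  captures the delayed, sigmoid onset characteristic of Kv2 activation.
* **Deactivation / relaxation.**
  \(f(t) = y_0 + A_1 e^{-(t-t_0)/\tau_1} + A_2 e^{-(t-t_0)/\tau_2}\),
  components ordered fast-first; \(A_2 = 0\) encodes a mono-exponential.
* **Equilibrium pore block** (RY785):
  unblocked fraction \(= 1/(1 + (c/K_D)^n)\) with n = 1 (1:1 binding) by
  default. At the 0.35 µM pre-block dose this predicts
  \(1 - 6/356 = 98\%\) block of homomers, which is the pre-block
  rationale of the concentration-effect protocol.
* **Saturating voltage-sensor modulation** (GxTX): applied only at its
  standard 100 nM dose, each population simply keeps a configured
  `gxtx_remaining` fraction of its conductance. A mechanistic
  voltage-sensor model is deliberately out of scope; a reported residual
  (e.g. Kv9.3-containing channels under GxTX) can be emulated through
  that scalar.
* **Hill concentration–effect.**
  \(r(c) = b + (1 - b)/(1 + (c/IC_{50})^{n_H})\) with the top fixed at 1.

## The synthetic generator

A `cell_model` is a weighted set of populations plus ohmic leak. Within a
sweep, each population carries an activation level \(a\) and an
availability \(h\). Epochs whose Boltzmann steady state exceeds the
current level follow the power-exponential rise toward it; epochs below
it relax bi-exponentially using the population's deactivation kinetics at
that voltage, so the conductance is continuous across the step→tail
boundary. Kinetics are tabulated per voltage; time constants interpolate
log-linearly between entries and clamp outside them.

Drug block is an instantaneous equilibrium scale per condition; the
paper's block-development pre-pulses are protocol metadata with no effect
in this equilibrium model, and kinetics are unchanged by RY785 at ≤1 µM
concentrations, matching the reported absence of kinetic modification at
low doses.

Slow inactivation engages only in epochs of ≥ 1 s (the 10-s protocols),
approaching the steady-state availability
\(h_\infty = \text{floor} + (1-\text{floor}) \cdot B_{inact}(V)\)
exponentially with a population time constant (default 2 s). During the
200 ms activation steps availability is frozen, consistent with treating
those steps as non-inactivating.

Other realism knobs:

* **Noise** — additive Gaussian white noise per sample, seeded per sweep
  so recordings are bit-reproducible. No 1/f or capacitive-transient
  component is modelled; P/4 is idealized as removing both linear leak
  and capacitance.
* **Rundown** — a geometric per-sweep decline of channel conductances
  (not leak), floored; the default rate (1.04%/sweep, floor 0.5) loses
  ≈30% over a 35-sweep wash schedule, matching the magnitude of the
  reported solution-exchange controls.
* **Liquid junction potential** — all command voltages are stored already
  LJP-corrected; the protocol records the applied offset (−9 mV CHO,
  −4 mV mouse/human DRG, −13 mV peptidergic DRG, −15 mV SCG).
* **P/4** — four quarter-amplitude pulses from holding; subtracting their
  scaled, baseline-corrected sum removes linear leak exactly in the
  noise-free case and leaves channel current untouched because the
  quarter pulses stay below activation voltages.

What the generator does **not** emulate: series-resistance error,
capacitive transients, drug wash-in/out kinetics and state-dependent
(trapped) block, voltage-clamp escape, 1/f noise, heterogeneous
Kv2:KvS stoichiometries, and the run-up/instability seen in some neuron
recordings. Tests that pass on synthetic data therefore validate the
analysis chain, not these instrumental complications.

## A constraint the tail-current method relies on

Tail amplitudes index the conductance activated by the preceding step
only if little gating relaxation occurs before the measurement. Two
consequences shaped the preset kinetics:

* At the tail voltage, activation from below must be slow and strongly
  delayed (τ ≥ ~20 ms, σ ≥ 2) so that steps below the tail voltage do
  not pick up re-activation inside the 1–5 ms window. Real Kv2 channels
  behave this way at threshold voltages.
* Near the activation midpoint, relaxation sits at the top of its τ(V)
  bell curve; the CHO presets use 150–400 ms there. With fast
  (tens of ms) relaxation at −9 mV the 1–5 ms window would decay points
  above the tail voltage but not below it, visibly distorting the
  recovered V~1/2~.

With those physical values, half-activation voltages recover to within
0.2 mV of the generating Boltzmann through the full simulate → measure →
fit chain.

## Fitting choices

All fits are bounded Levenberg–Marquardt (minpack.lm) with analytic model
evaluation; bounds are τ ∈ (0.01, 10^4^) ms, σ ∈ (0.1, 20),
z ∈ (0.1, 10), base ∈ [0, 1). Standard errors come from the Jacobian.

* **Activation** is fit on the 10–90% span of the rise; the baseline is
  the pre-step holding segment when available (otherwise the value at
  step onset) and the plateau is the mean of the final 10% of the epoch.
  The conventional 100 µs origin shift compensates instrument delay in
  real recordings; synthetic sweeps have no such delay, so round-trip
  tests pass `t0_offset = 0`.
* **Deactivation** windows run from the tail peak — located on a
  5-sample moving average within the first 20 ms, fitting raw samples —
  to 200 ms after the voltage step. If the two time constants collapse
  within 1% the equivalent mono-exponential is returned and flagged;
  crossed components are swapped post hoc so τ~1~ < τ~2~ always holds.
* **Boltzmann fits of SSI data**: min-max normalization maps the
  *observed* extremes to 0 and 1, which is an affine, not a pure scaling,
  transform. Fitting a plain Boltzmann to such data biases V~1/2~ when
  the sampled grid does not reach both plateaus, so with
  `minmax = TRUE` the model curve itself is min-max normalized over the
  data voltages before comparison. This keeps the estimate consistent
  with the normalization and recovers the generating V~1/2~ essentially
  exactly on the −109…−19 mV grid.
* **Hill fits of pre-block-normalized data**: when responses are
  normalized to the measurement at a reference concentration (0.35 µM),
  the fitted model is evaluated relative to its own value at that
  reference (`reference_conc`). Fitting the absolute top-1 curve to
  renormalized data would bias IC50 upward by ~20%. A small residual
  homomer contribution (< 0.5% of the reference tail in the shipped mix
  preset) still biases the recovered IC50 low by ≈ 1.5%.
* **Time-constant statistics** are summarized on natural logarithms
  (geometric mean, SEM propagated in log space), the field convention.

## Preset calibration

Transcribed published values (activation/inactivation Boltzmanns, RY785
KD/IC50, fast deactivation τ, headline inhibition fractions) are recorded
in each preset's JSON config with a provenance note. Population weights
are the free parameters: they were solved analytically — tail
contributions are linear in gmax — so that the full pipeline reproduces
the published headline numbers (SCG: 88% RY785 inhibition; Mrgprd DRG:
29% RY785 inhibition and 58% fractional KvS-like; Calca DRG: 58%;
human DRG: 76%). Magnitudes nowhere published (gmax ≈ 10 nS,
noise 5 pA, background-population gating, inactivation floors and time
constants) are documented generator choices.

Two quantitative caveats worth knowing:

* Under the equilibrium block model, 1 µM RY785 removes ~16% of the
  heteromer conductance (IC50 5.1 µM), so the "Kv2-like" subtraction
  slightly over-counts and the "KvS-like" component under-counts true
  heteromer current — exactly as in the real experiment.
* The three published Mrgprd percentages (29% RY785, a further 68% by
  GxTX, 58% fractional KvS-like) are per-cell means of ratios and are
  not jointly representable by any single cell: with a non-negative
  residual, the additional GxTX inhibition referenced to baseline is
  forced to `29 × 58/42 ≈ 40%`. The preset reproduces the two
  quantities used for calibration (29% and 58%); its GxTX-additional
  figure is therefore 40%, not 68%.

## Problem sizes and determinism

The shipped analyses run in seconds: 25 kHz-class sampling (0.05–0.1 ms)
for 500 ms step/tail sweeps, 1 kHz for the 10-s protocols, 16-voltage
G–V families, 5-concentration ladders, and 20 seeded replicates for the
noise-robustness checks. Every stochastic element derives from an integer
seed; identical configurations produce byte-identical recordings.

## Limitations

Beyond the generator simplifications above: the pipeline performs no
rundown/drift correction of real recordings (vehicle arms quantify it
instead); no statistical hypothesis testing between groups (descriptive
summaries only); no vendor file formats (ABF/Igor/NWB) — recordings
exchange as the package's CSV + JSON format; and the GxTX scalar model
cannot express voltage-dependent toxin effects such as a shifted G–V in
partially bound channels.
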