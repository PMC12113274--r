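# kvsdissect

Pharmacological dissection of Kv2-only and Kv2/KvS potassium conductances
in whole-cell voltage clamp.

Kv2.1/Kv2.2 delayed-rectifier channels carry much of the sustained K⁺
current of neurons and other excitable cells; the ten "silent" KvS
subunits (Kv5, Kv6, Kv8, Kv9 families) co-assemble with Kv2 into
heteromers whose contribution is hard to identify functionally. Two
selective inhibitors make it operational: **RY785** blocks Kv2-only
channels (K_D ≈ 6 nM) but is ~1000× weaker on Kv2/KvS heteromers, while
**GxTX** (guangxitoxin-1E, 100 nM) inhibits both. Recording the same cell
under baseline → 1 µM RY785 → RY785 + GxTX decomposes its current by
subtraction into

- **Kv2-like** = baseline − RY785,
- **KvS-like** = RY785 − (RY785 + GxTX),
- **residual** = what survives both drugs,

with the *fractional KvS-like conductance* defined as
tail(KvS-like) / (tail(Kv2-like) + tail(KvS-like)).

The package provides, for electrophysiologists and modellers:

- the closed-form models of the analysis — Boltzmann conductance–voltage
  f(V) = A·(1 + e^(−(V−V½)zF/RT))⁻¹ at 295 K, power-exponential
  activation A·(1 − e^(−t/τ))^σ, bi-exponential deactivation, 1:1
  equilibrium block, Hill concentration–effect with top fixed at 1;
- a seeded synthetic whole-cell sweep generator (step/tail/inactivation
  protocols, mixtures of drug-sensitive populations, leak, rundown,
  Gaussian noise, P/4 sub-sweeps, LJP-corrected voltages) with presets
  for the CHO expression system and for SCG, mouse DRG and human DRG
  neurons, calibrated to published headline fractions;
- bounded least-squares fitters with the standard fit windows (10–90%
  rise, tail peak → 200 ms post-step, 1–5 ms / 2–4 ms mean or 10 ms point
  tail windows, min–max-consistent steady-state-inactivation fits,
  log-space time-constant summaries);
- the subtraction pipeline: percent inhibition, fractional KvS-like
  conductance, G–V extraction, concentration-effect series, inactivation
  metrics, P/4 leak subtraction;
- a sweep interchange format (long CSV + JSON sidecar) and a small CLI
  (`inst/cli/kvsdissect.R`) with `simulate`, `analyze`, `dose-response`
  and `presets` subcommands.

## Worked example

Simulate a mouse nonpeptidergic nociceptor (Mrgprd-lineage DRG neuron)
under the three-condition protocol and decompose it:

```r
library(kvsdissect)

cell <- make_preset_cell("mrgprd_drg")       # noise/rundown off by default
d    <- preset_defaults(cell)                # drg_tail protocol, 10 ms point tail
rec  <- simulate_recording(cell, d$protocol, noise = FALSE)
dec  <- decompose(rec, d$window)

dec$percent_inhibition_ry785      # 29.0
100 * dec$fractional_kvs          # 58.0
dec$tails
#>       tail_baseline tail_ry785 tail_ry785_gxtx
#> 6.000         835.9      593.5           258.7

fit_deactivation(dec$kvs_like[[1]])$fit$tau1   # 43.8 ms (slower than Kv2-like)
```

1 µM RY785 removes 29% of the 10-ms tail current at −44 mV; of the total
drug-sensitive conductance, 58% is RY785-resistant but GxTX-sensitive —
the KvS-like component — and it deactivates more slowly than the
Kv2-like component, as expected for Kv2/KvS heteromers.

A concentration-effect experiment on the CHO Kv2.1/Kv8.1 preset:

```r
res <- run_dose_response(list(preset = "cho_kv8_1_mix"))
#> [INFO] Hill fit (nH = 1): IC50 = 5.02 uM, base = 0.00889
#> [INFO] Hill fit (nH free): IC50 = 5.07 uM, nH = 0.994
```

The fitted IC50 of the RY785-resistant (heteromer) population is ≈5 µM
with a Hill coefficient of 1, three orders of magnitude above the 6 nM
homomer K_D.

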