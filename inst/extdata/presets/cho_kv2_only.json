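{
  "name": "cho_kv2_only",
  "description": "Kv2.1-expressing CHO cell without KvS subunits: a single RY785- and GxTX-sensitive homomer population.",
  "protocol": "cho_activation_family",
  "tail_window": {"mode": "mean_window", "start": 1, "end": 5},
  "leak_conductance_nS": 0,
  "leak_reversal_mV": -89,
  "noise_sd_pA": 5,
  "rundown": {"rate": 0.0104, "floor": 0.5},
  "temperature_K": 295,
  "populations": [
    {
      "name": "kv2_homomer",
      "gmax_nS": 10,
      "activation": {"v_half_mV": -6.3, "z": 1.7},
      "act_kinetics": [
        {"voltage_mV": -9, "tau_ms": 20, "sigma": 3},
        {"voltage_mV": 71, "tau_ms": 3, "sigma": 2}
      ],
      "deact_kinetics": [
        {"voltage_mV": -45, "tau_fast_ms": 10, "tau_slow_ms": 50, "frac_fast": 0.9},
        {"voltage_mV": -9, "tau_fast_ms": 150, "tau_slow_ms": 400, "frac_fast": 1.0}
      ],
      "inactivation": {"v_half_mV": -54.7, "z": 3.1, "floor": 0.35},
      "tau_inact_ms": 2000,
      "ry785": {"ic50_nM": 6, "n": 1},
      "gxtx_remaining": 0,
      "reversal_mV": -82.8,
      "provenance": "Activation and steady-state-inactivation Boltzmann parameters are the published control (Kv2.1-only) values for this CHO line; RY785 KD ~6 nM is the published homomer estimate; GxTX at 100 nM removes essentially all homomer conductance. Kinetic time constants, sigmoidicity, inactivation floor and tau are plausible Kv2.1 values chosen for the generator (not published numbers). Reversal from K+ Nernst potential of the recording solutions (130 mM in / 5 mM out, 295 K)."
    }
  ],
  "calibration_targets": {
    "tail_remaining_in_1uM_ry785_fraction": 0.005964
  },
  "provenance": "Single-population expression-system preset; gmax is an arbitrary documented scale (order 10 nS)."
}
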