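{
  "name": "cho_kv8_1_mix",
  "description": "Kv8.1-transfected Kv2.1-CHO cell: Kv2.1 homomers plus a dominant Kv2.1/Kv8.1 heteromer population, as in the concentration-effect experiments where homomers are pre-blocked and the resistant population behaves homogeneously (Hill slope ~1).",
  "protocol": "cho_dose_response",
  "tail_window": {"mode": "mean_window", "start": 2, "end": 4},
  "leak_conductance_nS": 0,
  "leak_reversal_mV": -89,
  "noise_sd_pA": 5,
  "rundown": {"rate": 0.0104, "floor": 0.5},
  "temperature_K": 295,
  "populations": [
    {
      "name": "kv2_homomer",
      "gmax_nS": 2,
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
      "provenance": "Same homomer population as cho_kv2_only; weighted at 20% of total conductance so that after the 0.35 uM pre-block it contributes <0.5% of the reference tail, matching the observed homogeneity of the resistant population."
    },
    {
      "name": "kv2_kv8_1",
      "gmax_nS": 8,
      "activation": {"v_half_mV": 6, "z": 1.6},
      "act_kinetics": [
        {"voltage_mV": -9, "tau_ms": 35, "sigma": 2},
        {"voltage_mV": 71, "tau_ms": 5, "sigma": 1.5}
      ],
      "deact_kinetics": [
        {"voltage_mV": -45, "tau_fast_ms": 20, "tau_slow_ms": 90, "frac_fast": 0.85},
        {"voltage_mV": -9, "tau_fast_ms": 150, "tau_slow_ms": 400, "frac_fast": 0.8}
      ],
      "inactivation": {"v_half_mV": -66, "z": 1.8, "floor": 0.65},
      "tau_inact_ms": 2000,
      "ry785": {"ic50_nM": 5100, "n": 1},
      "gxtx_remaining": 0,
      "reversal_mV": -82.8,
      "provenance": "Activation Boltzmann (V1/2 = 6 mV, z = 1.6) and steady-state inactivation (V1/2 = -66 mV, z = 1.8) are the published RY785-resistant (heteromer) values for Kv8.1-transfected cells; RY785 IC50 5.1 uM with Hill slope 1 is the published concentration-effect estimate. Slower activation, higher inactivation floor (less inactivation after 10 s) and slower deactivation than the homomer reflect the published qualitative differences; exact kinetic values are generator choices."
    }
  ],
  "calibration_targets": {
    "hill_ic50_uM_nh1": 5.1
  },
  "provenance": "Heteromer-dominant two-population mix (80:20 by gmax)."
}
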