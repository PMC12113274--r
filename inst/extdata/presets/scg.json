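{
  "name": "scg",
  "description": "Mouse superior cervical ganglion neuron: Kv2-homomer-dominant delayed rectifier plus a drug-insensitive fast-deactivating background conductance, sized so 1 uM RY785 removes 88% of the 10-ms tail at -45 mV.",
  "protocol": "scg_tail",
  "tail_window": {
    "mode": "point",
    "start": 10
  },
  "leak_conductance_nS": 0,
  "leak_reversal_mV": -74,
  "noise_sd_pA": 5,
  "rundown": {
    "rate": 0.0104,
    "floor": 0.5
  },
  "temperature_K": 295,
  "populations": [
    {
      "name": "kv2_homomer",
      "gmax_nS": 10,
      "activation": {
        "v_half_mV": -11,
        "z": 2.1
      },
      "act_kinetics": [
        {
          "voltage_mV": -45,
          "tau_ms": 30,
          "sigma": 3
        },
        {
          "voltage_mV": 5,
          "tau_ms": 5,
          "sigma": 2
        }
      ],
      "deact_kinetics": [
        {
          "voltage_mV": -45,
          "tau_fast_ms": 16,
          "tau_slow_ms": 100,
          "frac_fast": 0.8
        }
      ],
      "inactivation": null,
      "ry785": {
        "ic50_nM": 6,
        "n": 1
      },
      "gxtx_remaining": 0,
      "reversal_mV": -93.8,
      "provenance": "Activation Boltzmann (V1/2 = -11 mV, z = 2.1) and fast deactivation time constant (16 ms at -45 mV) are the published Kv2-like (RY785-sensitive) subtraction-current values for SCG neurons. Slow component (100 ms, 20% of amplitude) and activation kinetics are generator choices. Reversal from K+ Nernst of the neuron solutions (140 mM in / 3.5 mM out)."
    },
    {
      "name": "background_dr",
      "gmax_nS": 2.907709,
      "activation": {
        "v_half_mV": -20,
        "z": 2
      },
      "act_kinetics": [
        {
          "voltage_mV": -45,
          "tau_ms": 10,
          "sigma": 2
        },
        {
          "voltage_mV": 5,
          "tau_ms": 3,
          "sigma": 1.5
        }
      ],
      "deact_kinetics": [
        {
          "voltage_mV": -45,
          "tau_fast_ms": 4,
          "tau_slow_ms": 20,
          "frac_fast": 0.9
        }
      ],
      "inactivation": null,
      "ry785": null,
      "gxtx_remaining": 1,
      "reversal_mV": -93.8,
      "provenance": "Drug-insensitive fast-deactivating delayed rectifier standing in for the uncharacterised current that remains in RY785+GxTX; all parameters are generator assumptions. gmax calibrated so RY785 removes 88% of the 10-ms tail."
    }
  ],
  "calibration_targets": {
    "percent_inhibition_ry785": 88
  },
  "provenance": "Two-population neuron preset; principal gmax is an arbitrary documented scale (10 nS)."
}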