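{
  "name": "human_drg",
  "description": "Human dorsal root ganglion neuron: KvS-dominant mixture calibrated so 76% of the drug-sensitive 10-ms tail is KvS-like.",
  "protocol": "drg_tail",
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
      "name": "kv2_only",
      "gmax_nS": 1.404512,
      "activation": {
        "v_half_mV": -14,
        "z": 2.5
      },
      "act_kinetics": [
        {
          "voltage_mV": -44,
          "tau_ms": 30,
          "sigma": 2.5
        },
        {
          "voltage_mV": 6,
          "tau_ms": 5,
          "sigma": 2
        }
      ],
      "deact_kinetics": [
        {
          "voltage_mV": -44,
          "tau_fast_ms": 15,
          "tau_slow_ms": 80,
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
      "provenance": "Half-activation between -14 and -4 mV was published for the drug-sensitive components of human DRG neurons; -14 mV and z = 2.5 chosen within that range. RY785 KD 6 nM as for homomers."
    },
    {
      "name": "kv2_kvs",
      "gmax_nS": 10,
      "activation": {
        "v_half_mV": -14,
        "z": 2.5
      },
      "act_kinetics": [
        {
          "voltage_mV": -44,
          "tau_ms": 50,
          "sigma": 2
        },
        {
          "voltage_mV": 6,
          "tau_ms": 12,
          "sigma": 1.5
        }
      ],
      "deact_kinetics": [
        {
          "voltage_mV": -44,
          "tau_fast_ms": 45,
          "tau_slow_ms": 150,
          "frac_fast": 0.7
        }
      ],
      "inactivation": null,
      "ry785": {
        "ic50_nM": 5100,
        "n": 1
      },
      "gxtx_remaining": 0,
      "reversal_mV": -93.8,
      "provenance": "As for the mouse kv2_kvs population; human-specific kinetics were not published."
    },
    {
      "name": "background_dr",
      "gmax_nS": 15.109463,
      "activation": {
        "v_half_mV": -20,
        "z": 2
      },
      "act_kinetics": [
        {
          "voltage_mV": -44,
          "tau_ms": 10,
          "sigma": 2
        },
        {
          "voltage_mV": 6,
          "tau_ms": 3,
          "sigma": 1.5
        }
      ],
      "deact_kinetics": [
        {
          "voltage_mV": -44,
          "tau_fast_ms": 4,
          "tau_slow_ms": 20,
          "frac_fast": 0.9
        }
      ],
      "inactivation": null,
      "ry785": null,
      "gxtx_remaining": 1,
      "reversal_mV": -93.8,
      "provenance": "Drug-insensitive background; gmax set so the residual is ~30% of the baseline tail (generator assumption; the published human recordings show a modest RY785 effect)."
    }
  ],
  "calibration_targets": {
    "fractional_kvs_percent": 76
  },
  "provenance": "Three-population human DRG preset."
}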