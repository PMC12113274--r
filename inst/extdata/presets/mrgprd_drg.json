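{
  "name": "mrgprd_drg",
  "description": "Mouse nonpeptidergic nociceptor (Mrgprd-lineage DRG neuron): Kv2-only, Kv2/KvS and drug-insensitive background populations, weights calibrated so 1 uM RY785 inhibits 29% of the 10-ms tail and 58% of the drug-sensitive tail is KvS-like.",
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
      "gmax_nS": 6.28095,
      "activation": {
        "v_half_mV": -18,
        "z": 2.7
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
      "provenance": "Activation Boltzmann (V1/2 = -18 mV, z = 2.7) is the published Kv2-like subtraction-current value for these neurons; RY785 KD 6 nM as for homomers. Deactivation kinetics are generator choices consistent with the published faster deactivation of the Kv2-like component."
    },
    {
      "name": "kv2_kvs",
      "gmax_nS": 10,
      "activation": {
        "v_half_mV": -18,
        "z": 3.0
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
      "provenance": "Activation Boltzmann (V1/2 = -18 mV, z = 3.0) is the published KvS-like subtraction-current value. RY785 IC50 taken from the CHO heteromer estimate (the neuron heteromer affinity is only bounded, >1 uM). Slower deactivation than the Kv2-only population reflects the published comparison; exact values are generator choices."
    },
    {
      "name": "background_dr",
      "gmax_nS": 22.308016,
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
      "provenance": "Drug-insensitive background as in the scg preset; gmax calibrated jointly with the other populations."
    }
  ],
  "calibration_targets": {
    "percent_inhibition_ry785": 29,
    "fractional_kvs_percent": 58
  },
  "provenance": "Three-population nociceptor preset."
}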