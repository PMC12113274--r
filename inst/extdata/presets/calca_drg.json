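{
  "name": "calca_drg",
  "description": "Mouse peptidergic nociceptor (Calca-lineage DRG neuron): same three-population structure as mrgprd_drg, calibrated so 58% of the drug-sensitive tail is KvS-like.",
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
      "provenance": "Gating as for the mrgprd_drg Kv2-only population; the peptidergic population's own gating was not separately published."
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
      "provenance": "As for mrgprd_drg kv2_kvs."
    },
    {
      "name": "background_dr",
      "gmax_nS": 12.441009,
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
      "provenance": "Drug-insensitive background; smaller than in mrgprd_drg since these recordings lacked the channel-inhibitor cocktail context that motivated the larger residual there (generator assumption)."
    }
  ],
  "calibration_targets": {
    "fractional_kvs_percent": 58
  },
  "provenance": "Three-population nociceptor preset (peptidergic)."
}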