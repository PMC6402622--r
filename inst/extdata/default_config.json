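{
  "settings": {
    "cycles": 12,
    "cycle_length_months": 1,
    "wtp_threshold": 64000,
    "n_psa": 10000,
    "seed": 42,
    "accrual_convention": "all_cycles",
    "perspective": "total",
    "wtp_grid_max": 100000,
    "wtp_grid_step": 2000
  },
  "strategies": {
    "usual_care": {
      "label": "Usual care",
      "probabilities": {
        "complication": {
          "value": 0.379,
          "horizon_months": 12
        },
        "healing": {
          "value": 0.228,
          "horizon_months": 3
        },
        "death_all_cause": {
          "value": 0.016,
          "horizon_months": 12
        },
        "death_wound": {
          "value": 0.024,
          "horizon_months": 12
        },
        "recurrence": {
          "value": 0.557,
          "horizon_months": 12
        }
      },
      "costs": {
        "uncomplicated": {
          "out_of_pocket": 215,
          "health_system": 306
        },
        "hospitalised": {
          "out_of_pocket": 0,
          "bed_day_price": 800,
          "bed_days": 30,
          "non_bed_health_system": 6319
        },
        "healed": {
          "out_of_pocket": 34,
          "health_system": 34
        },
        "dead": {
          "out_of_pocket": 0,
          "health_system": 0
        }
      }
    },
    "specialist_clinic": {
      "label": "Specialist clinics",
      "probabilities": {
        "complication": {
          "value": 0.034,
          "horizon_months": 3
        },
        "healing": {
          "value": 0.345,
          "horizon_months": 3
        },
        "death_all_cause": {
          "value": 0.016,
          "horizon_months": 12
        },
        "death_wound": {
          "value": 0.024,
          "horizon_months": 12
        },
        "recurrence": {
          "value": 0.222,
          "horizon_months": 12
        }
      },
      "costs": {
        "uncomplicated": {
          "out_of_pocket": 678,
          "health_system": 491
        },
        "hospitalised": {
          "out_of_pocket": 0,
          "bed_day_price": 800,
          "bed_days": 30,
          "non_bed_health_system": 6319
        },
        "healed": {
          "out_of_pocket": 42,
          "health_system": 42
        },
        "dead": {
          "out_of_pocket": 0,
          "health_system": 0
        }
      }
    }
  },
  "utilities": {
    "uncomplicated": 0.69,
    "hospitalised": 0.59,
    "healed": 0.89,
    "dead": 0
  },
  "uncertainty": {
    "probability_effective_n": {
      "default": 100,
      "usual_care.complication": 29,
      "specialist_clinic.complication": 29,
      "specialist_clinic.healing": 26
    },
    "utility_effective_n": 100,
    "cost_cv": 0.2
  }
}
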