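{
  "strata": [
    {"country": "Synthia", "sex": "male", "age_lo": 35, "age_hi": 70,
     "population": 1000000, "prevalence_current": 0.30, "prevalence_former": 0.0},
    {"country": "Synthia", "sex": "female", "age_lo": 35, "age_hi": 70,
     "population": 1000000, "prevalence_current": 0.25, "prevalence_former": 0.0}
  ],
  "baseline_never_rates": {
    "lung_cancer": 0.00014,
    "coronary_heart_disease": 0.004,
    "other_cancers": 0.003,
    "copd": 0.0002
  },
  "rr_current": {
    "lung_cancer": 21.0,
    "coronary_heart_disease": 3.0,
    "other_cancers": 1.8,
    "copd": 25.0
  },
  "noise": "none",
  "seed": 1,
  "year": 2000
}
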