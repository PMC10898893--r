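{
  "bonus": {
    "notes": {
      "palliation": "delay of first symptomatic musculoskeletal event, HR 0.52 (95% CI 0.33-0.80)",
      "qol": "significant delay in first clinically significant deterioration of pain and EQ-5D-5L VAS score",
      "tail": "curve point at twice the placebo median not reached; no tail points"
    },
    "palliation_significant": true,
    "qol_significant": true
  },
  "comparator_label": "placebo + ADT",
  "efficacy": {
    "death_hr": {
      "ci_high": 0.81,
      "ci_low": 0.53,
      "endpoint": "overall_survival",
      "point": 0.66
    }
  },
  "schema": "oncovalue-trial/1",
  "test_label": "enzalutamide + ADT",
  "toxicity_comparator": {
    "precomputed_total": 45
  },
  "toxicity_test": {
    "precomputed_total": 49.5
  },
  "trial_name": "ARCHES"
}
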