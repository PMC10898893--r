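{
  "bonus": {
    "notes": {
      "palliation": "statistically significant prolongation of median time to pain deterioration",
      "qol": "no significant differences in global or domain quality-of-life scores",
      "tail": "curve point at twice the placebo median not reached; no tail points"
    },
    "palliation_significant": true,
    "qol_significant": false
  },
  "comparator_label": "placebo + ADT",
  "efficacy": {
    "death_hr": {
      "ci_high": 0.89,
      "ci_low": 0.51,
      "endpoint": "overall_survival",
      "point": 0.67
    }
  },
  "schema": "oncovalue-trial/1",
  "test_label": "apalutamide + ADT",
  "toxicity_comparator": {
    "precomputed_total": 40
  },
  "toxicity_test": {
    "precomputed_total": 44.5
  },
  "trial_name": "TITAN"
}
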