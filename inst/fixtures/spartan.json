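{
  "bonus": {
    "notes": {
      "qol": "no significant FACT-P / EQ-5D-3L differences in overall scores or domains",
      "tail": "metastasis-free proportion 50% higher than control at 32.4 months; 16 points awarded"
    },
    "qol_significant": false,
    "tail": {
      "assessment_time": 32.4,
      "awarded_points": 16,
      "comparator_median": 16.2,
      "prop_comparator": 0.3,
      "prop_test": 0.45
    }
  },
  "comparator_label": "placebo + ADT",
  "efficacy": {
    "death_hr": {
      "ci_high": 0.96,
      "ci_low": 0.64,
      "endpoint": "overall_survival",
      "point": 0.78
    }
  },
  "metadata": {
    "ci_note": "in-text CI (0.23-0.35) is inconsistent with HR 0.78; the tabulated CI (0.64-0.96) is used",
    "tail_proportions": "synthetic: reconstructed from the stated 50% improvement; not printed in the source"
  },
  "schema": "oncovalue-trial/1",
  "test_label": "apalutamide + ADT",
  "toxicity_comparator": {
    "precomputed_total": 22
  },
  "toxicity_test": {
    "precomputed_total": 27
  },
  "trial_name": "SPARTAN"
}
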