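{
  "bonus": {
    "notes": {
      "qol": "FACT-P social/family wellbeing subdomain improved: mean least-square difference 0.94 (95% CI 0.02-1.85, p = 0.045); overall FACT-P and EQ-5D-5L not significant",
      "tail": "metastasis-free proportion 50% greater than control at 29.4 months; 16 points awarded"
    },
    "palliation_significant": false,
    "qol_significant": true,
    "tail": {
      "assessment_time": 29.4,
      "awarded_points": 16,
      "comparator_median": 14.7,
      "prop_comparator": 0.3,
      "prop_test": 0.45
    }
  },
  "comparator_label": "placebo + ADT",
  "efficacy": {
    "death_hr": {
      "ci_high": 0.89,
      "ci_low": 0.61,
      "endpoint": "overall_survival",
      "point": 0.73
    }
  },
  "metadata": {
    "nhb_note": "abstract prints 48.33; tables and results text print 48.36",
    "tail_proportions": "synthetic: reconstructed from the stated 50% improvement; not printed in the source",
    "toxicity_note": "printed totals 49.5/38 imply a recomputed score of -6.05, but the reported score and net health benefit (48.36) use -4.64; both are stored and neither silently preferred"
  },
  "reported_toxicity_score": -4.64,
  "schema": "oncovalue-trial/1",
  "test_label": "enzalutamide + ADT",
  "toxicity_comparator": {
    "precomputed_total": 38
  },
  "toxicity_test": {
    "precomputed_total": 49.5
  },
  "trial_name": "PROSPER"
}
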