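# Random-instance generators and independent oracles shared across tests.

# Random itemized toxicity table (valid by construction).
random_tox_entries <- function(n) {
  lapply(seq_len(n), function(i) {
    adverse_event(term = paste0("ae", i),
                  grade_band = sample(c("g1_2", "g3_4"), 1L),
                  frequency = stats::runif(1))
  })
}

# Independent brute-force oracle for per-arm toxicity points: restates the
# published rule directly (0.5/1 at the 10% cut for grades 1-2, 1.5/2 at
# the 5% cut for grades 3-4) without going through ae_entry_points().
oracle_tox_points <- function(entries) {
  total <- 0
  for (e in entries) {
    total <- total + if (e$grade_band == "g1_2") {
      if (e$frequency < 0.10) 0.5 else 1.0
    } else {
      if (e$frequency < 0.05) 1.5 else 2.0
    }
  }
  total
}

# Random valid trial evidence built around a death hazard ratio.
random_trial <- function(hr_point = stats::runif(1, 0.3, 1.2)) {
  lo <- hr_point * stats::runif(1, 0.7, 1)
  hi <- hr_point / stats::runif(1, 0.7, 1)
  trial_evidence(
    trial_name = "RANDOM",
    test_label = "test", comparator_label = "comparator",
    efficacy = efficacy_evidence(death_hr = hazard_ratio(hr_point, lo, hi)),
    toxicity_test = toxicity_profile(
      precomputed_total = stats::runif(1, 1, 60)),
    toxicity_comparator = toxicity_profile(
      precomputed_total = stats::runif(1, 1, 60)),
    bonus = bonus_evidence(
      palliation_significant = sample(c(TRUE, FALSE), 1L),
      qol_significant = sample(c(TRUE, FALSE), 1L)
    )
  )
}
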