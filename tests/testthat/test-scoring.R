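test_that("clinical benefit uses the death-HR rung when available", {
  cases <- list(
    list(hr = 0.73, score = 27),
    list(hr = 0.78, score = 22),
    list(hr = 0.66, score = 34),
    list(hr = 0.67, score = 33),
    list(hr = 1.00, score = 0)
  )
  for (cs in cases) {
    eff <- efficacy_evidence(death_hr = hazard_ratio(cs$hr, cs$hr * 0.8,
                                                     cs$hr / 0.8))
    cb <- clinical_benefit_score(eff)
    expect_equal(as.numeric(cb), cs$score, label = paste("HR", cs$hr))
    expect_identical(attr(cb, "rung"), "1.A")
  }
})

test_that("lower hierarchy rungs engage in strict priority order", {
  # 1.D only: median PFS {12, 10} with the 0.8 multiplier
  eff <- efficacy_evidence(median_pfs = median_estimate(
    12, 10, endpoint = "progression_free_survival"))
  cb <- clinical_benefit_score(eff)
  expect_equal(as.numeric(cb), 16)  # 100 * (12-10)/10 * 0.8, hand-checked
  expect_identical(attr(cb, "rung"), "1.D")

  # 1.B: median OS outranks PFS HR and response rate
  eff <- efficacy_evidence(
    median_os = median_estimate(20, 16),
    progression_hr = hazard_ratio(
      0.5, 0.4, 0.6, endpoint = "progression_free_survival"),
    response = response_rates(0.6, 0.3)
  )
  cb <- clinical_benefit_score(eff)
  expect_equal(as.numeric(cb), 25)  # 100 * 4/16 * 1.0
  expect_identical(attr(cb, "rung"), "1.B")

  # 1.C: progression HR with 0.8 multiplier
  eff <- efficacy_evidence(progression_hr = hazard_ratio(
    0.5, 0.4, 0.6, endpoint = "progression_free_survival"))
  expect_equal(as.numeric(clinical_benefit_score(eff)), 40)  # 50 * 0.8

  # 1.E: response-rate difference with 0.7 multiplier
  eff <- efficacy_evidence(response = response_rates(0.6, 0.3))
  cb <- clinical_benefit_score(eff)
  expect_equal(as.numeric(cb), 21)  # 100 * 0.3 * 0.7
  expect_identical(attr(cb, "rung"), "1.E")

  # a death HR outranks everything else even when all rungs are present
  eff <- efficacy_evidence(
    death_hr = hazard_ratio(0.73, 0.61, 0.89),
    median_os = median_estimate(20, 10),
    response = response_rates(0.9, 0.1)
  )
  expect_equal(as.numeric(clinical_benefit_score(eff)), 27)
})

test_that("a harmful hazard ratio yields a flagged negative benefit", {
  eff <- efficacy_evidence(death_hr = hazard_ratio(1.2, 1.0, 1.45))
  expect_warning(cb <- clinical_benefit_score(eff), "harmful")
  expect_equal(as.numeric(cb), -20)
})

test_that("clinical benefit is strictly decreasing in the death HR", {
  hrs <- sort(runif(30, 0.2, 1.5))
  scores <- vapply(hrs, function(h) {
    suppressWarnings(as.numeric(clinical_benefit_score(
      efficacy_evidence(death_hr = hazard_ratio(h, h * 0.9, h / 0.9)),
      scoring_config(component_decimals = 6L)
    )))
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("adverse-event points follow the grade-band frequency rules", {
  expect_equal(ae_entry_points("g1_2", 0.09), 0.5)
  expect_equal(ae_entry_points("g1_2", 0.10), 1.0)  # inclusive at 10%
  expect_equal(ae_entry_points("g1_2", 0.50), 1.0)
  expect_equal(ae_entry_points("g3_4", 0.04), 1.5)
  expect_equal(ae_entry_points("g3_4", 0.05), 2.0)  # inclusive at 5%
  expect_equal(ae_entry_points("g3_4", 0.07), 2.0)
  expect_error(ae_entry_points("g1_2", 1.3), "frequency")
})

test_that("toxicity totals sum itemized entries or use the precomputed value", {
  prof <- toxicity_profile(entries = list(
    adverse_event("a", "g1_2", 0.12),
    adverse_event("b", "g3_4", 0.03),
    adverse_event("c", "g3_4", 0.06)
  ))
  expect_equal(toxicity_points_total(prof), 1.0 + 1.5 + 2.0)
  expect_equal(toxicity_points_total(
    toxicity_profile(precomputed_total = 49.5)), 49.5)
  # precomputed takes precedence over entries when both are present
  prof$precomputed_total <- 7
  expect_equal(toxicity_points_total(prof), 7)
})

test_that("itemized totals match the brute-force oracle on random tables", {
  set.seed(101)
  for (i in 1:200) {
    entries <- random_tox_entries(sample(1:40, 1L))
    expect_equal(toxicity_points_total(toxicity_profile(entries = entries)),
                 oracle_tox_points(entries))
  }
})

test_that("toxicity score matches the published worked arithmetic", {
  expect_equal(toxicity_score(49.5, 45), -2.0)
  expect_equal(toxicity_score(27, 22), -4.54)   # ratio taken as 1.2272
  expect_equal(toxicity_score(44.5, 40), -2.25)
  expect_equal(toxicity_score(49.5, 38), -6.05) # ratio taken as 1.3026
})

test_that("toxicity score sign tracks which arm is more toxic", {
  set.seed(11)
  for (i in 1:50) {
    a <- runif(1, 1, 60)
    b <- runif(1, 1, 60)
    s <- toxicity_score(a, b, scoring_config(component_decimals = 8L))
    if (abs(a - b) > 1e-3) expect_identical(s > 0, a < b)
    expect_equal(toxicity_score(a, a), 0)
  }
  expect_error(toxicity_score(10, 0), "positive")
  expect_error(toxicity_score(10, -5), "positive")
})

test_that("tail-of-curve bonus follows the eligibility rules", {
  # absent evidence: the curve point was never reached
  b <- tail_of_curve_bonus(NULL)
  expect_equal(as.numeric(b), 0)
  expect_false(attr(b, "eligible"))

  # eligible with assessor-awarded points
  b <- tail_of_curve_bonus(tail_of_curve(16.2, 32.4, 0.45, 0.30,
                                         awarded_points = 16))
  expect_equal(as.numeric(b), 16)
  expect_true(attr(b, "eligible"))

  # eligible with no awarded points -> full maximum
  b <- tail_of_curve_bonus(tail_of_curve(12, 24, 0.40, 0.25))
  expect_equal(as.numeric(b), 20)

  # no improvement
  b <- tail_of_curve_bonus(tail_of_curve(12, 24, 0.30, 0.30))
  expect_equal(as.numeric(b), 0)
  expect_match(attr(b, "reason"), "improvement")

  # improvement below 50%
  expect_equal(as.numeric(tail_of_curve_bonus(
    tail_of_curve(12, 24, 0.42, 0.30))), 0)

  # comparator at or below the 20% floor the rule assumes
  b <- tail_of_curve_bonus(tail_of_curve(12, 24, 0.35, 0.18))
  expect_equal(as.numeric(b), 0)
  expect_match(attr(b, "reason"), "floor")

  # assessment time far from twice the comparator median is flagged
  expect_warning(tail_of_curve_bonus(tail_of_curve(12, 30, 0.45, 0.30)),
                 "twice the comparator median")
})

test_that("bonus breakdown awards categorical points iff flags are TRUE", {
  # PROSPER: tail 16 + quality of life 10, palliation reported negative
  b <- categorical_bonus(builtin_fixture("prosper")$bonus)
  expect_equal(b$tail_points, 16)
  expect_equal(b$qol_points, 10)
  expect_equal(b$palliation_points, 0)
  expect_equal(b$tfi_points, 0)
  expect_equal(b$total, 26)

  # TITAN: palliation only
  b <- categorical_bonus(builtin_fixture("titan")$bonus)
  expect_equal(b$total, 10)

  # nothing reported
  b <- categorical_bonus(bonus_evidence())
  expect_equal(b$total, 0)

  # total is the exact sum of the four components, always
  set.seed(5)
  for (i in 1:25) {
    be <- bonus_evidence(
      tail = if (runif(1) < 0.5) tail_of_curve(12, 24, runif(1), runif(1)),
      palliation_significant = sample(c(TRUE, FALSE, NA), 1L) %in% TRUE,
      qol_significant = sample(c(TRUE, FALSE), 1L),
      tfi_significant = sample(c(TRUE, FALSE), 1L)
    )
    b <- categorical_bonus(be)
    expect_identical(b$total, b$tail_points + b$palliation_points +
                       b$qol_points + b$tfi_points)
  }
})

test_that("net health benefit is the exact sum of its components", {
  b16 <- categorical_bonus(bonus_evidence(
    tail = tail_of_curve(16.2, 32.4, 0.45, 0.30, awarded_points = 16)))
  expect_equal(net_health_benefit(22, -4.54, b16)$nhb, 33.46)

  b0 <- categorical_bonus(bonus_evidence())
  expect_equal(net_health_benefit(0, 0, b0)$nhb, 0)

  set.seed(23)
  for (i in 1:100) {
    cb <- round(runif(1, -20, 100), 2)
    tox <- round(runif(1, -20, 20), 2)
    pall <- sample(c(TRUE, FALSE), 1L)
    b <- categorical_bonus(bonus_evidence(palliation_significant = pall))
    n <- net_health_benefit(cb, tox, b)
    expect_identical(n$nhb, cb + tox + b$total)
  }
})

test_that("an NHB above the nominal maximum triggers a warning", {
  b <- categorical_bonus(bonus_evidence(palliation_significant = TRUE,
                                        qol_significant = TRUE))
  expect_warning(net_health_benefit(90, 80, b), "exceeds the nominal maximum")
})

test_that("NHB is strictly decreasing in the death HR, all else fixed", {
  cfg <- scoring_config(component_decimals = 6L)
  hrs <- sort(runif(20, 0.3, 1.1))
  b <- categorical_bonus(bonus_evidence(qol_significant = TRUE), cfg)
  nhbs <- vapply(hrs, function(h) {
    cb <- suppressWarnings(clinical_benefit_score(
      efficacy_evidence(death_hr = hazard_ratio(h, h * 0.9, h / 0.9)), cfg))
    net_health_benefit(cb, -2.25, b, cfg)$nhb
  }, numeric(1))
  expect_true(all(diff(nhbs) < 0))
})
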