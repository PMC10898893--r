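test_that("monthly cost reproduces the regulated-price arithmetic", {
  expect_equal(monthly_drug_cost(builtin_dosing("enzalutamide")), 10383984)
  expect_equal(monthly_drug_cost(builtin_dosing("apalutamide")), 9767808)
  zero <- regimen_dosing("nil", 40, 1e-12, 100)
  expect_lt(monthly_drug_cost(zero), 1)
})

test_that("doubling the daily dose exactly doubles the monthly cost", {
  set.seed(3)
  for (i in 1:20) {
    strength <- sample(c(20, 40, 60, 80), 1L)
    dose <- strength * sample(1:6, 1L)
    price <- runif(1, 100, 5000)
    d1 <- regimen_dosing("x", strength, dose, price)
    d2 <- regimen_dosing("x", strength, 2 * dose, price)
    # exact before whole-COP rounding; within 1 COP after it
    expect_equal(price * 2 * dose * 30, 2 * (price * dose * 30))
    expect_lte(abs(monthly_drug_cost(d2) - 2 * monthly_drug_cost(d1)), 1)
  }
})

test_that("tablet counts ceiling to whole tablets", {
  expect_equal(tablets_per_month(builtin_dosing("enzalutamide")), 120L)
  expect_equal(tablets_per_month(builtin_dosing("apalutamide")), 120L)
  expect_warning(d <- regimen_dosing("odd", 40, 50, 100), "whole number")
  expect_equal(tablets_per_month(d), 60L)  # ceiling(1.25) = 2 per day
})

test_that("cost per NHB point divides and guards against non-positive NHB", {
  expect_equal(cost_per_nhb_point(10383984, 48.36), 214723)
  expect_equal(cost_per_nhb_point(10383984, 52), 199692)
  expect_equal(cost_per_nhb_point(9767808, 40.75), 239701)
  expect_equal(cost_per_nhb_point(9767808, 33.46), 291925)
  expect_error(cost_per_nhb_point(10383984, 0), "positive")
  expect_error(cost_per_nhb_point(10383984, -5), "positive")
})

test_that("USD conversion is linear and matches the back-solved rate", {
  expect_equal(to_usd(0), 0)
  expect_lt(abs(to_usd(10383984) - 2652.24) / 2652.24, 0.005)
  expect_lt(abs(to_usd(214723) - 54.84) / 54.84, 0.005)
  set.seed(9)
  for (i in 1:20) {
    a <- runif(1, 0, 1e7)
    b <- runif(1, 0, 1e7)
    expect_lt(abs(to_usd(a + b) - (to_usd(a) + to_usd(b))), 0.011)
  }
  bad <- scoring_config()
  bad$cop_per_usd <- 0
  expect_error(to_usd(100, bad), "positive")
})

test_that("scorecards assemble the full pipeline end to end", {
  arches <- suppressWarnings(build_scorecard(builtin_fixture("arches"),
                                             builtin_dosing("enzalutamide")))
  expect_equal(arches$nhb$nhb, 52)
  expect_equal(arches$cost_per_point, 199692)
  expect_identical(arches$provenance$benefit_rung, "1.A")

  titan <- build_scorecard(builtin_fixture("titan"),
                           builtin_dosing("apalutamide"))
  expect_equal(titan$nhb$nhb, 40.75)
  expect_equal(titan$cost_per_point, 239701)

  spartan <- build_scorecard(builtin_fixture("spartan"),
                             builtin_dosing("apalutamide"))
  expect_equal(spartan$nhb$nhb, 33.46)
  expect_equal(spartan$cost_per_point, 291925)
})

test_that("the reported-vs-recomputed toxicity discrepancy is surfaced", {
  prosper <- builtin_fixture("prosper")
  expect_warning(
    rep_card <- build_scorecard(prosper, builtin_dosing("enzalutamide"),
                                toxicity_source = "reported"),
    "disagrees"
  )
  expect_equal(rep_card$nhb$toxicity_score, -4.64)
  expect_equal(rep_card$nhb$nhb, 48.36)
  expect_equal(rep_card$cost_per_point, 214723)

  expect_warning(
    rec_card <- build_scorecard(prosper, builtin_dosing("enzalutamide"),
                                toxicity_source = "recomputed"),
    "disagrees"
  )
  expect_equal(rec_card$nhb$toxicity_score, -6.05)
  expect_equal(rec_card$nhb$nhb, 27 - 6.05 + 26)
  # both values always recorded in provenance
  expect_equal(rec_card$provenance$toxicity_reported, -4.64)
  expect_equal(rec_card$provenance$toxicity_recomputed, -6.05)
})

test_that("a null regimen has zero NHB and an undefined cost per point", {
  null_trial <- trial_evidence(
    trial_name = "NULL-REGIMEN", test_label = "t", comparator_label = "c",
    efficacy = efficacy_evidence(death_hr = hazard_ratio(1, 1, 1)),
    toxicity_test = toxicity_profile(precomputed_total = 30),
    toxicity_comparator = toxicity_profile(precomputed_total = 30),
    bonus = bonus_evidence()
  )
  expect_warning(
    sc <- build_scorecard(null_trial, builtin_dosing("enzalutamide")),
    "cost per point is undefined"
  )
  expect_equal(sc$nhb$nhb, 0)
  expect_true(is.na(sc$cost_per_point))
  expect_error(cost_per_nhb_point(sc$monthly_cost, sc$nhb$nhb), "positive")
})

test_that("cost per point reconstructs monthly cost within rounding", {
  set.seed(17)
  for (i in 1:50) {
    trial <- random_trial(runif(1, 0.3, 0.9))
    dosing <- regimen_dosing("rx", 40, 40 * sample(1:6, 1L),
                             runif(1, 100, 5000))
    sc <- suppressWarnings(build_scorecard(trial, dosing))
    if (!is.na(sc$cost_per_point)) {
      expect_lt(abs(sc$cost_per_point * sc$nhb$nhb - sc$monthly_cost),
                0.5 * sc$nhb$nhb + 1e-6)
    }
  }
})

test_that("dosing readers accept CSV and JSON", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("regimen_name,tablet_strength_mg,daily_dose_mg,price_per_mg,currency",
               "enzalutamide,40,160,2163.33,COP"), p)
  d <- read_dosing(p)
  expect_equal(monthly_drug_cost(d$enzalutamide), 10383984)

  pj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"regimen_name":"apalutamide","tablet_strength":60,
               "daily_dose":240,"price_per_mg":1356.64,"currency":"COP"}', pj)
  expect_equal(monthly_drug_cost(read_dosing(pj)$apalutamide), 9767808)

  expect_error(read_dosing("missing.csv"), "not found")
})
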