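arches_card <- function() {
  suppressWarnings(build_scorecard(builtin_fixture("arches"),
                                   builtin_dosing("enzalutamide")))
}

test_that("the stepwise report shows the published arithmetic", {
  md <- render_stepwise(arches_card())
  expect_match(md, "## Step 1: Clinical benefit")
  expect_match(md, "(1 - 0.66) * 100 = 34", fixed = TRUE)
  expect_match(md, "49.5/45 = 1.1", fixed = TRUE)
  expect_match(md, "34 + -2 + 20 = 52", fixed = TRUE)
  expect_match(md, "10,383,984 COP", fixed = TRUE)
  expect_match(md, "Cost per NHB point: 199,692 COP", fixed = TRUE)
  expect_match(md, "120 tablets/month", fixed = TRUE)
})

test_that("a zero scorecard renders without error", {
  null_trial <- trial_evidence(
    trial_name = "NULL", test_label = "t", comparator_label = "c",
    efficacy = efficacy_evidence(death_hr = hazard_ratio(1, 1, 1)),
    toxicity_test = toxicity_profile(precomputed_total = 10),
    toxicity_comparator = toxicity_profile(precomputed_total = 10)
  )
  sc <- suppressWarnings(build_scorecard(null_trial,
                                         builtin_dosing("enzalutamide")))
  md <- render_stepwise(sc)
  expect_match(md, "0 \\+ 0 \\+ 0 = 0")
  expect_match(md, "Cost per NHB point: NA")
})

test_that("CSV rows round-trip the scorecard values exactly", {
  sc <- arches_card()
  p <- withr::local_tempfile(fileext = ".csv")
  write_scorecard_csv(sc, p)
  df <- read.csv(p, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 1L)
  expect_equal(df$nhb, sc$nhb$nhb)
  expect_equal(df$clinical_benefit, sc$nhb$clinical_benefit)
  expect_equal(df$toxicity_score, sc$nhb$toxicity_score)
  expect_equal(df$bonus_total, sc$nhb$bonus$total)
  expect_equal(df$monthly_cost_cop, sc$monthly_cost)
  expect_equal(df$cost_per_point_cop, sc$cost_per_point)
})

test_that("comparisons show differences and self-comparison is all zero", {
  a <- arches_card()
  b <- build_scorecard(builtin_fixture("titan"), builtin_dosing("apalutamide"))
  tab <- compare_scorecards(a, b)
  expect_equal(tab$a[tab$component == "cost_per_point_cop"], 199692)
  expect_equal(tab$b[tab$component == "cost_per_point_cop"], 239701)
  expect_equal(tab$difference[tab$component == "nhb"], 52 - 40.75)

  self <- compare_scorecards(a, a)
  expect_true(all(self$difference == 0))
})

test_that("cmd_score runs the fixtures and writes reports", {
  out <- withr::local_tempfile()
  expect_equal(cmd_score(fixture = "arches", dosing = "enzalutamide",
                         output = out, quiet = TRUE), 0L)
  md <- readLines(paste0(out, ".md"))
  expect_true(any(grepl("199,692", md, fixed = TRUE)))
  df <- read.csv(paste0(out, ".csv"))
  expect_equal(df$nhb, 52)

  expect_equal(suppressMessages(
    cmd_score(fixture = "spartan", dosing = "apalutamide", output = out,
              quiet = TRUE)), 0L)
  expect_equal(read.csv(paste0(out, ".csv"))$nhb, 33.46)

  # all four fixture runs exit 0
  for (f in c("prosper", "spartan", "arches", "titan")) {
    d <- if (f %in% c("prosper", "arches")) "enzalutamide" else "apalutamide"
    expect_equal(suppressMessages(cmd_score(fixture = f, dosing = d,
                                            quiet = TRUE)), 0L,
                 label = f)
  }
})

test_that("cmd_score distinguishes I/O, schema and scoring failures", {
  expect_equal(suppressMessages(
    cmd_score(trial_path = "no/such/trial.json", dosing = "enzalutamide",
              quiet = TRUE)), 1L)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema": "oncovalue-trial/1", "trial_name": 5}', bad)
  expect_equal(suppressMessages(
    cmd_score(trial_path = bad, dosing = "enzalutamide", quiet = TRUE)), 2L)

  expect_equal(suppressMessages(
    cmd_score(fixture = "arches", quiet = TRUE)), 3L)  # no dosing given
})

test_that("cmd_score can append a deterministic uncertainty block", {
  out1 <- withr::local_tempfile()
  out2 <- withr::local_tempfile()
  expect_equal(suppressMessages(
    cmd_score(fixture = "prosper", dosing = "enzalutamide", output = out1,
              uncertainty = TRUE, draws = 2000, seed = 5, quiet = TRUE)), 0L)
  expect_equal(suppressMessages(
    cmd_score(fixture = "prosper", dosing = "enzalutamide", output = out2,
              uncertainty = TRUE, draws = 2000, seed = 5, quiet = TRUE)), 0L)
  md1 <- readLines(paste0(out1, ".md"))
  expect_true(any(grepl("NHB 95% interval", md1)))
  expect_identical(md1, readLines(paste0(out2, ".md")))
})

test_that("cmd_compare tabulates two regimens side by side", {
  out <- withr::local_tempfile(fileext = ".csv")
  expect_equal(suppressMessages(
    cmd_compare("arches", "enzalutamide", "titan", "apalutamide",
                output = out, quiet = TRUE)), 0L)
  tab <- read.csv(out, stringsAsFactors = FALSE)
  expect_equal(tab$a[tab$component == "nhb"], 52)
  expect_equal(tab$b[tab$component == "nhb"], 40.75)
  expect_gt(tab$difference[tab$component == "nhb"], 0)
})

test_that("cmd_simulate writes evidence plus a truth sidecar", {
  out <- withr::local_tempfile()
  expect_equal(cmd_simulate(true_hr = 0.7, n_per_arm = 100, seed = 3,
                            output = out), 0L)
  trial <- load_trial_evidence(paste0(out, ".json"))
  expect_s3_class(trial, "trial_evidence")
  truth <- jsonlite::fromJSON(paste0(out, ".truth.json"))
  expect_equal(truth$true_hr, 0.7)
})
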