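# Human-readable report rendering: a six-step markdown walk-through per
# scorecard (mirroring the framework's published table layout), flat CSV
# rows, and side-by-side comparisons.

fmt_cop <- function(x) {
  if (is.na(x)) "NA" else format(x, big.mark = ",", scientific = FALSE)
}

fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

benefit_arithmetic <- function(efficacy, rung, score, config) {
  m <- config$benefit_multipliers
  mul <- function(v) if (v == 1) "" else paste0(" * ", fmt_num(v))
  switch(rung,
    "1.A" = sprintf("(1 - %s) * 100%s = %s",
                    fmt_num(efficacy$death_hr$point), mul(m$os_hr),
                    fmt_num(score)),
    "1.B" = sprintf("100 * (%s - %s) / %s%s = %s",
                    fmt_num(efficacy$median_os$median_test),
                    fmt_num(efficacy$median_os$median_comparator),
                    fmt_num(efficacy$median_os$median_comparator),
                    mul(m$median_os), fmt_num(score)),
    "1.C" = sprintf("(1 - %s) * 100%s = %s",
                    fmt_num(efficacy$progression_hr$point), mul(m$pfs_hr),
                    fmt_num(score)),
    "1.D" = sprintf("100 * (%s - %s) / %s%s = %s",
                    fmt_num(efficacy$median_pfs$median_test),
                    fmt_num(efficacy$median_pfs$median_comparator),
                    fmt_num(efficacy$median_pfs$median_comparator),
                    mul(m$median_pfs), fmt_num(score)),
    "1.E" = sprintf("100 * (%s - %s)%s = %s",
                    fmt_num(efficacy$response$rr_test),
                    fmt_num(efficacy$response$rr_comparator),
                    mul(m$rr), fmt_num(score))
  )
}

#' Render a scorecard as a stepwise markdown report
#'
#' Six labelled sections (clinical benefit, toxicity, bonus points, net
#' health benefit, monthly cost, summary) showing the intermediate
#' arithmetic -- input values, ratios, multipliers and rounded results --
#' for each step.
#'
#' @param scorecard a [build_scorecard()] result.
#' @return A single markdown string.
#' @export
render_stepwise <- function(scorecard) {
  stopifnot(inherits(scorecard, "value_scorecard"))
  p <- scorecard$provenance
  n <- scorecard$nhb
  b <- n$bonus
  lines <- c(
    sprintf("# Value scorecard: %s (%s)", scorecard$trial_name,
            scorecard$regimen_name),
    sprintf("%s vs %s. Config %s.", scorecard$test_label,
            scorecard$comparator_label, p$config_hash),
    "",
    "## Step 1: Clinical benefit",
    sprintf("Rung %s: %s points", p$benefit_rung,
            fmt_num(n$clinical_benefit)),
    sprintf("Arithmetic: %s", p$benefit_arithmetic),
    "",
    "## Step 2: Toxicity",
    sprintf("Point totals: test %s, comparator %s",
            fmt_num(p$toxicity_test_total),
            fmt_num(p$toxicity_comparator_total)),
    sprintf("Recomputed: %s", p$toxicity_arithmetic),
    if (!is.null(p$toxicity_reported)) {
      sprintf("Reported score: %s (source used: %s)",
              fmt_num(p$toxicity_reported), p$toxicity_source)
    },
    sprintf("Toxicity score: %s points", fmt_num(n$toxicity_score)),
    "",
    "## Step 3: Bonus points",
    sprintf("Tail of the curve: %s (%s)", fmt_num(b$tail_points),
            b$tail_verdict),
    sprintf("Palliation: %s, quality of life: %s, treatment-free interval: %s",
            fmt_num(b$palliation_points), fmt_num(b$qol_points),
            fmt_num(b$tfi_points)),
    sprintf("Total bonus: %s points", fmt_num(b$total)),
    "",
    "## Step 4: Net health benefit",
    sprintf("%s + %s + %s = %s (of %s possible)",
            fmt_num(n$clinical_benefit), fmt_num(n$toxicity_score),
            fmt_num(b$total), fmt_num(n$nhb), fmt_num(n$max_possible)),
    "",
    "## Step 5: Monthly cost",
    sprintf("%s tablets/month; %s COP (%s USD)",
            fmt_num(p$tablets_per_month), fmt_cop(scorecard$monthly_cost),
            fmt_num(scorecard$monthly_cost_usd)),
    "",
    "## Step 6: Summary",
    sprintf("Cost per NHB point: %s COP (%s USD)",
            fmt_cop(scorecard$cost_per_point),
            if (is.na(scorecard$cost_per_point)) "NA"
            else fmt_num(scorecard$cost_per_point_usd))
  )
  paste(lines[!vapply(lines, is.null, logical(1))], collapse = "\n")
}

#' Flatten a scorecard to a one-row data frame
#'
#' Machine-readable row with all components, the net health benefit, costs
#' and provenance; numbers are written without thousands separators.
#'
#' @param x a \code{value_scorecard}.
#' @param row.names,optional,... ignored (data frame method signature).
#' @return A one-row \code{data.frame}.
#' @export
as.data.frame.value_scorecard <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(
    trial_name = x$trial_name,
    regimen_name = x$regimen_name,
    benefit_rung = x$provenance$benefit_rung,
    clinical_benefit = x$nhb$clinical_benefit,
    toxicity_score = x$nhb$toxicity_score,
    bonus_tail = x$nhb$bonus$tail_points,
    bonus_palliation = x$nhb$bonus$palliation_points,
    bonus_qol = x$nhb$bonus$qol_points,
    bonus_tfi = x$nhb$bonus$tfi_points,
    bonus_total = x$nhb$bonus$total,
    nhb = x$nhb$nhb,
    monthly_cost_cop = x$monthly_cost,
    monthly_cost_usd = x$monthly_cost_usd,
    cost_per_point_cop = x$cost_per_point,
    cost_per_point_usd = x$cost_per_point_usd,
    config_hash = x$provenance$config_hash,
    stringsAsFactors = FALSE
  )
}

#' Write scorecards to CSV
#'
#' One row per scorecard, in the column layout of
#' [as.data.frame.value_scorecard()].
#'
#' @param scorecards a \code{value_scorecard} or list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_scorecard_csv <- function(scorecards, path) {
  if (inherits(scorecards, "value_scorecard")) {
    scorecards <- list(scorecards)
  }
  df <- do.call(rbind, lapply(scorecards, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Compare two scorecards side by side
#'
#' @param a,b \code{value_scorecard}s.
#' @return A data frame with one row per component: the two values and
#'   their difference (a minus b).
#' @examples
#' a <- build_scorecard(builtin_fixture("arches"),
#'                      builtin_dosing("enzalutamide"))
#' b <- build_scorecard(builtin_fixture("titan"),
#'                      builtin_dosing("apalutamide"))
#' compare_scorecards(a, b)
#' @export
compare_scorecards <- function(a, b) {
  stopifnot(inherits(a, "value_scorecard"), inherits(b, "value_scorecard"))
  components <- c("clinical_benefit", "toxicity_score", "bonus_total",
                  "nhb", "monthly_cost_cop", "cost_per_point_cop")
  da <- as.data.frame(a)
  db <- as.data.frame(b)
  data.frame(
    component = components,
    a = unlist(da[components], use.names = FALSE),
    b = unlist(db[components], use.names = FALSE),
    difference = unlist(da[components], use.names = FALSE) -
      unlist(db[components], use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
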