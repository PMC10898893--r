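# Steps 1-4 of the advanced-disease value framework: clinical benefit,
# toxicity, bonus points and net health benefit.

#' Clinical benefit score (Step 1)
#'
#' Applies the five-rung evidence hierarchy, using the highest-priority rung
#' available and ignoring the rest:
#' \describe{
#'   \item{1.A death HR}{\eqn{(1 - HR) \times 100 \times m_{os\_hr}}}
#'   \item{1.B median OS}{\eqn{100 \times (m_t - m_c)/m_c \times m_{median\_os}}}
#'   \item{1.C progression HR}{\eqn{(1 - HR) \times 100 \times m_{pfs\_hr}}}
#'   \item{1.D median PFS}{as 1.B with the PFS multiplier}
#'   \item{1.E response rate}{\eqn{100 \times (rr_t - rr_c) \times m_{rr}}}
#' }
#' The result is rounded to \code{config$component_decimals}.  A hazard
#' ratio above 1 yields a negative score, reported with a warning rather
#' than clamped: harm should be visible, not hidden.
#'
#' @param efficacy an [efficacy_evidence()].
#' @param config a [scoring_config()].
#' @return Score in points (numeric scalar) with attribute \code{"rung"}
#'   (one of \code{"1.A"}..\code{"1.E"}) naming the evidence used.
#' @examples
#' clinical_benefit_score(
#'   efficacy_evidence(death_hr = hazard_ratio(0.73, 0.61, 0.89))
#' )
#' @export
clinical_benefit_score <- function(efficacy, config = scoring_config()) {
  validate_efficacy_evidence(efficacy, "/")
  m <- config$benefit_multipliers
  if (!is.null(efficacy$death_hr)) {
    rung <- "1.A"
    raw <- (1 - efficacy$death_hr$point) * 100 * m$os_hr
  } else if (!is.null(efficacy$median_os)) {
    rung <- "1.B"
    me <- efficacy$median_os
    if (me$median_comparator <= 0) {
      stop("clinical_benefit_score: comparator median must be positive ",
           "for the median-based rung", call. = FALSE)
    }
    raw <- 100 * (me$median_test - me$median_comparator) /
      me$median_comparator * m$median_os
  } else if (!is.null(efficacy$progression_hr)) {
    rung <- "1.C"
    raw <- (1 - efficacy$progression_hr$point) * 100 * m$pfs_hr
  } else if (!is.null(efficacy$median_pfs)) {
    rung <- "1.D"
    me <- efficacy$median_pfs
    if (me$median_comparator <= 0) {
      stop("clinical_benefit_score: comparator median must be positive ",
           "for the median-based rung", call. = FALSE)
    }
    raw <- 100 * (me$median_test - me$median_comparator) /
      me$median_comparator * m$median_pfs
  } else {
    rung <- "1.E"
    raw <- 100 * (efficacy$response$rr_test - efficacy$response$rr_comparator) *
      m$rr
  }
  score <- round_component(raw, config)
  if (score < 0) {
    warning("clinical benefit is negative (", score,
            " points): the test regimen appears harmful on rung ", rung,
            call. = FALSE)
  }
  structure(score, rung = rung)
}

#' Points for one graded adverse event (Step 2, per entry)
#'
#' Grade 1-2 events score 0.5 points when their frequency is below the
#' 10\% threshold and 1 point at or above it; grade 3-4 events score 1.5
#' below 5\% and 2 at or above.  Thresholds are inclusive on the high side
#' ("\eqn{\ge}").
#'
#' @param grade_band \code{"g1_2"} or \code{"g3_4"}.
#' @param frequency event frequency as a proportion in \code{[0, 1]}.
#' @param config a [scoring_config()].
#' @return Points (numeric scalar).
#' @export
ae_entry_points <- function(grade_band, frequency,
                            config = scoring_config()) {
  check_enum(grade_band, "/grade_band", GRADE_BANDS)
  check_number(frequency, "/frequency", 0, 1)
  if (grade_band == "g1_2") {
    if (frequency < config$low_grade_threshold) {
      config$low_grade_minor_points
    } else {
      config$low_grade_major_points
    }
  } else {
    if (frequency < config$high_grade_threshold) {
      config$high_grade_minor_points
    } else {
      config$high_grade_major_points
    }
  }
}

#' Toxicity point total for one arm (Step 2, per arm)
#'
#' A precomputed total, when present, takes precedence; otherwise the sum
#' of [ae_entry_points()] over the itemized entries (0 for an empty list).
#'
#' @param profile a [toxicity_profile()].
#' @param config a [scoring_config()].
#' @return Total points (numeric scalar).
#' @export
toxicity_points_total <- function(profile, config = scoring_config()) {
  validate_toxicity_profile(profile, "/")
  if (!is.null(profile$precomputed_total)) {
    return(profile$precomputed_total)
  }
  if (length(profile$entries) == 0L) return(0)
  sum(vapply(profile$entries, function(e) {
    ae_entry_points(e$grade_band, e$frequency, config)
  }, numeric(1)))
}

#' Toxicity score (Step 2)
#'
#' \eqn{(1 - T_{test}/T_{comparator}) \times 20}, negative when the test
#' regimen is more toxic.  The ratio is truncated to
#' \code{config$ratio_decimals} decimal places before multiplication and the
#' score rounded to \code{config$component_decimals} -- the arithmetic
#' convention of the published worked examples (27/22 is taken as 1.2272,
#' giving -4.54).
#'
#' @param test_total,comparator_total per-arm toxicity point totals;
#'   \code{comparator_total} must be positive.
#' @param config a [scoring_config()].
#' @return Score in points (numeric scalar).
#' @examples
#' toxicity_score(44.5, 40)  # -2.25
#' @export
toxicity_score <- function(test_total, comparator_total,
                           config = scoring_config()) {
  check_number(test_total, "/test_total", lower = 0)
  check_number(comparator_total, "/comparator_total")
  if (comparator_total <= 0) {
    stop("toxicity_score: comparator point total must be positive ",
         "(the relative difference is undefined at ", comparator_total, ")",
         call. = FALSE)
  }
  ratio <- truncate_ratio(test_total / comparator_total, config)
  round_component((1 - ratio) * config$toxicity_multiplier, config)
}

#' Tail-of-the-curve bonus (Step 3.A)
#'
#' Eligibility at the survival-curve point twice the comparator median:
#' the comparator's surviving proportion must exceed the 20\% floor the rule
#' assumes, and the test arm's proportion must be at least 50\% greater in
#' relative terms.  When eligible, the points are \code{awarded_points} if
#' the evidence supplies them (the framework leaves the magnitude, up to the
#' 20-point maximum, to the assessor) and the full maximum otherwise.  An
#' assessment time differing from twice the comparator median by more than
#' 5\% is flagged with a warning.
#'
#' @param tail a [tail_of_curve()], or \code{NULL} when the curve point was
#'   not reached or not reported (0 points).
#' @param config a [scoring_config()].
#' @return Points (numeric scalar) with attributes \code{"eligible"}
#'   (logical) and \code{"reason"} (character).
#' @export
tail_of_curve_bonus <- function(tail, config = scoring_config()) {
  if (is.null(tail)) {
    return(structure(0, eligible = FALSE,
                     reason = "no tail-of-curve evidence"))
  }
  validate_tail_of_curve(tail, "/tail/")
  expected <- 2 * tail$comparator_median
  if (abs(tail$assessment_time - expected) > 0.05 * expected) {
    warning(sprintf(paste("tail-of-curve assessment time %.1f months is not",
                          "twice the comparator median (expected %.1f)"),
                    tail$assessment_time, expected), call. = FALSE)
  }
  if (tail$prop_comparator <= config$tail_comparator_floor) {
    return(structure(0, eligible = FALSE,
                     reason = sprintf(
                       "comparator surviving proportion %.3f not above the %.0f%% floor",
                       tail$prop_comparator, 100 * config$tail_comparator_floor)))
  }
  improvement <- (tail$prop_test - tail$prop_comparator) /
    tail$prop_comparator
  if (improvement < config$tail_improvement_threshold) {
    return(structure(0, eligible = FALSE,
                     reason = sprintf(
                       "relative improvement %.3f below the %.0f%% threshold",
                       improvement, 100 * config$tail_improvement_threshold)))
  }
  pts <- if (is.null(tail$awarded_points)) {
    config$tail_max_points
  } else {
    min(max(tail$awarded_points, 0), config$tail_max_points)
  }
  structure(pts, eligible = TRUE,
            reason = sprintf("relative improvement %.3f at %.1f months",
                             improvement, tail$assessment_time))
}

#' Bonus-point breakdown (Step 3)
#'
#' Tail-of-curve points from [tail_of_curve_bonus()], plus the three
#' categorical bonuses: palliation of symptoms, quality of life and
#' treatment-free interval each contribute their configured 10 points iff
#' the corresponding significance flag is \code{TRUE}; \code{FALSE} or
#' absent scores 0.
#'
#' @param bonus a [bonus_evidence()].
#' @param config a [scoring_config()].
#' @return An object of class \code{bonus_breakdown}: list with
#'   \code{tail_points}, \code{palliation_points}, \code{qol_points},
#'   \code{tfi_points}, \code{total} (the exact sum) and
#'   \code{tail_verdict}.
#' @export
categorical_bonus <- function(bonus, config = scoring_config()) {
  validate_bonus_evidence(bonus, "/")
  tail_pts <- tail_of_curve_bonus(bonus$tail, config)
  flag_points <- function(flag, pts) if (isTRUE(flag)) pts else 0
  out <- list(
    tail_points = as.numeric(tail_pts),
    palliation_points = flag_points(bonus$palliation_significant,
                                    config$palliation_points),
    qol_points = flag_points(bonus$qol_significant, config$qol_points),
    tfi_points = flag_points(bonus$tfi_significant, config$tfi_points),
    tail_verdict = attr(tail_pts, "reason")
  )
  out$total <- out$tail_points + out$palliation_points + out$qol_points +
    out$tfi_points
  structure(out, class = "bonus_breakdown")
}

#' Net health benefit (Step 4)
#'
#' The exact sum of the (already rounded) clinical benefit, toxicity score
#' and total bonus points.  A result above the configured nominal maximum
#' triggers a warning.
#'
#' @param clinical_benefit Step-1 score in points.
#' @param toxicity Step-2 score in points (sign carries direction).
#' @param bonus a [categorical_bonus()] breakdown.
#' @param config a [scoring_config()].
#' @return An object of class \code{net_health_benefit}: list with
#'   \code{clinical_benefit}, \code{toxicity_score}, \code{bonus},
#'   \code{nhb} and \code{max_possible}.
#' @examples
#' b <- categorical_bonus(bonus_evidence(palliation_significant = TRUE))
#' net_health_benefit(33, -2.25, b)$nhb  # 40.75
#' @export
net_health_benefit <- function(clinical_benefit, toxicity, bonus,
                               config = scoring_config()) {
  stopifnot(inherits(bonus, "bonus_breakdown"))
  check_number(as.numeric(clinical_benefit), "/clinical_benefit")
  check_number(as.numeric(toxicity), "/toxicity")
  nhb <- as.numeric(clinical_benefit) + as.numeric(toxicity) + bonus$total
  if (nhb > config$max_nhb) {
    warning("net health benefit ", nhb, " exceeds the nominal maximum of ",
            config$max_nhb, " points", call. = FALSE)
  }
  structure(list(clinical_benefit = as.numeric(clinical_benefit),
                 toxicity_score = as.numeric(toxicity),
                 bonus = bonus,
                 nhb = nhb,
                 max_possible = config$max_nhb),
            class = "net_health_benefit")
}

#' @export
print.net_health_benefit <- function(x, ...) {
  cat(sprintf(paste0("<net_health_benefit> %s = %s (benefit) + %s (toxicity)",
                     " + %s (bonus), of %s possible\n"),
              format(x$nhb), format(x$clinical_benefit),
              format(x$toxicity_score), format(x$bonus$total),
              format(x$max_possible)))
  invisible(x)
}
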