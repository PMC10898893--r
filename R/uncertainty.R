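# Monte-Carlo propagation of hazard-ratio confidence intervals into net
# health benefit and cost-per-point intervals.
#
# This is an extension of the scoring pipeline: the source evidence reports
# 95% CIs around each hazard ratio but propagates only the point estimates.
# Toxicity and bonus points are held fixed (no uncertainty distributions
# exist for them), so NHB is a decreasing affine map of the sampled HR.

# Evaluate code with a local, seeded RNG stream; the caller's stream is
# untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Sample hazard ratios from a reported point estimate and 95\% CI
#'
#' Standard meta-analytic convention: log HR is normal with mean
#' \eqn{\ln(point)} and standard error
#' \eqn{(\ln ci_{high} - \ln ci_{low}) / (2 \times 1.959964)}.
#' A degenerate interval (low = point = high) yields constant draws.
#'
#' @param hr a [hazard_ratio()].
#' @param n_draws number of draws (>= 1).
#' @param seed RNG seed; identical (seed, n_draws) give identical draws.
#' @return Numeric vector of positive hazard ratios.
#' @examples
#' draws <- sample_hr(hazard_ratio(0.73, 0.61, 0.89), 1000, seed = 1)
#' @export
sample_hr <- function(hr, n_draws, seed) {
  validate_hazard_ratio(hr, "/")
  if (!is.numeric(n_draws) || n_draws < 1) {
    stop("sample_hr: n_draws must be at least 1", call. = FALSE)
  }
  se <- (log(hr$ci_high) - log(hr$ci_low)) / (2 * stats::qnorm(0.975))
  if (se == 0) return(rep(hr$point, n_draws))
  with_seed(seed, exp(stats::rnorm(n_draws, log(hr$point), se)))
}

#' Monte-Carlo interval for NHB and cost per point
#'
#' Samples the death hazard ratio with [sample_hr()], maps each draw through
#' the scorecard (clinical benefit rounded exactly as in the deterministic
#' pipeline; toxicity, bonus and cost fixed at their scorecard values) and
#' summarizes NHB and cost-per-point quantiles.  Quantiles use the inverse
#' empirical CDF (\code{type = 1}), so for this strictly decreasing map the
#' NHB quantile at probability p equals the scorecard evaluated at the HR
#' quantile at 1 - p, draw set by draw set.
#'
#' Draws with non-positive NHB have no defined cost per point and are
#' dropped from the cost quantiles (with a warning reporting how many).
#'
#' @param trial a [trial_evidence()] whose efficacy carries a death HR.
#' @param dosing a [regimen_dosing()].
#' @param config a [scoring_config()].
#' @param n_draws number of Monte-Carlo draws.
#' @param seed RNG seed.
#' @param probs quantile probabilities.
#' @param toxicity_source passed to [build_scorecard()].
#' @return An object of class \code{uncertainty_summary}: list with
#'   \code{n_draws}, \code{seed}, \code{nhb_quantiles},
#'   \code{cost_per_point_quantiles}, \code{hr_quantiles} and the fixed
#'   \code{toxicity_score} / \code{bonus_total} used.
#' @export
nhb_interval <- function(trial, dosing, config = scoring_config(),
                         n_draws = 10000, seed = 1,
                         probs = c(0.025, 0.5, 0.975),
                         toxicity_source = c("reported", "recomputed")) {
  validate_trial_evidence(trial)
  if (is.null(trial$efficacy$death_hr)) {
    stop("nhb_interval: trial must report a death hazard ratio with CI",
         call. = FALSE)
  }
  toxicity_source <- match.arg(toxicity_source)
  base <- suppressWarnings(
    build_scorecard(trial, dosing, config, toxicity_source)
  )
  fixed <- base$nhb$toxicity_score + base$nhb$bonus$total

  draws <- sample_hr(trial$efficacy$death_hr, n_draws, seed)
  cb <- round_component((1 - draws) * 100 * config$benefit_multipliers$os_hr,
                        config)
  nhb <- cb + fixed
  cpp <- ifelse(nhb > 0, round(base$monthly_cost / nhb), NA_real_)
  n_undef <- sum(is.na(cpp))
  if (n_undef > 0) {
    warning("cost per point undefined for ", n_undef, " of ", n_draws,
            " draws (non-positive NHB); dropped from cost quantiles",
            call. = FALSE)
  }

  structure(list(
    n_draws = as.integer(n_draws),
    seed = as.integer(seed),
    nhb_quantiles = stats::quantile(nhb, probs, type = 1, names = TRUE),
    cost_per_point_quantiles =
      stats::quantile(cpp, probs, type = 1, names = TRUE, na.rm = TRUE),
    hr_quantiles = stats::quantile(draws, probs, type = 1, names = TRUE),
    toxicity_score = base$nhb$toxicity_score,
    bonus_total = base$nhb$bonus$total,
    monthly_cost = base$monthly_cost
  ), class = "uncertainty_summary")
}

#' @export
print.uncertainty_summary <- function(x, ...) {
  cat("<uncertainty_summary> ", x$n_draws, " draws, seed ", x$seed, "\n",
      sep = "")
  cat("  NHB quantiles:\n")
  print(x$nhb_quantiles)
  cat("  cost per NHB point quantiles (COP):\n")
  print(x$cost_per_point_quantiles)
  invisible(x)
}
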