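# Synthetic two-arm trial generator with known ground truth.
#
# Survival is exponential in both arms (test hazard = true_hr x comparator
# hazard), with no censoring, so every scoring quantity has a closed form:
# the comparator's surviving fraction at twice its own median is exactly
# 0.25, and the test arm's is 0.25^true_hr.  Adverse events are independent
# binomial draws at the specified per-arm frequencies.  Survival and
# adverse-event draws use separate seeded streams, so changing the AE
# specification does not perturb the survival draws under the same seed.

#' Simulation configuration for a synthetic two-arm trial
#'
#' @param true_hr true hazard ratio (test vs comparator, > 0).
#' @param comparator_median true comparator median survival in months (> 0).
#' @param n_per_arm patients per arm (the two-arm total must allow at least
#'   10 events, i.e. \code{n_per_arm >= 5} without censoring).
#' @param ae_spec data frame with columns \code{term}, \code{grade_band},
#'   \code{freq_test}, \code{freq_comparator} (frequencies as proportions);
#'   may have zero rows.
#' @param bonus_truth named list of logical flags \code{palliation},
#'   \code{qol}, \code{tfi}.
#' @param seed integer RNG seed.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(true_hr, comparator_median = 12,
                              n_per_arm = 500,
                              ae_spec = empty_ae_spec(),
                              bonus_truth = list(palliation = FALSE,
                                                 qol = FALSE, tfi = FALSE),
                              seed = 1) {
  check_number(true_hr, "/true_hr", lower = 1e-12)
  check_number(comparator_median, "/comparator_median", lower = 1e-12)
  check_number(n_per_arm, "/n_per_arm", lower = 2)
  stopifnot(is.data.frame(ae_spec),
            all(c("term", "grade_band", "freq_test",
                  "freq_comparator") %in% names(ae_spec)))
  if (nrow(ae_spec)) {
    stopifnot(all(ae_spec$grade_band %in% GRADE_BANDS),
              all(ae_spec$freq_test >= 0 & ae_spec$freq_test <= 1),
              all(ae_spec$freq_comparator >= 0 &
                    ae_spec$freq_comparator <= 1))
  }
  structure(list(true_hr = true_hr, comparator_median = comparator_median,
                 n_per_arm = as.integer(n_per_arm), ae_spec = ae_spec,
                 bonus_truth = bonus_truth, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
empty_ae_spec <- function() {
  data.frame(term = character(), grade_band = character(),
             freq_test = numeric(), freq_comparator = numeric(),
             stringsAsFactors = FALSE)
}

#' Closed-form tail-of-curve proportions under exponential survival
#'
#' At twice its own median, an exponential comparator arm has surviving
#' fraction \eqn{0.5^2 = 0.25} regardless of the median; the test arm, with
#' proportional hazard \code{true_hr}, has \eqn{0.25^{true\_hr}}.  The
#' 50\%-improvement eligibility rule therefore holds exactly when
#' \eqn{0.25^{hr} \ge 1.5 \times 0.25}, i.e. for
#' \eqn{hr \le \ln(0.375)/\ln(0.25) \approx 0.7075}.
#'
#' @param true_hr true hazard ratio (> 0).
#' @param comparator_median comparator median (unused in the closed form;
#'   kept for interface symmetry with the simulator).
#' @return Named numeric vector \code{c(comparator = 0.25, test =
#'   0.25^true_hr)}.
#' @examples
#' true_tail_proportions(0.5)  # comparator 0.25, test 0.5
#' @export
true_tail_proportions <- function(true_hr, comparator_median = 12) {
  check_number(true_hr, "/true_hr", lower = 1e-12)
  c(comparator = 0.25, test = 0.25^true_hr)
}

#' True hazard ratio at the tail-of-curve eligibility boundary
#'
#' @param config a [scoring_config()]; the boundary depends on the
#'   configured relative-improvement threshold.
#' @return The hazard ratio below which the exponential-model tail rule is
#'   satisfied (about 0.7075 at the default 50\% threshold).
#' @export
tail_eligibility_boundary <- function(config = scoring_config()) {
  log(0.25 * (1 + config$tail_improvement_threshold)) / log(0.25)
}

#' Simulate a two-arm trial and summarize it as trial evidence
#'
#' Draws exponential event times in each arm, estimates the hazard ratio by
#' Cox partial likelihood ([survival::coxph()]) with its Wald 95\% CI,
#' measures the empirical surviving proportions at twice the comparator's
#' empirical median, draws per-term adverse-event frequencies as binomial
#' proportions, and assembles a schema-valid [trial_evidence()] together
#' with the generating truth.
#'
#' @param sim a [simulation_config()].
#' @return A list with elements \code{trial} (a [trial_evidence()]) and
#'   \code{truth} (the generating parameters plus closed-form tail
#'   proportions).
#' @examples
#' out <- simulate_trial(simulation_config(true_hr = 0.7, n_per_arm = 200,
#'                                         seed = 42))
#' out$trial$efficacy$death_hr$point
#' @export
simulate_trial <- function(sim) {
  stopifnot(inherits(sim, "simulation_config"))
  n <- sim$n_per_arm
  if (2L * n < 10L) {
    stop("simulate_trial: fewer than 10 events total (n_per_arm = ", n,
         "); the hazard ratio cannot be estimated", call. = FALSE)
  }
  lambda_c <- log(2) / sim$comparator_median
  lambda_t <- sim$true_hr * lambda_c

  surv <- with_seed(sim$seed, {
    list(test = stats::rexp(n, lambda_t),
         comparator = stats::rexp(n, lambda_c))
  })

  arm <- c(rep(1L, n), rep(0L, n))
  time <- c(surv$test, surv$comparator)
  fit <- survival::coxph(survival::Surv(time, rep(1L, 2L * n)) ~ arm)
  est <- unname(exp(stats::coef(fit)))
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  z <- stats::qnorm(0.975)
  hr_hat <- hazard_ratio(est, exp(log(est) - z * se), exp(log(est) + z * se),
                         endpoint = "overall_survival")

  med_c <- stats::median(surv$comparator)
  t2 <- 2 * med_c
  tail_ev <- tail_of_curve(
    comparator_median = med_c, assessment_time = t2,
    prop_test = mean(surv$test > t2),
    prop_comparator = mean(surv$comparator > t2)
  )

  # independent stream for adverse events
  ae <- sim$ae_spec
  if (nrow(ae)) {
    freqs <- with_seed(sim$seed + 499979L, {
      list(test = stats::rbinom(nrow(ae), n, ae$freq_test) / n,
           comparator = stats::rbinom(nrow(ae), n, ae$freq_comparator) / n)
    })
    make_entries <- function(f) {
      lapply(seq_len(nrow(ae)), function(i) {
        adverse_event(ae$term[i], ae$grade_band[i], f[i])
      })
    }
    tox_test <- toxicity_profile(entries = make_entries(freqs$test))
    tox_comp <- toxicity_profile(entries = make_entries(freqs$comparator))
  } else {
    tox_test <- toxicity_profile(precomputed_total = 0)
    tox_comp <- toxicity_profile(precomputed_total = 0)
  }

  trial <- trial_evidence(
    trial_name = sprintf("SIM-hr%.4g-seed%d", sim$true_hr, sim$seed),
    test_label = "test regimen",
    comparator_label = "comparator",
    efficacy = efficacy_evidence(death_hr = hr_hat),
    toxicity_test = tox_test,
    toxicity_comparator = tox_comp,
    bonus = bonus_evidence(
      tail = tail_ev,
      palliation_significant = isTRUE(sim$bonus_truth$palliation),
      qol_significant = isTRUE(sim$bonus_truth$qol),
      tfi_significant = isTRUE(sim$bonus_truth$tfi)
    ),
    metadata = list(synthetic = "simulated under the exponential model")
  )

  truth <- list(true_hr = sim$true_hr,
                comparator_median = sim$comparator_median,
                n_per_arm = n,
                tail_proportions = true_tail_proportions(sim$true_hr),
                bonus_truth = sim$bonus_truth,
                seed = sim$seed)
  list(trial = trial, truth = truth)
}

#' Hazard-ratio recovery experiment over a grid of true values
#'
#' For each true hazard ratio in \code{true_hrs}, simulates
#' \code{replicates} independent trials and reports the mean estimated HR,
#' the mean clinical benefit score computed from the estimates, and the
#' fraction of replicates whose empirical tail-of-curve evidence satisfies
#' the eligibility rule.  Under the exponential model the eligibility rate
#' crosses 50\% at a true HR of about 0.7075 (see
#' [tail_eligibility_boundary()]).
#'
#' @param true_hrs numeric vector of true hazard ratios.
#' @param n_per_arm patients per arm per replicate.
#' @param replicates replicates per grid point.
#' @param seed base seed; replicate seeds are derived deterministically.
#' @param comparator_median true comparator median in months.
#' @param config a [scoring_config()].
#' @return A data frame with one row per grid point: \code{true_hr},
#'   \code{mean_hr_hat}, \code{mean_clinical_benefit},
#'   \code{tail_eligibility_rate}.
#' @export
recovery_experiment <- function(true_hrs, n_per_arm = 1000,
                                replicates = 20, seed = 1,
                                comparator_median = 12,
                                config = scoring_config()) {
  stopifnot(length(true_hrs) >= 1)
  rows <- lapply(seq_along(true_hrs), function(i) {
    hr <- true_hrs[i]
    hr_hats <- numeric(replicates)
    benefits <- numeric(replicates)
    eligible <- logical(replicates)
    for (r in seq_len(replicates)) {
      out <- simulate_trial(simulation_config(
        true_hr = hr, comparator_median = comparator_median,
        n_per_arm = n_per_arm,
        seed = seed + 7919L * (i - 1L) + r
      ))
      hr_hats[r] <- out$trial$efficacy$death_hr$point
      benefits[r] <- suppressWarnings(
        as.numeric(clinical_benefit_score(out$trial$efficacy, config))
      )
      eligible[r] <- isTRUE(attr(
        tail_of_curve_bonus(out$trial$bonus$tail, config), "eligible"))
    }
    data.frame(true_hr = hr,
               mean_hr_hat = mean(hr_hats),
               mean_clinical_benefit = mean(benefits),
               tail_eligibility_rate = mean(eligible))
  })
  do.call(rbind, rows)
}
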