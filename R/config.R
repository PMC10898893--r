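#' Framework scoring configuration
#'
#' Collects every numeric constant of the advanced-disease value framework in
#' one versioned object: adverse-event point values and their frequency
#' thresholds, the toxicity multiplier, the clinical-benefit hierarchy
#' multipliers, bonus point values and tail-of-curve eligibility rules, the
#' nominal score ceiling, rounding conventions, the month length used for
#' costing and the COP/USD conversion rate.
#'
#' Defaults reproduce the framework as applied to the enzalutamide /
#' apalutamide prostate-cancer comparisons: grade 1-2 adverse events score
#' 0.5 points below a 10\% frequency and 1 point at or above it; grade 3-4
#' events score 1.5 below 5\% and 2 at or above; the relative toxicity
#' difference is multiplied by 20.  The toxicity ratio (test total /
#' comparator total) is truncated to \code{ratio_decimals} decimal places
#' before multiplication and every component score is rounded to
#' \code{component_decimals} decimals before summation -- the convention that
#' reproduces the published worked scores.
#'
#' @param low_grade_minor_points points for a grade 1-2 event below threshold.
#' @param low_grade_major_points points for a grade 1-2 event at/above threshold.
#' @param low_grade_threshold frequency threshold for grade 1-2 events.
#' @param high_grade_minor_points points for a grade 3-4 event below threshold.
#' @param high_grade_major_points points for a grade 3-4 event at/above threshold.
#' @param high_grade_threshold frequency threshold for grade 3-4 events.
#' @param toxicity_multiplier multiplier applied to the relative toxicity
#'   difference.
#' @param benefit_multipliers named list of scaling multipliers for the five
#'   rungs of the clinical-benefit hierarchy (\code{os_hr}, \code{median_os},
#'   \code{pfs_hr}, \code{median_pfs}, \code{rr}).
#' @param tail_improvement_threshold minimum relative improvement in the
#'   surviving proportion for tail-of-curve eligibility (0.5 = 50\%).
#' @param tail_comparator_floor minimum comparator surviving proportion
#'   assumed by the tail rule (0.20 = ">20\% survive with the standard").
#' @param tail_max_points maximum tail-of-curve bonus.
#' @param palliation_points,qol_points,tfi_points categorical bonus values.
#' @param max_nhb nominal maximum net health benefit ("out of 180 possible
#'   points" in the framework text; the component caps used here sum to 170 --
#'   the discrepancy is documented, not resolved).
#' @param component_decimals decimals each component score is rounded to
#'   before summation.
#' @param ratio_decimals decimals the toxicity ratio is truncated to before
#'   multiplication.
#' @param cop_per_usd Colombian pesos per US dollar used by [to_usd()].
#' @param days_per_month month length (days) used by the cost model.
#' @return An object of class \code{scoring_config} (a named list).
#' @examples
#' cfg <- scoring_config()
#' cfg$toxicity_multiplier
#' @export
scoring_config <- function(low_grade_minor_points = 0.5,
                           low_grade_major_points = 1.0,
                           low_grade_threshold = 0.10,
                           high_grade_minor_points = 1.5,
                           high_grade_major_points = 2.0,
                           high_grade_threshold = 0.05,
                           toxicity_multiplier = 20,
                           benefit_multipliers = list(os_hr = 1.0,
                                                      median_os = 1.0,
                                                      pfs_hr = 0.8,
                                                      median_pfs = 0.8,
                                                      rr = 0.7),
                           tail_improvement_threshold = 0.50,
                           tail_comparator_floor = 0.20,
                           tail_max_points = 20,
                           palliation_points = 10,
                           qol_points = 10,
                           tfi_points = 10,
                           max_nhb = 180,
                           component_decimals = 2L,
                           ratio_decimals = 4L,
                           cop_per_usd = 3915.3,
                           days_per_month = 30L) {
  cfg <- list(
    schema = "oncovalue-config/1",
    low_grade_minor_points = low_grade_minor_points,
    low_grade_major_points = low_grade_major_points,
    low_grade_threshold = low_grade_threshold,
    high_grade_minor_points = high_grade_minor_points,
    high_grade_major_points = high_grade_major_points,
    high_grade_threshold = high_grade_threshold,
    toxicity_multiplier = toxicity_multiplier,
    benefit_multipliers = benefit_multipliers,
    tail_improvement_threshold = tail_improvement_threshold,
    tail_comparator_floor = tail_comparator_floor,
    tail_max_points = tail_max_points,
    palliation_points = palliation_points,
    qol_points = qol_points,
    tfi_points = tfi_points,
    max_nhb = max_nhb,
    component_decimals = as.integer(component_decimals),
    ratio_decimals = as.integer(ratio_decimals),
    cop_per_usd = cop_per_usd,
    days_per_month = as.integer(days_per_month)
  )
  validate_scoring_config(cfg)
  structure(cfg, class = "scoring_config")
}

validate_scoring_config <- function(cfg) {
  thr <- c(low_grade_threshold = cfg$low_grade_threshold,
           high_grade_threshold = cfg$high_grade_threshold,
           tail_comparator_floor = cfg$tail_comparator_floor)
  bad <- thr[thr <= 0 | thr >= 1]
  if (length(bad)) {
    stop("scoring_config: thresholds must lie in (0, 1): ",
         paste(names(bad), collapse = ", "), call. = FALSE)
  }
  pts <- c(cfg$low_grade_minor_points, cfg$low_grade_major_points,
           cfg$high_grade_minor_points, cfg$high_grade_major_points,
           cfg$toxicity_multiplier, cfg$tail_max_points,
           cfg$palliation_points, cfg$qol_points, cfg$tfi_points,
           cfg$max_nhb)
  if (any(pts < 0)) {
    stop("scoring_config: point values must be non-negative", call. = FALSE)
  }
  need <- c("os_hr", "median_os", "pfs_hr", "median_pfs", "rr")
  if (!all(need %in% names(cfg$benefit_multipliers))) {
    stop("scoring_config: benefit_multipliers must name all of: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (cfg$cop_per_usd <= 0) {
    stop("scoring_config: cop_per_usd must be positive", call. = FALSE)
  }
  if (cfg$days_per_month < 28L) {
    stop("scoring_config: days_per_month must be at least 28", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("<scoring_config> (", x$schema, ")\n", sep = "")
  cat("  AE points g1-2: ", x$low_grade_minor_points, " (<",
      100 * x$low_grade_threshold, "%) / ", x$low_grade_major_points,
      "; g3-4: ", x$high_grade_minor_points, " (<",
      100 * x$high_grade_threshold, "%) / ", x$high_grade_major_points, "\n",
      sep = "")
  cat("  toxicity multiplier ", x$toxicity_multiplier,
      ", bonus: tail <=", x$tail_max_points, ", palliation ",
      x$palliation_points, ", QoL ", x$qol_points, ", TFI ",
      x$tfi_points, "\n", sep = "")
  cat("  max NHB ", x$max_nhb, ", rounding ", x$component_decimals,
      " dp (ratio ", x$ratio_decimals, " dp), ", x$days_per_month,
      "-day month, ", x$cop_per_usd, " COP/USD\n", sep = "")
  cat("  hash ", config_hash(x), "\n", sep = "")
  invisible(x)
}

# Round a component score to the configured number of decimals.
round_component <- function(x, config) {
  round(x, config$component_decimals)
}

# Truncate a ratio to the configured number of decimals (toward zero), with
# a tiny epsilon guard against binary representation just below an exact
# decimal.  This is the convention the published worked examples use
# (27/22 -> 1.2272, not 1.2273).
truncate_ratio <- function(x, config) {
  scale <- 10^config$ratio_decimals
  trunc(x * scale + sign(x) * 1e-9) / scale
}

#' Read a scoring configuration from JSON
#'
#' The document may set any subset of the [scoring_config()] arguments
#' (lower-snake-case keys); unspecified constants keep their defaults.
#' Unknown keys are rejected.
#'
#' @param path path to a JSON configuration file.
#' @return A [scoring_config()].
#' @export
read_scoring_config <- function(path) {
  if (!file.exists(path)) {
    stop("scoring config file not found: ", path, call. = FALSE)
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  doc$schema <- NULL
  allowed <- names(formals(scoring_config))
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown)) {
    stop("scoring config: unknown field \"", unknown[[1L]], "\"",
         call. = FALSE)
  }
  if (!is.null(doc$benefit_multipliers)) {
    doc$benefit_multipliers <- as.list(doc$benefit_multipliers)
  }
  do.call(scoring_config, doc)
}

#' Provenance fingerprint of a scoring configuration
#'
#' A short FNV-1a hash of the configuration's canonical JSON, printed in
#' report headers so a scorecard can be traced to the exact constants that
#' produced it.  Not cryptographic.
#'
#' @param config a [scoring_config()].
#' @return An 8-character hexadecimal string.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(json)))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply in doubles via a 16-bit split
    h <- ((h %/% 65536 * p) %% 65536 * 65536 + h %% 65536 * p) %% 2^32
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
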