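# JSON readers/writers for trial evidence (schema "oncovalue-trial/1").
#
# Documents are UTF-8 JSON with lower-snake-case keys.  Loading validates
# against the schema: unknown fields are rejected and the first failure is
# reported with its JSON-pointer path.  Writing emits key-sorted JSON so
# that write -> load -> write is byte-stable.

TRIAL_SCHEMA <- "oncovalue-trial/1"

trial_fields <- list(
  top = c("schema", "trial_name", "test_label", "comparator_label",
          "efficacy", "toxicity_test", "toxicity_comparator", "bonus",
          "reported_toxicity_score", "frequency_unit", "metadata"),
  efficacy = c("death_hr", "median_os", "progression_hr", "median_pfs",
               "response"),
  hr = c("point", "ci_low", "ci_high", "endpoint"),
  median = c("median_test", "median_comparator", "endpoint"),
  response = c("rr_test", "rr_comparator"),
  toxicity = c("entries", "precomputed_total"),
  ae = c("term", "grade_band", "frequency"),
  bonus = c("tail", "palliation_significant", "qol_significant",
            "tfi_significant", "notes"),
  tail = c("comparator_median", "assessment_time", "prop_test",
           "prop_comparator", "awarded_points")
)

check_known_fields <- function(obj, allowed, path) {
  unknown <- setdiff(names(obj), allowed)
  if (length(unknown)) {
    ov_stop(paste0(path, unknown[[1L]]), "unknown field")
  }
  invisible(obj)
}

#' Load trial evidence from a JSON document
#'
#' Reads and validates a two-arm trial evidence summary.  Adverse-event
#' frequencies may be stored as proportions (default) or, when the document
#' sets \code{"frequency_unit": "percent"}, as percentages that are converted
#' to proportions on load -- removing the 10-vs-0.10 ambiguity.
#'
#' @param path path to a JSON file.
#' @param schema_version expected schema identifier.
#' @return A validated [trial_evidence()].
#' @examples
#' p <- fixture_path("prosper")
#' load_trial_evidence(p)$efficacy$death_hr$point
#' @export
load_trial_evidence <- function(path, schema_version = TRIAL_SCHEMA) {
  if (!file.exists(path)) {
    stop("trial evidence file not found: ", path, call. = FALSE)
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_known_fields(doc, trial_fields$top, "/")
  if (!identical(doc$schema, schema_version)) {
    ov_stop("/schema", sprintf("expected \"%s\", got \"%s\"",
                               schema_version,
                               if (is.null(doc$schema)) "<missing>" else doc$schema))
  }
  unit <- doc$frequency_unit
  if (!is.null(unit)) {
    check_enum(unit, "/frequency_unit", c("proportion", "percent"))
  } else {
    unit <- "proportion"
  }
  trial <- parse_trial(doc, percent = identical(unit, "percent"))
  validate_trial_evidence(trial)
  trial
}

parse_trial <- function(doc, percent = FALSE) {
  eff <- doc$efficacy
  if (is.null(eff)) ov_stop("/efficacy", "missing required value")
  check_known_fields(eff, trial_fields$efficacy, "/efficacy/")

  parse_hr <- function(o, path) {
    if (is.null(o)) return(NULL)
    check_known_fields(o, trial_fields$hr, path)
    structure(list(point = o$point, ci_low = o$ci_low, ci_high = o$ci_high,
                   endpoint = o$endpoint %||% "overall_survival"),
              class = "hazard_ratio")
  }
  parse_median <- function(o, path) {
    if (is.null(o)) return(NULL)
    check_known_fields(o, trial_fields$median, path)
    structure(list(median_test = o$median_test,
                   median_comparator = o$median_comparator,
                   endpoint = o$endpoint %||% "overall_survival"),
              class = "median_estimate")
  }
  parse_tox <- function(o, path) {
    if (is.null(o)) ov_stop(path, "missing required value")
    check_known_fields(o, trial_fields$toxicity, path)
    entries <- lapply(seq_along(o$entries), function(i) {
      e <- o$entries[[i]]
      epath <- sprintf("%sentries/%d/", path, i - 1L)
      check_known_fields(e, trial_fields$ae, epath)
      freq <- e$frequency
      if (percent && is.numeric(freq)) freq <- freq / 100
      structure(list(term = e$term, grade_band = e$grade_band,
                     frequency = freq),
                class = "adverse_event")
    })
    structure(list(entries = entries,
                   precomputed_total = o$precomputed_total),
              class = "toxicity_profile")
  }

  bon <- doc$bonus %||% list()
  check_known_fields(bon, trial_fields$bonus, "/bonus/")
  tail_ev <- NULL
  if (!is.null(bon$tail)) {
    check_known_fields(bon$tail, trial_fields$tail, "/bonus/tail/")
    tail_ev <- structure(bon$tail[trial_fields$tail], class = "tail_of_curve")
    names(tail_ev) <- trial_fields$tail
  }

  resp <- NULL
  if (!is.null(eff$response)) {
    check_known_fields(eff$response, trial_fields$response,
                       "/efficacy/response/")
    resp <- structure(list(rr_test = eff$response$rr_test,
                           rr_comparator = eff$response$rr_comparator),
                      class = "response_rates")
  }

  structure(list(
    trial_name = doc$trial_name,
    test_label = doc$test_label,
    comparator_label = doc$comparator_label,
    efficacy = structure(list(
      death_hr = parse_hr(eff$death_hr, "/efficacy/death_hr/"),
      median_os = parse_median(eff$median_os, "/efficacy/median_os/"),
      progression_hr = parse_hr(eff$progression_hr,
                                "/efficacy/progression_hr/"),
      median_pfs = parse_median(eff$median_pfs, "/efficacy/median_pfs/"),
      response = resp
    ), class = "efficacy_evidence"),
    toxicity_test = parse_tox(doc$toxicity_test, "/toxicity_test/"),
    toxicity_comparator = parse_tox(doc$toxicity_comparator,
                                    "/toxicity_comparator/"),
    bonus = structure(list(
      tail = tail_ev,
      palliation_significant = bon$palliation_significant,
      qol_significant = bon$qol_significant,
      tfi_significant = bon$tfi_significant,
      notes = bon$notes %||% list()
    ), class = "bonus_evidence"),
    reported_toxicity_score = doc$reported_toxicity_score,
    metadata = doc$metadata %||% list()
  ), class = "trial_evidence")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strip classes, drop NULLs, sort keys at every level -> stable JSON.
canonical_list <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x <- x[!vapply(x, is.null, logical(1))]
    if (!is.null(names(x)) && all(nzchar(names(x)))) {
      x <- x[order(names(x))]
    }
    lapply(x, canonical_list)
  } else {
    x
  }
}

#' Write trial evidence to JSON
#'
#' Emits a key-sorted, pretty-printed UTF-8 JSON document; writing the same
#' object twice is byte-identical, and [load_trial_evidence()] on the result
#' reproduces the object field-for-field.  Frequencies are always written as
#' proportions.
#'
#' @param trial a valid [trial_evidence()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trial_evidence <- function(trial, path) {
  validate_trial_evidence(trial)
  doc <- canonical_list(c(list(schema = TRIAL_SCHEMA), unclass(trial)))
  # empty lists (notes/metadata/entries) must serialize as {} / [] and
  # round-trip; drop empty optional containers instead
  doc <- drop_empty(doc)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  ok <- tryCatch({
    writeLines(json, path, useBytes = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write trial evidence to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

drop_empty <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, drop_empty)
  keep <- !vapply(x, function(e) is.list(e) && length(e) == 0L, logical(1))
  # toxicity profile "entries" may legitimately be empty alongside a
  # precomputed total; it is reconstructed as empty on load either way
  x[keep]
}

#' Read itemized adverse-event tables from CSV
#'
#' Reads an RFC-4180 CSV with header \code{term,grade_band,arm,frequency}
#' (dot decimal separator; \code{arm} is \code{"test"} or
#' \code{"comparator"}) and returns one [toxicity_profile()] per arm.
#'
#' @param path CSV file path.
#' @param percent if \code{TRUE}, frequencies are percentages and divided by
#'   100 on load.
#' @return A list with elements \code{test} and \code{comparator}.
#' @export
read_adverse_events <- function(path, percent = FALSE) {
  if (!file.exists(path)) {
    stop("adverse-event file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("term", "grade_band", "arm", "frequency")
  if (!identical(sort(names(df)), sort(need))) {
    stop("adverse-event CSV must have header term,grade_band,arm,frequency",
         call. = FALSE)
  }
  if (!all(df$arm %in% c("test", "comparator"))) {
    stop("adverse-event CSV: arm must be \"test\" or \"comparator\"",
         call. = FALSE)
  }
  if (percent) df$frequency <- df$frequency / 100
  make_profile <- function(arm) {
    rows <- df[df$arm == arm, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)  # arm not present in the table
    toxicity_profile(entries = lapply(seq_len(nrow(rows)), function(i) {
      adverse_event(rows$term[i], rows$grade_band[i], rows$frequency[i])
    }))
  }
  list(test = make_profile("test"), comparator = make_profile("comparator"))
}
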