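#' @title Model parameter set
#' @description
#' A `ls_parameters` object bundles every input used by the diagnostic
#' decision tree, the individual patient simulation and the cost-utility
#' engine:
#'
#' * `accuracies`: list of test accuracy entries (`test_id`, `sensitivity`,
#'   `specificity`, optional `conditional_on` naming the preceding test —
#'   BRAF and methylation testing carry distinct accuracies after MSI
#'   versus after IHC).
#' * `hazards`: [hazard_fn()] objects per (cancer, sex, Lynch status),
#'   including metachronous colorectal cancer, stage-specific excess cancer
#'   mortality and general mortality from a life table.
#' * `surveillance`: hazard ratios under colonoscopic surveillance
#'   (`hr_index_crc`, default 0.387; `hr_metachronous_crc`, default 0.533).
#' * `utilities`: Ara-Brazier age/sex population norm coefficients and the
#'   disutility set (metastatic colorectal cancer 0.13 until death;
#'   genetic testing for four months; prophylactic H-BSO, endometrial
#'   cancer and colonoscopy all 0 in the base case).
#' * `econ`: discounting (3.5% per annum for costs and QALYs),
#'   willingness-to-pay (20,000 GBP/QALY), the colonoscopy cost multiplier
#'   (2/3) and the price-year label.
#' * `population`: annual cohort definition, Lynch prevalence, relatives
#'   per mutation-positive proband, uptake probabilities and representative
#'   ages.
#' * `costs`: per-unit costs in GBP.
#' * `policy`: surveillance window (ages 25-75, 2-yearly), H-BSO offer age,
#'   maximum of two colorectal cancers, age-100 horizon.
#' * `provenance`: per-value source tag (`"paper"` or `"synthetic"`).
#'
#' Build one with [generate_parameter_set()] (anchored or random), check it
#' with [validate_parameters()], and perturb it immutably with
#' [apply_univariate_override()].
#' @name ls_parameters
NULL

new_parameter_set <- function(x) {
  stopifnot(is.list(x))
  structure(x, class = "ls_parameters")
}

#' @export
print.ls_parameters <- function(x, ...) {
  pv <- provenance_summary(x)
  cat("Lynch syndrome CEA parameter set\n")
  cat(sprintf("  probands/year: %d, LS prevalence: %.3f\n",
              x$population$n_probands, x$population$ls_prevalence))
  cat(sprintf("  discounting %.1f%%, WTP GBP %s/QALY, price year %s\n",
              100 * x$econ$discount_rate_qalys,
              format(x$econ$wtp, big.mark = ","), x$econ$price_year))
  cat(sprintf("  provenance: %d paper-anchored, %d synthetic values\n",
              pv["paper"], pv["synthetic"]))
  invisible(x)
}

#' Summarise provenance tags of a parameter set
#' @param params a [ls_parameters] object.
#' @return named integer vector with counts of `paper` and `synthetic` tags.
#' @export
provenance_summary <- function(params) {
  tags <- unlist(params$provenance, use.names = FALSE)
  c(paper = sum(tags == "paper"), synthetic = sum(tags == "synthetic"))
}

#' Look up a test accuracy entry
#'
#' @param params a [ls_parameters] object.
#' @param test_id test identifier.
#' @param conditional_on preceding test identifier or `NULL`.
#' @return the accuracy entry (list with `sensitivity`, `specificity`).
#' @export
get_accuracy <- function(params, test_id, conditional_on = NULL) {
  for (a in params$accuracies) {
    if (a$test_id == test_id &&
        identical(a$conditional_on %||% NULL, conditional_on %||% NULL))
      return(a)
  }
  # fall back to an unconditional entry when no conditional one exists
  if (!is.null(conditional_on)) return(get_accuracy(params, test_id, NULL))
  stopf("no accuracy entry for test '%s'", test_id)
}

prob_fields <- function() {
  c("population$ls_prevalence", "population$proportion_female",
    "population$uptake_counselling", "population$uptake_mutation_test",
    "population$uptake_predictive_test", "population$uptake_surveillance",
    "population$uptake_hbso",
    "diagnostics$p_ihc_concordant", "diagnostics$p_sporadic_mlh1_pattern",
    "simulation$p_colonoscopy_complication", "simulation$p_colonoscopy_death",
    "simulation$p_hbso_death")
}

#' Validate a parameter set
#'
#' Checks every structural invariant (probabilities in `[0, 1]`, rates and
#' costs nonnegative, hazard functions well-formed, policy values sane) and
#' returns a report rather than throwing: an empty character vector means
#' the set is valid, otherwise each element names the offending field.
#' Side-effect free and idempotent.
#'
#' @param params a [ls_parameters] object.
#' @return character vector of violations (empty if valid).
#' @export
validate_parameters <- function(params) {
  bad <- character(0)
  note <- function(path, msg) bad <<- c(bad, sprintf("%s: %s", path, msg))

  get_path <- function(path) {
    parts <- strsplit(path, "$", fixed = TRUE)[[1]]
    v <- params
    for (p in parts) {
      if (is.null(v[[p]])) return(NULL)
      v <- v[[p]]
    }
    v
  }

  for (i in seq_along(params$accuracies)) {
    a <- params$accuracies[[i]]
    pre <- sprintf("accuracies[[%d]] (%s)", i, a$test_id %||% "?")
    for (f in c("sensitivity", "specificity")) {
      v <- a[[f]]
      if (is.null(v) || !is.numeric(v) || v < 0 || v > 1)
        note(sprintf("%s$%s", pre, f), "must be a probability in [0, 1]")
    }
  }

  for (p in prob_fields()) {
    v <- get_path(p)
    if (is.null(v) || !is.numeric(v) || any(v < 0 | v > 1))
      note(p, "must be a probability in [0, 1]")
  }

  pop <- params$population
  if (is.null(pop$n_probands) || pop$n_probands <= 0)
    note("population$n_probands", "must be > 0")
  if (is.null(pop$relatives_per_positive_proband) ||
      pop$relatives_per_positive_proband < 0)
    note("population$relatives_per_positive_proband", "must be >= 0")
  ad <- pop$relative_age_distribution
  if (is.null(ad$age) || is.null(ad$prob) || length(ad$age) != length(ad$prob) ||
      any(ad$prob < 0) || abs(sum(ad$prob) - 1) > 1e-9)
    note("population$relative_age_distribution", "probs must be >= 0 and sum to 1")

  econ <- params$econ
  for (f in c("discount_rate_costs", "discount_rate_qalys")) {
    if (is.null(econ[[f]]) || econ[[f]] < 0) note(paste0("econ$", f), "must be >= 0")
  }
  if (is.null(econ$wtp) || econ$wtp <= 0) note("econ$wtp", "must be > 0")
  if (is.null(econ$colonoscopy_cost_multiplier) ||
      econ$colonoscopy_cost_multiplier <= 0 || econ$colonoscopy_cost_multiplier > 1)
    note("econ$colonoscopy_cost_multiplier", "must be in (0, 1]")

  sv <- params$surveillance
  for (f in c("hr_index_crc", "hr_metachronous_crc")) {
    if (is.null(sv[[f]]) || sv[[f]] <= 0 || sv[[f]] > 1)
      note(paste0("surveillance$", f), "must be in (0, 1]")
  }

  ut <- params$utilities
  for (f in c("disutility_metastatic_crc", "disutility_genetic_testing",
              "disutility_hbso", "disutility_ec", "disutility_colonoscopy")) {
    if (is.null(ut[[f]]) || ut[[f]] < 0) note(paste0("utilities$", f), "must be >= 0")
  }
  if (is.null(ut$population_norms) || length(ut$population_norms$female) != 3 ||
      length(ut$population_norms$male) != 3)
    note("utilities$population_norms", "need quadratic coefficients per sex")

  for (f in names(params$costs)) {
    v <- params$costs[[f]]
    if (!is.numeric(v) || any(v < 0)) note(paste0("costs$", f), "must be >= 0")
  }

  for (nm in names(params$hazards)) {
    h <- params$hazards[[nm]]
    if (!inherits(h, "hazard_fn")) { note(paste0("hazards$", nm), "not a hazard_fn"); next }
    if (any(diff(h$knots) <= 0)) note(paste0("hazards$", nm), "knots not increasing")
    if (any(h$rates < 0)) note(paste0("hazards$", nm), "negative rate")
  }

  pol <- params$policy
  if (pol$surveillance_start_age >= pol$surveillance_stop_age)
    note("policy$surveillance_start_age", "must precede stop age")
  if (pol$surveillance_interval <= 0) note("policy$surveillance_interval", "must be > 0")
  if (pol$max_crcs < 1) note("policy$max_crcs", "must be >= 1")
  if (pol$horizon_age <= pol$surveillance_stop_age)
    note("policy$horizon_age", "must exceed surveillance stop age")

  sp <- params$diagnostics$mutation_spectrum
  if (is.null(sp) || any(sp < 0) || abs(sum(sp) - 1) > 1e-9)
    note("diagnostics$mutation_spectrum", "must be a distribution over genes")

  bad
}

#' Override one parameter immutably
#'
#' Returns a new parameter set differing from `params` only at `path`
#' (`$`-separated, e.g. `"utilities$disutility_hbso"`); the original is not
#' modified.  The new value must satisfy the field's invariant.
#'
#' @param params a [ls_parameters] object.
#' @param path `$`-separated field path.
#' @param value replacement value.
#' @return a new [ls_parameters] object.
#' @examples
#' \dontrun{
#' p2 <- apply_univariate_override(p, "utilities$disutility_hbso", 0.1)
#' }
#' @export
apply_univariate_override <- function(params, path, value) {
  parts <- strsplit(path, "$", fixed = TRUE)[[1]]
  # check existence
  v <- params
  for (p in parts) {
    if (!is.list(v) || is.null(v[[p]])) stopf("unknown parameter path '%s'", path)
    v <- v[[p]]
  }
  out <- unclass(params)
  out[[parts]] <- value
  out <- new_parameter_set(out)
  out$provenance[[gsub("\\$", ".", path)]] <- "synthetic"
  rep <- validate_parameters(out)
  if (length(rep) > 0)
    stopf("override of '%s' violates invariants: %s", path, rep[1])
  out
}

#' Write a parameter set to a JSON file
#'
#' The on-disk format is plain structured text (JSON with nested sections);
#' [read_parameters()] round-trips it exactly.
#' @param params a [ls_parameters] object.
#' @param path output file path.
#' @export
write_parameters <- function(params, path) {
  strip <- function(v) {
    if (is.list(v)) lapply(unclass(v), strip)
    else if (is.atomic(v) && !is.null(names(v))) as.list(v)  # keep names
    else v
  }
  jsonlite::write_json(strip(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a parameter set from a JSON file
#' @param path file written by [write_parameters()].
#' @return a [ls_parameters] object.
#' @export
read_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$accuracies <- lapply(x$accuracies, function(a) {
    if (length(a$conditional_on) == 0) a$conditional_on <- NULL
    a
  })
  x$hazards <- lapply(x$hazards, function(h) hazard_fn(h$knots, h$rates))
  x$diagnostics$mutation_spectrum <- unlist(x$diagnostics$mutation_spectrum)
  x$simulation$stage_dist_symptomatic <-
    unlist(x$simulation$stage_dist_symptomatic)
  x$simulation$stage_dist_detected <- unlist(x$simulation$stage_dist_detected)
  new_parameter_set(x)
}

#' Population-norm utility at an age
#'
#' Quadratic age/sex norms in the Ara-Brazier form
#' `u = c0 + c1 * age + c2 * age^2` (the male intercept absorbs the sex
#' coefficient).
#' @param params a [ls_parameters] object.
#' @param age ages in years.
#' @param sex `"male"` or `"female"`.
#' @export
norm_utility <- function(params, age, sex) {
  cf <- params$utilities$population_norms[[sex]]
  cf[1] + cf[2] * age + cf[3] * age^2
}
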