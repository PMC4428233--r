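#' Project surveillance colonoscopy demand over calendar time
#'
#' Treats each calendar year's diagnostic cohort as the base-case cohort
#' shifted in time (stationary demographics and epidemiology): every year
#' a fresh set of surveillance acceptors enters the biennial programme and
#' contributes scheduled colonoscopies attrited by survival (general
#' mortality) and by programme cessation at the stop age.  Demand ramps up
#' to a steady state once the oldest cohort has aged out.
#'
#' @param strategy_id strategy identifier.
#' @param params a validated [ls_parameters] object.
#' @param years number of calendar years to project (>= 1).
#' @param diag optional precomputed diagnostic outcomes (with relatives);
#'   computed from the strategy if omitted.
#' @param population_scale optional scaling ratio (e.g. 400000 divided by
#'   the national population) for per-locality series.
#' @return object of class `ls_demand_series`: data.frame (`year`,
#'   `colonoscopies`) plus `steady_state` and `initial_growth_rate`
#'   attributes.
#' @export
project_demand <- function(strategy_id, params, years = 60, diag = NULL,
                           population_scale = NULL) {
  stopifnot(years >= 1)
  if (is.null(diag)) {
    diag <- cascade_relatives(
      evaluate_probands(build_strategy(strategy_id), params), params)
  }
  pol <- params$policy
  pf <- params$population$proportion_female

  acceptors <- list(
    proband = sum(diag$n_accepting_surveillance),
    relative = sum(diag$n_accepting_surveillance_relatives %||% 0)
  )
  entry_age <- list(
    proband = params$population$proband_start_age,
    relative = params$population$relative_age_distribution$age[1]
  )

  # per-entrant expected colonoscopies by whole years since entry
  offsets_profile <- function(entry, sex) {
    from <- max(entry, pol$surveillance_start_age)
    if (from > pol$surveillance_stop_age) return(numeric(0))
    ages <- seq(from, pol$surveillance_stop_age, by = pol$surveillance_interval)
    h <- params$hazards[[paste0("mortality_", sex)]]
    s <- exp(-(cumulative_hazard(h, ages) - cumulative_hazard(h, entry)))
    data.frame(offset = floor(ages - entry), weight = s)
  }

  demand <- numeric(years)
  for (role in names(acceptors)) {
    for (sex in c("male", "female")) {
      n <- acceptors[[role]] * if (sex == "female") pf else 1 - pf
      if (n == 0) next
      op <- offsets_profile(entry_age[[role]], sex)
      if (nrow(op) == 0) next
      # cohort entering in calendar year c contributes at year c + offset;
      # with identical annual cohorts, year y demand is the cumulative
      # weight of offsets <= y
      for (k in seq_len(nrow(op))) {
        y0 <- op$offset[k] + 1            # 1-based year index
        if (y0 <= years) demand[y0:years] <- demand[y0:years] + n * op$weight[k]
      }
    }
  }
  if (!is.null(population_scale)) demand <- demand * population_scale
  structure(data.frame(year = seq_len(years), colonoscopies = demand),
            class = c("ls_demand_series", "data.frame"),
            steady_state = if (years > 1) demand[years] else demand,
            initial_growth_rate = if (years > 1) mean(diff(demand[seq_len(min(5, years))]))
                                  else demand[1],
            strategy_id = strategy_id)
}

#' Colonoscopy efficiency metrics between two strategies
#'
#' Number-needed-to-scope style ratios: additional colonoscopies per
#' colorectal cancer prevented, per life year gained and per QALY gained,
#' comparing strategy arm `b` (more colonoscopies) against arm `a`.
#' Nonpositive denominators give `NA` entries.  Both undiscounted
#' (life years) and discounted (QALY) variants are reported.
#'
#' @param results_a,results_b `ls_strategy_result` objects (e.g. the
#'   no-testing baseline and a testing strategy).
#' @return list with `colonoscopies_per_crc_prevented`,
#'   `colonoscopies_per_life_year`, `colonoscopies_per_qaly` and the raw
#'   increments.
#' @export
efficiency <- function(results_a, results_b) {
  d_col <- results_b$n_colonoscopies - results_a$n_colonoscopies
  if (d_col < 0) stopf("arm b must have at least as many colonoscopies as arm a")
  d_crc <- results_a$n_crcs - results_b$n_crcs        # prevented
  d_ly <- results_b$life_years_undiscounted - results_a$life_years_undiscounted
  d_q <- results_b$total_qalys - results_a$total_qalys
  ratio <- function(den) if (is.na(den) || den <= 0) NA_real_ else d_col / den
  list(
    colonoscopies_per_crc_prevented = ratio(d_crc),
    colonoscopies_per_life_year = ratio(d_ly),
    colonoscopies_per_qaly = ratio(d_q),
    delta_colonoscopies = d_col,
    delta_crcs_prevented = d_crc,
    delta_life_years = d_ly,
    delta_qalys = d_q
  )
}
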