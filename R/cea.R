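#' Combine diagnostic and management submodels into a strategy result
#'
#' Expands the diagnostic joint counts into management profile cells
#' (role x sex x true status x accepted surveillance x accepted H-BSO),
#' weights the per-profile mean discounted outcomes by the expected cell
#' counts, and adds diagnostic costs and the short-term genetic-testing
#' disutility.  Totals are linear in counts by construction.
#'
#' @param diag an `ls_diag_outcomes` with the relative cascade filled
#'   (see [cascade_relatives()]).
#' @param mgmt per-profile mean outcomes from [simulate_cohort()] over the
#'   cell set returned by [management_profiles()] (same order).
#' @param params a validated [ls_parameters] object.
#' @return an object of class `ls_strategy_result`: discounted cost by
#'   category (diagnosis, CRC prevention, CRC treatment, EC prevention,
#'   EC treatment), total cost, short/long-term and total QALYs, life
#'   years and event counts for the whole annual cohort.
#' @export
combine_submodels <- function(diag, mgmt, params) {
  profs <- attr(mgmt, "profiles")
  if (is.null(profs)) stopf("mgmt must carry its profile list")
  key <- vapply(profs, profile_key, "")
  counts <- cell_counts(diag, params)
  missing <- setdiff(names(counts)[counts > 0], key)
  if (length(missing) > 0)
    stopf("missing management profile cell(s): %s",
          paste(missing, collapse = ", "))
  w <- counts[key]
  w[is.na(w)] <- 0

  wsum <- function(col) sum(w * mgmt[[col]])
  cost_cat <- c(
    diagnosis = diag$diagnostic_cost,
    crc_prevention = wsum("cost_crc_prevention"),
    crc_treatment = wsum("cost_crc_treatment"),
    ec_prevention = wsum("cost_ec_prevention"),
    ec_treatment = wsum("cost_ec_treatment")
  )
  ut <- params$utilities
  q_short <- -diag$n_genetic_tests_taken * ut$disutility_genetic_testing *
    ut$genetic_testing_disutility_years + wsum("qalys_short")
  q_long <- wsum("qalys_long")
  structure(list(
    strategy_id = diag$strategy_id,
    cost = as.list(cost_cat),
    total_cost = sum(cost_cat),
    qalys_short = q_short,
    qalys_long = q_long,
    total_qalys = q_short + q_long,
    life_years_undiscounted = wsum("ly_undisc"),
    life_years_discounted = wsum("ly_disc"),
    n_colonoscopies = wsum("n_colonoscopies"),
    n_crcs = wsum("n_crcs"),
    n_ecs = wsum("n_ecs"),
    cohort_n = sum(w)
  ), class = "ls_strategy_result")
}

#' @export
print.ls_strategy_result <- function(x, ...) {
  cat(sprintf("Strategy %s: total cost GBP %.1fk, total QALYs %.1f\n",
              strategy_label(x$strategy_id), x$total_cost / 1000, x$total_qalys))
  invisible(x)
}

# Canonical cell key for a management profile.
profile_key <- function(p) {
  paste(p$role, p$sex, if (p$true_ls) "LS" else "NONLS",
        if (p$accepted_surveillance) "surv" else "nosurv",
        if (p$accepted_hbso) "hbso" else "nohbso", sep = "|")
}

#' Enumerate the management profile cells
#'
#' The management submodel depends on classification only through the
#' accepted interventions, so simulation cells are enumerated over
#' (role, sex, true status, surveillance, H-BSO); one simulation of this
#' cell set serves all nine strategies.
#'
#' @param params a validated [ls_parameters] object.
#' @return list of [ls_profile()] objects.
#' @export
management_profiles <- function(params) {
  out <- list()
  for (role in c("proband", "relative")) {
    start <- if (role == "proband") params$population$proband_start_age
             else params$population$relative_age_distribution$age[1]
    for (sex in c("male", "female")) {
      for (ls in c(TRUE, FALSE)) {
        for (sv in c(TRUE, FALSE)) {
          hb_opts <- if (sex == "female") c(TRUE, FALSE) else FALSE
          for (hb in hb_opts) {
            out[[length(out) + 1]] <- ls_profile(
              role = role, sex = sex, true_ls = ls,
              classification = if (sv || hb) "LS_POSITIVE" else "LS_NEGATIVE",
              accepted_surveillance = sv, accepted_hbso = hb,
              start_age = start)
          }
        }
      }
    }
  }
  out
}

# Expected count per management cell implied by the diagnostic outcomes.
cell_counts <- function(diag, params) {
  pop <- params$population
  pf <- pop$proportion_female
  u_s <- pop$uptake_surveillance
  u_h <- pop$uptake_hbso
  counts <- numeric(0)
  bump <- function(key, n) counts[key] <<- (if (is.na(counts[key] %||% NA)) 0
                                            else counts[key]) + n
  for (role in c("proband", "relative")) {
    j <- if (role == "proband") diag$joint_probands else diag$joint_relatives
    if (is.null(j)) stopf("diagnostic outcomes missing %s joint", role)
    for (true in c("LS", "NONLS")) {
      for (cls in CLASSIFICATIONS) {
        n <- j[true, cls]
        if (n == 0) next
        diagnosed <- cls %in% c("LS_POSITIVE", "LS_ASSUMED")
        p_sv <- if (diagnosed) u_s else 0
        for (sex in c("male", "female")) {
          n_sex <- n * if (sex == "female") pf else 1 - pf
          p_hb <- if (diagnosed && sex == "female") u_h else 0
          for (sv in c(TRUE, FALSE)) {
            for (hb in if (sex == "female") c(TRUE, FALSE) else FALSE) {
              wgt <- n_sex * (if (sv) p_sv else 1 - p_sv) *
                (if (sex == "female") (if (hb) p_hb else 1 - p_hb) else 1)
              if (wgt == 0) next
              key <- paste(role, sex, true,
                           if (sv) "surv" else "nosurv",
                           if (hb) "hbso" else "nohbso", sep = "|")
              bump(key, wgt)
            }
          }
        }
      }
    }
  }
  counts
}

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost incremental cost (GBP).
#' @param delta_qalys incremental QALYs (must be nonzero).
#' @param rounded if `TRUE` (default) round half away from zero to the
#'   nearest pound (reporting convention); internal callers use
#'   `rounded = FALSE`.
#' @return GBP per QALY gained.
#' @examples
#' icer(984500, 179.3)   # 5491
#' @export
icer <- function(delta_cost, delta_qalys, rounded = TRUE) {
  if (any(delta_qalys == 0))
    stopf("ICER undefined for zero QALY difference (handle via dominance)")
  r <- delta_cost / delta_qalys
  if (rounded) round_half_away(r) else r
}

#' Incremental net health benefit
#'
#' `delta_qalys - delta_cost / wtp`, in QALYs, at willingness-to-pay `wtp`.
#'
#' @param delta_cost incremental cost (GBP).
#' @param delta_qalys incremental QALYs.
#' @param wtp willingness-to-pay (GBP/QALY, > 0).
#' @examples
#' inhb(984500, 179.3, 20000)  # 130.075
#' @export
inhb <- function(delta_cost, delta_qalys, wtp) {
  if (any(wtp <= 0)) stopf("wtp must be > 0")
  delta_qalys - delta_cost / wtp
}

#' Cost-effectiveness frontier with dominance and extended dominance
#'
#' Sorts strategies by total cost, removes strictly dominated strategies
#' (another strategy no more costly and no less effective, at least one
#' strict; equal QALYs at higher cost counts as dominated), then
#' iteratively removes extended-dominated strategies until the ICER ladder
#' along the frontier is strictly increasing.  Equal-cost equal-QALY ties
#' are both retained with a warning.
#'
#' @param results list of `ls_strategy_result` (or any list with
#'   `strategy_id`, `total_cost`, `total_qalys`).
#' @return object of class `ls_frontier`: data.frame `labels` with per
#'   strategy label `ON_FRONTIER`/`DOMINATED`/`EXTENDED_DOMINATED`, and
#'   data.frame `ladder` with the frontier ICERs versus the previous
#'   frontier point.
#' @export
find_frontier <- function(results) {
  stopifnot(length(results) >= 1)
  df <- data.frame(
    strategy_id = vapply(results, function(r) r$strategy_id, ""),
    cost = vapply(results, function(r) r$total_cost, 0),
    qalys = vapply(results, function(r) r$total_qalys, 0),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$cost, -df$qalys), ]
  n <- nrow(df)
  label <- setNames(rep("ON_FRONTIER", n), df$strategy_id)

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- df$cost[i]; qi <- df$qalys[i]
      cj <- df$cost[j]; qj <- df$qalys[j]
      if (cj <= ci && qj >= qi && (cj < ci || qj > qi)) {
        label[df$strategy_id[i]] <- "DOMINATED"
        break
      }
      if (cj == ci && qj == qi && i > j)
        warning("strategies ", df$strategy_id[j], " and ", df$strategy_id[i],
                " are exactly tied; both retained", call. = FALSE)
    }
  }

  repeat {
    cand <- df[label[df$strategy_id] == "ON_FRONTIER", ]
    if (nrow(cand) <= 2) break
    ic <- diff(cand$cost) / diff(cand$qalys)
    drop <- which(diff(ic) <= 0)           # ladder not strictly increasing
    if (length(drop) == 0) break
    label[cand$strategy_id[drop[1] + 1]] <- "EXTENDED_DOMINATED"
  }

  cand <- df[label[df$strategy_id] == "ON_FRONTIER", ]
  ladder <- data.frame(
    strategy_id = cand$strategy_id,
    icer_vs_previous = c(NA, if (nrow(cand) > 1)
      diff(cand$cost) / diff(cand$qalys) else numeric(0))
  )
  structure(list(
    labels = data.frame(strategy_id = df$strategy_id,
                        label = unname(label[df$strategy_id]),
                        stringsAsFactors = FALSE),
    ladder = ladder
  ), class = "ls_frontier")
}

#' @export
print.ls_frontier <- function(x, ...) {
  cat("Cost-effectiveness frontier:\n")
  print(x$labels, row.names = FALSE)
  cat("ICER ladder:\n")
  print(transform(x$ladder,
                  icer_vs_previous = round_half_away(icer_vs_previous)),
        row.names = FALSE)
  invisible(x)
}

#' Plot-ready cost-utility plane table
#'
#' Incremental cost and QALYs of every strategy versus the anchor
#' (least-cost) strategy, flagged with frontier labels.  Content is
#' invariant to the input order.
#'
#' @param results list of strategy results (as for [find_frontier()]).
#' @param anchor_id strategy used as origin (default: the cheapest).
#' @return data.frame (strategy, delta_cost, delta_qalys, label, icer
#'   versus anchor, INHB at the willingness-to-pay in `wtp`).
#' @param wtp willingness-to-pay for the INHB column.
#' @export
cost_utility_plane <- function(results, anchor_id = NULL, wtp = 20000) {
  fr <- find_frontier(results)
  df <- data.frame(
    strategy_id = vapply(results, function(r) r$strategy_id, ""),
    cost = vapply(results, function(r) r$total_cost, 0),
    qalys = vapply(results, function(r) r$total_qalys, 0),
    stringsAsFactors = FALSE
  )
  df <- df[order(match(df$strategy_id, fr$labels$strategy_id)), ]
  anchor_id <- anchor_id %||% df$strategy_id[which.min(df$cost)]
  a <- df[df$strategy_id == anchor_id, ]
  df$delta_cost <- df$cost - a$cost
  df$delta_qalys <- df$qalys - a$qalys
  df$label <- fr$labels$label[match(df$strategy_id, fr$labels$strategy_id)]
  df$icer_vs_anchor <- ifelse(df$delta_qalys == 0, NA,
                              df$delta_cost / df$delta_qalys)
  df$inhb <- inhb(df$delta_cost, df$delta_qalys, wtp)
  rownames(df) <- NULL
  df
}
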