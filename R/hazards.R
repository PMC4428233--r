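#' Piecewise-constant hazard function
#'
#' The model's age-specific event rates (cancer incidence, excess cancer
#' mortality, general mortality) are piecewise-constant on half-open age
#' intervals `[knot_i, knot_{i+1})`.  The hazard is zero outside the covered
#' range; generators therefore extend knots to the simulation horizon
#' explicitly rather than relying on implicit continuation.
#'
#' @param knots strictly increasing ages (years); length m.
#' @param rates per-year hazard on each interval; length m - 1, all >= 0.
#' @return an object of class `hazard_fn`.
#' @export
hazard_fn <- function(knots, rates) {
  knots <- as.numeric(knots); rates <- as.numeric(rates)
  if (length(knots) < 2) stopf("hazard_fn: need at least two knots")
  if (any(diff(knots) <= 0)) stopf("hazard_fn: knots must be strictly increasing")
  if (length(rates) != length(knots) - 1)
    stopf("hazard_fn: length(rates) must be length(knots) - 1")
  if (any(rates < 0) || any(!is.finite(rates)))
    stopf("hazard_fn: rates must be finite and >= 0")
  structure(list(knots = knots, rates = rates), class = "hazard_fn")
}

#' @export
print.hazard_fn <- function(x, ...) {
  cat("piecewise-constant hazard:", length(x$rates), "intervals on [",
      x$knots[1], ",", x$knots[length(x$knots)], ")\n")
  invisible(x)
}

#' Hazard rate at given ages
#' @param h a [hazard_fn()].
#' @param age ages (vectorised).
#' @return per-year rate; zero outside the knot range.
#' @export
hazard_rate <- function(h, age) {
  i <- findInterval(age, h$knots, left.open = FALSE)
  out <- numeric(length(age))
  ok <- i >= 1 & i <= length(h$rates)
  out[ok] <- h$rates[i[ok]]
  out
}

#' Cumulative hazard H(age) from the first knot
#'
#' @inheritParams hazard_rate
#' @return cumulative hazard, continuous and nondecreasing in age.
#' @export
cumulative_hazard <- function(h, age) {
  cumH <- c(0, cumsum(h$rates * diff(h$knots)))   # at each knot
  i <- findInterval(age, h$knots)
  out <- numeric(length(age))
  below <- i < 1
  above <- i > length(h$rates)
  mid <- !below & !above
  out[mid] <- cumH[i[mid]] + h$rates[i[mid]] * (age[mid] - h$knots[i[mid]])
  out[above] <- cumH[length(cumH)]
  out
}

#' Cumulative risk (incidence proportion) implied by a hazard
#'
#' `1 - exp(-H(age))` ignoring competing events.
#' @inheritParams hazard_rate
#' @export
cumulative_risk <- function(h, age) 1 - exp(-cumulative_hazard(h, age))

#' Scale a hazard by a constant factor
#' @param h a [hazard_fn()].
#' @param f nonnegative factor (e.g. a hazard ratio).
#' @export
scale_hazard <- function(h, f) hazard_fn(h$knots, h$rates * f)

#' Apply a multiplier to a hazard over an age window
#'
#' Used to apply surveillance hazard ratios while an individual is under
#' colonoscopic surveillance, leaving the hazard unchanged outside
#' `[from, to)`.
#' @param h a [hazard_fn()].
#' @param f multiplier (> 0).
#' @param from,to window bounds in years of age.
#' @export
window_multiply_hazard <- function(h, f, from, to) {
  if (to <= from) return(h)
  knots <- sort(unique(c(h$knots, max(min(h$knots), from), min(max(h$knots), to))))
  mids <- (knots[-1] + knots[-length(knots)]) / 2
  r <- hazard_rate(h, mids)
  w <- mids >= from & mids < to
  r[w] <- r[w] * f
  hazard_fn(knots, r)
}

#' Zero a hazard at and beyond an age
#'
#' Used to remove endometrial cancer risk after prophylactic H-BSO.
#' @param h a [hazard_fn()].
#' @param age cut age.
#' @export
truncate_hazard <- function(h, age) {
  window_multiply_hazard(h, 0, age, max(h$knots))
}

#' Invert a cumulative hazard: event time from a uniform draw
#'
#' Inversion sampling for the piecewise-exponential distribution: given a
#' uniform `u`, solves `H(t) - H(start) = -log(u)` for the event age `t`.
#' Returns `Inf` when the total remaining hazard is exhausted (the event
#' never happens).  Vectorised over `u` and `start`.
#'
#' @param h a [hazard_fn()].
#' @param u uniform(0,1) draws.
#' @param start age at which the clock starts (default: first knot).
#' @return event ages (possibly `Inf`).
#' @export
sample_event_age <- function(h, u, start = h$knots[1]) {
  n <- max(length(u), length(start))
  u <- rep_len(u, n); start <- rep_len(start, n)
  target <- cumulative_hazard(h, start) - log(u)
  cumH <- c(0, cumsum(h$rates * diff(h$knots)))
  # index of interval containing the target cumulative hazard
  i <- findInterval(target, cumH, left.open = TRUE)
  out <- rep(Inf, n)
  ok <- i <= length(h$rates) & target > 0
  # within flat (rate 0) stretches findInterval can land on a zero-rate
  # interval boundary only when target equals cumH exactly; guard rate > 0
  ok <- ok & h$rates[pmin(i, length(h$rates))] > 0
  ii <- i[ok]
  out[ok] <- h$knots[ii] + (target[ok] - cumH[ii]) / h$rates[ii]
  pmax(out, start)
}

#' Calibrate a piecewise-constant hazard to cumulative-risk targets
#'
#' Exact interval-wise inversion of `F(a) = 1 - exp(-H(a))`: between
#' consecutive target ages the hazard increment is distributed as a single
#' constant rate across the knot intervals it spans.  Every target age must
#' be a knot; risks must be nondecreasing and in `[0, 1)`.
#'
#' @param targets two-column object (age, cumulative_risk): a data.frame
#'   with columns `age` and `risk`, or a 2-column matrix.
#' @param knots ascending ages covering `[0, max(target age)]`; must
#'   contain every target age.
#' @return a [hazard_fn()] with `cumulative_risk(h, age_j) == risk_j` to
#'   within 1e-10 at every target.
#' @examples
#' h <- calibrate_piecewise_hazard(data.frame(age = 70, risk = 0.38), c(0, 70))
#' h$rates                      # -log(0.62)/70 ~ 0.006829
#' cumulative_risk(h, 70)       # 0.38
#' @export
calibrate_piecewise_hazard <- function(targets, knots) {
  if (is.matrix(targets)) targets <- data.frame(age = targets[, 1], risk = targets[, 2])
  stopifnot(all(c("age", "risk") %in% names(targets)))
  ord <- order(targets$age)
  targets <- targets[ord, , drop = FALSE]
  if (any(diff(targets$age) <= 0))
    stopf("calibration error: target ages must be strictly increasing")
  if (any(targets$risk < 0 | targets$risk >= 1))
    stopf("calibration error: risks must lie in [0, 1)")
  dr <- diff(c(0, targets$risk))
  if (any(dr < 0)) {
    j <- which(dr < 0)[1]
    stopf("calibration error: decreasing risk between ages %g and %g",
          c(0, targets$age)[j], targets$age[j])
  }
  knots <- sort(unique(as.numeric(knots)))
  if (knots[1] > 0) stopf("calibration error: knots must start at or below 0")
  if (max(knots) < max(targets$age))
    stopf("calibration error: knots must cover the largest target age")
  if (!all(targets$age %in% knots))
    stopf("calibration error: every target age must be a knot")
  Htarget <- -log(1 - targets$risk)
  bounds <- c(knots[1], targets$age)
  Hb <- c(0, Htarget)
  rates <- numeric(length(knots) - 1)
  for (j in seq_len(nrow(targets))) {
    lo <- bounds[j]; hi <- bounds[j + 1]
    rate <- (Hb[j + 1] - Hb[j]) / (hi - lo)
    sel <- which(knots >= lo & knots < hi)
    rates[sel] <- rate
  }
  # knot intervals beyond the last target keep the final calibrated rate of
  # zero; callers append continuation intervals explicitly if needed
  hazard_fn(knots, rates)
}

#' Proportional-hazards transform of a cumulative risk
#'
#' Maps a cumulative risk `F` through a hazard ratio `hr` under
#' proportional hazards: `1 - (1 - F)^hr`.
#'
#' @param F cumulative risk in `[0, 1)` (exactly 1 allowed only with hr = 1).
#' @param hr hazard ratio (> 0).
#' @examples
#' transform_cumulative_risk(0.38, 0.387)  # ~0.169
#' @export
transform_cumulative_risk <- function(F, hr) {
  if (any(hr <= 0)) stopf("transform_cumulative_risk: hr must be > 0")
  if (any(F < 0 | F > 1)) stopf("transform_cumulative_risk: F must be in [0, 1]")
  if (any(F == 1 & hr != 1)) stopf("transform_cumulative_risk: F = 1 only valid with hr = 1")
  1 - (1 - F)^hr
}
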