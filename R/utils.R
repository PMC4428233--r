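#' Round half away from zero
#'
#' Reporting-layer rounding used for ICERs (nearest pound) and QALY/INHB
#' summaries (one decimal).  Base `round()` rounds half to even, which does
#' not match conventional health-economic table formatting.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Discount factor
#'
#' Present-value factor for an amount accruing `t` years in the future at a
#' per-annum discount rate `r`: `(1 + r)^(-t)`.  Continuous (non-integer)
#' times are allowed.
#'
#' @param t time in years (>= 0), vectorised.
#' @param r per-annum discount rate (>= 0).
#' @return dimensionless discount factor(s).
#' @examples
#' discount_factor(0, 0.035)   # 1
#' discount_factor(1, 0.035)   # 1/1.035
#' @export
discount_factor <- function(t, r) {
  if (any(t < 0)) stop("discount_factor: t must be >= 0")
  if (r < 0) stop("discount_factor: r must be >= 0")
  (1 + r)^(-t)
}

# Integrals of t^k * exp(-delta * t) over [t0, t1], k = 0, 1, 2.
# Used for closed-form continuous discounting of utility streams where the
# utility is (at most) quadratic in age.  delta = log(1 + r); delta = 0 is
# handled exactly.  Vectorised over t0/t1.
disc_int_powers <- function(t0, t1, delta) {
  if (delta == 0) {
    list(i0 = t1 - t0,
         i1 = (t1^2 - t0^2) / 2,
         i2 = (t1^3 - t0^3) / 3)
  } else {
    e0 <- exp(-delta * t0)
    e1 <- exp(-delta * t1)
    a0 <- (e0 - e1) / delta
    # antiderivative of t e^{-dt}:  -(t/d + 1/d^2) e^{-dt}
    f1 <- function(t, e) -(t / delta + 1 / delta^2) * e
    # antiderivative of t^2 e^{-dt}: -(t^2/d + 2t/d^2 + 2/d^3) e^{-dt}
    f2 <- function(t, e) -(t^2 / delta + 2 * t / delta^2 + 2 / delta^3) * e
    list(i0 = a0,
         i1 = f1(t1, e1) - f1(t0, e0),
         i2 = f2(t1, e1) - f2(t0, e0))
  }
}

# Discounted integral of a quadratic-in-age utility over model time
# [t0, t1], where age = age0 + t and utility(age) = c0 + c1*age + c2*age^2.
disc_int_quadratic <- function(t0, t1, age0, coefs, delta) {
  p0 <- coefs[1] + coefs[2] * age0 + coefs[3] * age0^2
  p1 <- coefs[2] + 2 * coefs[3] * age0
  p2 <- coefs[3]
  ii <- disc_int_powers(t0, t1, delta)
  p0 * ii$i0 + p1 * ii$i1 + p2 * ii$i2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
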