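#' Time-dependent diffusion coefficient
#'
#' Closed-form D(t) of the generalized Drude-Lorentz model, per branch (with
#' A = kB*T/m* the thermal velocity scale):
#'
#' * overdamped: `A (tau/aI) [exp(-(1-aI) t/(2 tau)) - exp(-(1+aI) t/(2 tau))]`
#' * underdamped: `2 A (tau/aR) sin(aR t/(2 tau)) exp(-t/(2 tau))`
#' * critical: `A t exp(-t/(2 tau))`
#' * drude: `A tau (1 - exp(-t/tau))`, the overdamped form at aI = 1
#'
#' D(0) = 0 on every branch; the drude branch rises monotonically to the
#' stationary Drude-Einstein value kB*T*tau/m*, the others peak and decay
#' (the underdamped branch oscillating through negative lobes).
#'
#' @param t Time(s) in seconds, >= 0. Vectorized.
#' @param p A [transport_params()] object.
#' @return Diffusion coefficient(s) in m²/s.
#' @export
#' @examples
#' p <- params_from_preset("cnt_3_1", alpha = 0.1, regime = "overdamped")
#' diffusion(1e-13, p)
diffusion <- function(t, p) {
  check_times(t)
  A <- p$A; tau <- p$tau; a <- p$alpha
  switch(p$regime,
    drude = A * tau * (1 - exp(-t / tau)),
    critical = A * t * exp(-t / (2 * tau)),
    overdamped = A * (tau / a) *
      (exp(-(1 - a) * t / (2 * tau)) - exp(-(1 + a) * t / (2 * tau))),
    underdamped = 2 * A * (tau / a) *
      sin(a * t / (2 * tau)) * exp(-t / (2 * tau)))
}

#' Velocity autocorrelation function
#'
#' The closed-form time derivative of [diffusion()] — the velocity
#' autocorrelation <v(t).v(0)> whose running integral is D(t). At t = 0 it
#' equals the equipartition value kB*T/m* on every branch. On the overdamped
#' branch it crosses zero exactly where D(t) peaks.
#'
#' @inheritParams diffusion
#' @return ACF value(s) in m²/s².
#' @export
#' @examples
#' p <- params_from_preset("cnt_3_1", alpha = 0.1, regime = "overdamped")
#' velocity_acf(0, p)  # kB*T/m*
velocity_acf <- function(t, p) {
  check_times(t)
  A <- p$A; tau <- p$tau; a <- p$alpha
  x <- t / (2 * tau)
  switch(p$regime,
    drude = A * exp(-t / tau),
    critical = A * exp(-x) * (1 - x),
    overdamped = (A / (2 * a)) *
      ((1 + a) * exp(-(1 + a) * x) - (1 - a) * exp(-(1 - a) * x)),
    underdamped = A * exp(-x) * (cos(a * x) - sin(a * x) / a))
}

#' Mean-squared displacement
#'
#' Closed-form R²(t) = 2 * integral of D from 0 to t. All branches start
#' ballistically, R²(t) ~ (kB*T/m*) t² for t << tau. With a restoring force
#' (omega0 > 0) the carrier is confined and R² saturates at the oscillator
#' equipartition plateau 2 kB*T/(m* omega0²) — monotonically on the
#' overdamped and critical branches, with decaying oscillatory overshoot on
#' the underdamped branch; the free (drude) carrier crosses over to
#' ordinary diffusion, R² ~ 2 (kB*T*tau/m*) t.
#'
#' @inheritParams diffusion
#' @return MSD value(s) in m².
#' @export
#' @examples
#' p <- params_from_preset("cnt_3_1", alpha = 0.1, regime = "overdamped")
#' msd(200 * p$tau, p)  # ~ 2 kB T / (m* omega0^2)
msd <- function(t, p) {
  check_times(t)
  A <- p$A; tau <- p$tau; a <- p$alpha
  switch(p$regime,
    drude = 2 * A * tau * (t - tau * (1 - exp(-t / tau))),
    critical = {
      x <- t / (2 * tau)
      8 * A * tau^2 * (1 - exp(-x) * (1 + x))
    },
    overdamped = {
      em <- -expm1(-(1 - a) * t / (2 * tau))  # 1 - exp(...)
      ep <- -expm1(-(1 + a) * t / (2 * tau))
      (4 * A * tau^2 / a) * (em / (1 - a) - ep / (1 + a))
    },
    underdamped = {
      b <- a / (2 * tau); cc <- 1 / (2 * tau)
      w02 <- b^2 + cc^2  # = omega0^2
      (4 * A * tau / a) *
        (b - exp(-cc * t) * (b * cos(b * t) + cc * sin(b * t))) / w02
    })
}

#' Peak of the diffusion coefficient
#'
#' Location and height of the first (global) interior maximum of D(t):
#'
#' * overdamped: `t* = (tau/aI) log((1+aI)/(1-aI))`
#' * underdamped: `t* = (2 tau/aR) atan(aR)` (later oscillation extrema are
#'   visible in [make_curve()], not reported here)
#' * critical: `t* = 2 tau`
#' * drude: no interior maximum; `t_star = Inf` with the asymptote
#'   `D_max = kB*T*tau/m*`
#'
#' At an interior maximum the velocity autocorrelation is exactly zero.
#'
#' @param p A [transport_params()] object.
#' @return List with `t_star` (s), `D_max` (m²/s) and `D_max_cm2_s`.
#' @export
#' @examples
#' p <- params_from_preset("cnt_3_1", alpha = 0.1, regime = "overdamped")
#' peak_diffusion(p)$D_max_cm2_s  # ~6.8 cm²/s
peak_diffusion <- function(p) {
  tau <- p$tau; a <- p$alpha
  t_star <- switch(p$regime,
    drude = Inf,
    critical = 2 * tau,
    overdamped = (tau / a) * log((1 + a) / (1 - a)),
    underdamped = (2 * tau / a) * atan(a))
  D_max <- if (is.infinite(t_star)) p$A * tau else diffusion(t_star, p)
  list(t_star = t_star, D_max = D_max, D_max_cm2_s = convert_diffusion(D_max))
}

#' Sample a transport curve on a uniform time grid
#'
#' Evaluates the ACF, D(t) (in both m²/s and cm²/s) and R²(t) on n uniform
#' points from 0 to `t_max`.
#'
#' @param p A [transport_params()] object.
#' @param t_max End of the time grid in seconds, > 0.
#' @param n Number of grid points, >= 2.
#' @return A `transport_curve` data frame with columns `t_s`, `acf_m2_s2`,
#'   `D_m2_s`, `D_cm2_s`, `msd_m2`, carrying the parameters as attribute
#'   `params`.
#' @export
#' @examples
#' p <- params_from_preset("cnt_3_1", alpha = 0.1, regime = "overdamped")
#' curve <- make_curve(p, 2e-12, 500)
#' max(curve$D_cm2_s)
make_curve <- function(p, t_max, n) {
  stopifnot(is.numeric(t_max), length(t_max) == 1L, is.finite(t_max))
  if (t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2 ||
      n != round(n)) {
    stop("n must be an integer >= 2", call. = FALSE)
  }
  t <- seq(0, t_max, length.out = n)
  D <- diffusion(t, p)
  out <- data.frame(
    t_s = t,
    acf_m2_s2 = velocity_acf(t, p),
    D_m2_s = D,
    D_cm2_s = convert_diffusion(D),
    msd_m2 = msd(t, p))
  attr(out, "params") <- p
  class(out) <- c("transport_curve", "data.frame")
  out
}

check_times <- function(t) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  invisible(t)
}
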