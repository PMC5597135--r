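#' Classify the damping regime of a carrier
#'
#' The model's two analytic branches are selected by the dimensionless
#' discriminant 4 tau^2 omega0^2: below 1 the carrier is overdamped (branch
#' parameter alpha_I = sqrt(1 - 4 tau^2 omega0^2)), above 1 it is underdamped
#' (alpha_R = sqrt(4 tau^2 omega0^2 - 1)). The boundary 4 tau^2 omega0^2 = 1
#' is the critically damped case, and omega0 = 0 (alpha_I = 1) is the free
#' carrier (Drude) limit with no restoring force.
#'
#' @param tau Relaxation time in seconds, > 0.
#' @param omega0 Center frequency in rad/s, >= 0.
#' @param tol Tolerance on |4 tau^2 omega0^2 - 1| for the critical tag.
#'   Must lie in (0, 1e-3); keeping a finite band avoids catastrophic
#'   cancellation of the two overdamped exponentials as alpha_I -> 0.
#' @return One of `"overdamped"`, `"underdamped"`, `"critical"`, `"drude"`.
#' @export
#' @examples
#' classify_regime(1e-13, 3e12)   # overdamped, alpha_I = 0.8
#' classify_regime(1e-13, 5e12)   # critical
#' classify_regime(1e-13, 0)      # drude
classify_regime <- function(tau, omega0, tol = 1e-6) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  stopifnot(is.numeric(omega0), length(omega0) == 1L, is.finite(omega0))
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (omega0 < 0) stop("omega0 must be >= 0", call. = FALSE)
  stopifnot(is.numeric(tol), tol > 0, tol < 1e-3)
  if (omega0 == 0) return("drude")
  disc <- 4 * tau^2 * omega0^2
  if (abs(disc - 1) <= tol) return("critical")
  if (disc < 1) "overdamped" else "underdamped"
}

#' Center frequency from a branch parameter
#'
#' Inverts the branch definitions: for the overdamped branch
#' omega0 = sqrt(1 - alpha^2) / (2 tau), for the underdamped branch
#' omega0 = sqrt(1 + alpha^2) / (2 tau). The worked carbon-nanotube example
#' fixes alpha_I rather than omega0, so this inverse is the usual entry
#' point.
#'
#' @param tau Relaxation time in seconds, > 0.
#' @param alpha Dimensionless branch parameter: alpha_I in \[0, 1\]
#'   (overdamped) or alpha_R >= 0 (underdamped).
#' @param regime `"overdamped"` or `"underdamped"` (`"drude"` is accepted as
#'   an alias for overdamped alpha = 1; `"critical"` for alpha = 0).
#' @return Center frequency omega0 in rad/s.
#' @export
#' @examples
#' omega_from_alpha(1e-13, 0.1, "overdamped")  # ~4.9749e12 rad/s
#' omega_from_alpha(1e-13, 1, "overdamped")    # 0 (Drude limit)
omega_from_alpha <- function(tau, alpha, regime = c("overdamped", "underdamped",
                                                    "critical", "drude")) {
  regime <- match.arg(regime)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (regime == "drude") {
    if (alpha != 1) stop("drude regime requires alpha_I = 1", call. = FALSE)
    return(0)
  }
  if (regime == "critical") {
    if (alpha != 0) stop("critical regime requires alpha = 0", call. = FALSE)
    return(1 / (2 * tau))
  }
  if (regime == "overdamped") {
    if (alpha < 0 || alpha > 1)
      stop("overdamped branch requires 0 <= alpha_I <= 1", call. = FALSE)
    sqrt(1 - alpha^2) / (2 * tau)
  } else {
    if (alpha < 0)
      stop("underdamped branch requires alpha_R >= 0", call. = FALSE)
    sqrt(1 + alpha^2) / (2 * tau)
  }
}

alpha_from_omega <- function(tau, omega0, regime) {
  disc <- 4 * tau^2 * omega0^2
  switch(regime,
         drude = 1,
         critical = 0,
         overdamped = sqrt(max(1 - disc, 0)),
         underdamped = sqrt(max(disc - 1, 0)))
}

#' Physical parameters of one carrier system
#'
#' Bundles the effective mass, relaxation time, temperature and restoring
#' frequency of a carrier, resolving the analytic branch once at
#' construction. Exactly one of `omega0` or (`alpha`, `regime`) must be
#' supplied; the other is derived through 4 tau^2 omega0^2 = 1 - alpha_I^2
#' (overdamped) or 1 + alpha_R^2 (underdamped) and both are stored.
#'
#' The thermal velocity scale kB*T/m* (one translational degree of freedom)
#' normalizes the velocity autocorrelation at t = 0; it is precomputed and
#' stored as `A`.
#'
#' @param m_eff_ratio Effective mass as a multiple of the electron mass, > 0.
#' @param tau Relaxation time in seconds, > 0.
#' @param temperature Temperature in kelvin, > 0.
#' @param omega0 Center frequency in rad/s (>= 0), or `NULL` if `alpha` given.
#' @param alpha Branch parameter alpha_I or alpha_R, or `NULL` if `omega0`
#'   given.
#' @param regime Branch for `alpha`; required with `alpha`, ignored with
#'   `omega0`.
#' @param constants Constants list from [transport_constants()].
#' @param tol Critical-band tolerance passed to [classify_regime()].
#' @return A `transport_params` object.
#' @export
#' @examples
#' p <- transport_params(0.507, 1e-13, 310, alpha = 0.1, regime = "overdamped")
#' p$omega0
transport_params <- function(m_eff_ratio, tau, temperature = 310,
                             omega0 = NULL, alpha = NULL, regime = NULL,
                             constants = transport_constants(),
                             tol = 1e-6) {
  stopifnot(is.numeric(m_eff_ratio), length(m_eff_ratio) == 1L,
            is.finite(m_eff_ratio))
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature))
  if (m_eff_ratio <= 0) stop("m_eff_ratio must be > 0", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)

  if (is.null(omega0) == is.null(alpha)) {
    stop("supply exactly one of omega0 or (alpha, regime)", call. = FALSE)
  }
  if (is.null(omega0)) {
    if (is.null(regime)) stop("alpha requires a regime", call. = FALSE)
    omega0 <- omega_from_alpha(tau, alpha, regime)
    regime <- classify_regime(tau, omega0, tol)
  } else {
    regime <- classify_regime(tau, omega0, tol)
  }
  alpha <- alpha_from_omega(tau, omega0, regime)

  m_eff <- m_eff_ratio * constants$me
  structure(list(
    m_eff_ratio = m_eff_ratio,
    m_eff = m_eff,
    tau = tau,
    temperature = temperature,
    omega0 = omega0,
    alpha = alpha,
    regime = regime,
    A = constants$kB * temperature / m_eff,  # kB*T/m*, m^2/s^2
    constants = constants
  ), class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat("<transport_params>\n")
  cat(sprintf("  m* = %g m_e (%.4g kg), tau = %g s, T = %g K\n",
              x$m_eff_ratio, x$m_eff, x$tau, x$temperature))
  cat(sprintf("  regime = %s, alpha = %.6g, omega0 = %.6g rad/s\n",
              x$regime, x$alpha, x$omega0))
  cat(sprintf("  kB*T/m* = %.6g m^2/s^2\n", x$A))
  invisible(x)
}

#' Build transport parameters from a carrier preset
#'
#' @param preset A `carrier_preset` or a preset name.
#' @param alpha,regime,omega0 Branch specification as in
#'   [transport_params()].
#' @param tau,temperature Optional overrides of the preset defaults.
#' @param ... Passed to [transport_params()].
#' @return A `transport_params` object.
#' @export
#' @examples
#' params_from_preset("cnt_7_3", alpha = 0.5, regime = "overdamped")
params_from_preset <- function(preset, alpha = NULL, regime = NULL,
                               omega0 = NULL, tau = NULL,
                               temperature = NULL, ...) {
  if (is.character(preset)) preset <- get_preset(preset)
  transport_params(
    m_eff_ratio = preset$m_eff_ratio,
    tau = if (is.null(tau)) preset$default_tau_s else tau,
    temperature = if (is.null(temperature)) preset$default_temperature_K
                  else temperature,
    omega0 = omega0, alpha = alpha, regime = regime, ...)
}
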