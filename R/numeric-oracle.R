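#' Diffusion coefficient by direct quadrature of the ACF
#'
#' Independent check of the closed-form [diffusion()]: integrates the
#' velocity autocorrelation over \[0, t\] with adaptive quadrature
#' (`stats::integrate`). For strongly oscillatory underdamped integrands
#' (alpha_R > 10) the interval is split at the sine zeros so each panel is
#' smooth.
#'
#' @param t Time in seconds, scalar >= 0.
#' @param p A [transport_params()] object.
#' @param rel_tol Requested relative tolerance of the quadrature.
#' @return D(t) in m²/s.
#' @export
#' @examples
#' p <- params_from_preset("cnt_3_1", alpha = 0.5, regime = "overdamped")
#' diffusion_quad(2e-13, p)
diffusion_quad <- function(t, p, rel_tol = 1e-12) {
  stopifnot(length(t) == 1L)
  check_times(t)
  if (t == 0) return(0)
  quad_panels(function(s) velocity_acf(s, p), 0, t, p, rel_tol)
}

#' Mean-squared displacement by direct quadrature
#'
#' Literal transcription of the defining integral
#' R²(t) = 2 * integral over \[0, t\] of (t - t') <v(t').v(0)> dt',
#' keeping the (t - t') weight rather than integrating D(t). This makes it
#' an independent check of the exchange-of-integration-order identity that
#' the closed-form [msd()] relies on.
#'
#' @inheritParams diffusion_quad
#' @return R²(t) in m².
#' @export
msd_quad <- function(t, p, rel_tol = 1e-12) {
  stopifnot(length(t) == 1L)
  check_times(t)
  if (t == 0) return(0)
  2 * quad_panels(function(s) (t - s) * velocity_acf(s, p), 0, t, p, rel_tol)
}

#' Diffusion coefficient as half the MSD slope
#'
#' Centered finite difference of the defining relation D = (1/2) dR²/dt:
#' `(msd(t + h) - msd(t - h)) / (4 h)`, accurate to O(h²).
#'
#' @param t Time in seconds, scalar, with t > h.
#' @param p A [transport_params()] object.
#' @param h Finite-difference step in seconds, 0 < h < t.
#' @return D(t) estimate in m²/s.
#' @export
d_from_msd <- function(t, p, h = p$tau / 1000) {
  stopifnot(length(t) == 1L, length(h) == 1L, is.numeric(h), is.finite(h))
  check_times(t)
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  if (h >= t) stop("h must be < t", call. = FALSE)
  (msd(t + h, p) - msd(t - h, p)) / (4 * h)
}

#' Closed form vs quadrature comparison table
#'
#' @param p A [transport_params()] object.
#' @param t Times in seconds (vector).
#' @param quantity `"diffusion"` or `"msd"`.
#' @return Data frame with `t`, `closed_form`, `quadrature`, `rel_err`. The
#'   relative error uses an absolute floor of `(kB*T/m*) * tau * 1e-5` — the
#'   natural diffusion scale of the problem, scaled down to just above the
#'   double-precision rounding floor of the quadrature. Adaptive quadrature
#'   of the oscillatory ACF cannot beat an absolute error of about
#'   eps * integral of |ACF| (roughly 1e-15 of kB*T*tau/m* at small
#'   alpha_R), so any smaller floor would turn pure rounding noise at
#'   exponentially suppressed tail values of D(t) into spurious relative
#'   error.
#' @export
oracle_report <- function(p, t, quantity = c("diffusion", "msd")) {
  quantity <- match.arg(quantity)
  closed <- switch(quantity, diffusion = diffusion(t, p), msd = msd(t, p))
  quad <- vapply(t, function(ti) {
    switch(quantity, diffusion = diffusion_quad(ti, p), msd = msd_quad(ti, p))
  }, numeric(1))
  floor_scale <- p$A * p$tau * 1e-5
  data.frame(t = t, closed_form = closed, quadrature = quad,
             rel_err = abs(closed - quad) / pmax(abs(quad), floor_scale))
}

# Adaptive quadrature with panel splitting for oscillatory integrands.
quad_panels <- function(f, lower, upper, p, rel_tol) {
  cuts <- c(lower, upper)
  if (p$regime == "underdamped" && p$alpha > 10) {
    period <- 2 * pi * 2 * p$tau / p$alpha  # period of sin(alpha t / 2 tau)
    zeros <- seq(lower, upper, by = period / 2)
    cuts <- sort(unique(c(zeros, upper)))
  }
  total <- 0
  achieved <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    q <- stats::integrate(f, cuts[i], cuts[i + 1L], rel.tol = rel_tol,
                          abs.tol = p$A * p$tau * rel_tol,
                          subdivisions = 1000L, stop.on.error = FALSE)
    if (!q$message %in% c("OK", "roundoff error was detected")) {
      stop(sprintf("quadrature failed on [%g, %g]: %s (abs.error %g)",
                   cuts[i], cuts[i + 1L], q$message, q$abs.error),
           call. = FALSE)
    }
    total <- total + q$value
    achieved <- achieved + q$abs.error
  }
  total
}
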