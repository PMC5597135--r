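# Shared fixtures: the carbon-nanotube worked example and random draws.

case_a <- function(alpha = 0.1) {
  params_from_preset("cnt_3_1", alpha = alpha, regime = "overdamped",
                     tol = 1e-12)
}

case_b <- function(alpha = 0.1) {
  params_from_preset("cnt_7_3", alpha = alpha, regime = "overdamped",
                     tol = 1e-12)
}

drude_params <- function(m_eff_ratio = 0.507) {
  transport_params(m_eff_ratio, 1e-13, 310, omega0 = 0)
}

critical_params <- function(tau = 1e-13, m_eff_ratio = 0.507) {
  transport_params(m_eff_ratio, tau, 310, omega0 = 1 / (2 * tau))
}

# n random parameter sets per branch; tau log-uniform in [1e-14, 1e-12],
# alpha in [0.05, 0.95] (underdamped draws also stretched up to ~2).
random_params <- function(n, seed) {
  set.seed(seed)
  draws <- list()
  for (i in seq_len(n)) {
    tau <- 10^stats::runif(1, -14, -12)
    meff <- stats::runif(1, 0.05, 1.5)
    branch <- if (i %% 2 == 0) "overdamped" else "underdamped"
    alpha <- stats::runif(1, 0.05, 0.95)
    if (branch == "underdamped" && i %% 4 == 1) alpha <- alpha * 2
    draws[[i]] <- transport_params(meff, tau, 310, alpha = alpha,
                                   regime = branch, tol = 1e-12)
  }
  draws
}
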