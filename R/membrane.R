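#' Toy membrane specification
#'
#' A membrane patch with `n_channels` identical ion channels, each gated by
#' `gates_per_channel` independent gates, of which exactly `n_open_gates`
#' are open. Following the Hodgkin-Huxley n^4 convention for potassium
#' channels, a channel conducts only when all of its gates are open. The
#' canonical example is 3 channels x 4 gates with 9 open gates.
#'
#' @param n_channels Number of channels, >= 1.
#' @param gates_per_channel Gates per channel, >= 1.
#' @param n_open_gates Number of open gates, between 0 and the total gate
#'   count.
#' @return A `membrane_spec` object.
#' @export
#' @examples
#' membrane_spec(3, 4, 9)
membrane_spec <- function(n_channels, gates_per_channel, n_open_gates) {
  for (v in list(n_channels, gates_per_channel, n_open_gates)) {
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v), v == round(v))
  }
  if (n_channels < 1 || gates_per_channel < 1)
    stop("need at least one channel and one gate per channel", call. = FALSE)
  total <- n_channels * gates_per_channel
  if (n_open_gates < 0 || n_open_gates > total)
    stop("n_open_gates must be between 0 and the total gate count",
         call. = FALSE)
  structure(list(n_channels = as.integer(n_channels),
                 gates_per_channel = as.integer(gates_per_channel),
                 n_open_gates = as.integer(n_open_gates),
                 total_gates = as.integer(total)),
            class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf("<membrane_spec> %d channels x %d gates, %d open gates\n",
              x$n_channels, x$gates_per_channel, x$n_open_gates))
  invisible(x)
}

max_enumeration_gates <- 24L

#' Enumerate all gate configurations
#'
#' Exhaustively lists every assignment of open/closed states to the gates
#' with exactly `n_open_gates` gates open — choose(total_gates,
#' n_open_gates) configurations. Enumeration is capped at 24 gates; beyond
#' that use [open_channel_distribution()] directly.
#'
#' @param spec A [membrane_spec()].
#' @return Logical matrix, one row per configuration, one column per gate
#'   (gate columns grouped by channel: columns 1..g are channel 1, etc.),
#'   with attribute `open_channels` giving the number of fully open channels
#'   per configuration.
#' @export
#' @examples
#' cfgs <- enumerate_configs(membrane_spec(3, 4, 9))
#' nrow(cfgs)  # choose(12, 9) = 220
enumerate_configs <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  if (spec$total_gates > max_enumeration_gates) {
    stop(sprintf(paste0("exhaustive enumeration capped at %d gates ",
                        "(got %d); use open_channel_distribution()"),
                 max_enumeration_gates, spec$total_gates), call. = FALSE)
  }
  n <- spec$total_gates
  k <- spec$n_open_gates
  configs <- matrix(FALSE, nrow = choose(n, k), ncol = n)
  if (k == 0) {
    # single all-closed configuration
  } else {
    idx <- utils::combn(n, k)
    for (j in seq_len(ncol(idx))) configs[j, idx[, j]] <- TRUE
  }
  colnames(configs) <- paste0("ch", rep(seq_len(spec$n_channels),
                                        each = spec$gates_per_channel),
                              "_g", rep(seq_len(spec$gates_per_channel),
                                        spec$n_channels))
  attr(configs, "open_channels") <- count_open_channels(configs, spec)
  attr(configs, "spec") <- spec
  configs
}

count_open_channels <- function(configs, spec) {
  g <- spec$gates_per_channel
  open <- integer(nrow(configs))
  for (ch in seq_len(spec$n_channels)) {
    cols <- ((ch - 1L) * g + 1L):(ch * g)
    open <- open + as.integer(rowSums(configs[, cols, drop = FALSE]) == g)
  }
  open
}

#' Distribution of the number of open channels
#'
#' Probability mass function of the number of fully open channels under the
#' uniform measure over all gate configurations with exactly `n_open_gates`
#' open gates.
#'
#' @param spec A [membrane_spec()].
#' @return Named numeric vector over 0..n_channels summing to 1, with
#'   attribute `counts` (integer configuration counts) and `n_configs`.
#' @export
#' @examples
#' open_channel_distribution(membrane_spec(3, 4, 9))
#' # 64/220, 144/220, 12/220, 0
open_channel_distribution <- function(spec) {
  configs <- enumerate_configs(spec)
  open <- attr(configs, "open_channels")
  counts <- tabulate(open + 1L, nbins = spec$n_channels + 1L)
  pmf <- counts / sum(counts)
  names(pmf) <- as.character(0:spec$n_channels)
  attr(pmf, "counts") <- counts
  attr(pmf, "n_configs") <- nrow(configs)
  pmf
}

#' Probability of one gate configuration
#'
#' Joint probability of a configuration under independent Bernoulli gates:
#' the product over gates of `p_gate` (open) or `1 - p_gate` (closed).
#' These products sum to 1 over the full unconstrained configuration space.
#'
#' @param q Logical (or 0/1) vector of gate states, open = TRUE.
#' @param p_gate Per-gate open probability in (0, 1); scalar or one value
#'   per gate.
#' @return The configuration probability.
#' @export
#' @examples
#' config_probability(rep(TRUE, 12), 0.5)  # 0.5^12
config_probability <- function(q, p_gate) {
  q <- as.logical(q)
  stopifnot(!anyNA(q))
  stopifnot(is.numeric(p_gate), all(is.finite(p_gate)))
  if (any(p_gate <= 0) || any(p_gate >= 1))
    stop("p_gate must lie strictly inside (0, 1)", call. = FALSE)
  if (length(p_gate) == 1L) p_gate <- rep(p_gate, length(q))
  stopifnot(length(p_gate) == length(q))
  prod(ifelse(q, p_gate, 1 - p_gate))
}

#' Probability flux of a state coordinate
#'
#' The flux invariant ties the flux of states along coordinate j to the
#' gradient of the configuration probability: Phi_j + lambda * dP/dq_j = 0,
#' so Phi_j = -lambda * dP/dq_j. The derivative is taken over a continuous
#' relaxation of the state (per-gate probabilities), by centered finite
#' difference. A constant probability field therefore carries zero flux.
#'
#' @param P Scalar function of the continuous state vector q.
#' @param q Numeric state vector at which to evaluate.
#' @param j Coordinate index.
#' @param lam Coupling constant lambda (dimensionless; the model leaves its
#'   value to the user).
#' @param h Finite-difference step.
#' @return The flux Phi_j = -lambda * dP/dq_j.
#' @export
#' @examples
#' probability_flux(function(q) sum(q), c(0.2, 0.7), j = 1, lam = 1)  # -1
probability_flux <- function(P, q, j, lam, h = 1e-6) {
  stopifnot(is.function(P), is.numeric(q), j >= 1, j <= length(q),
            is.numeric(lam), length(lam) == 1L, is.finite(lam),
            h > 0)
  qp <- q; qp[j] <- qp[j] + h
  qm <- q; qm[j] <- qm[j] - h
  Pp <- P(qp); Pm <- P(qm)
  if (!is.finite(Pp) || !is.finite(Pm))
    stop("P evaluated to a non-finite value near q", call. = FALSE)
  -lam * (Pp - Pm) / (2 * h)
}

#' Kullback-Leibler divergence of two discrete distributions
#'
#' KL(P || Q) = sum P log(P/Q), in nats. Zero-probability entries of P
#' contribute nothing; Q must be positive wherever P is.
#'
#' @param p,q Numeric probability vectors on the same support (same length,
#'   matching names if named), each summing to 1.
#' @return Divergence in nats (>= 0; 0 iff P = Q).
#' @export
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.75, 0.25))  # ~0.1438 nats
kl_divergence <- function(p, q) {
  stopifnot(is.numeric(p), is.numeric(q))
  if (length(p) != length(q))
    stop("p and q must share the same support", call. = FALSE)
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q)))
    stop("p and q must share the same support", call. = FALSE)
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("p and q must be probability vectors", call. = FALSE)
  pos <- p > 0
  if (any(q[pos] == 0))
    stop("q must be positive wherever p is positive", call. = FALSE)
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Fisher information matrix of a parametrized discrete family
#'
#' For a family P(x; q) over a fixed finite support, estimates
#' G_ij(q) = sum_x P(x; q) d(log P)/dq_i d(log P)/dq_j with centered finite
#' differences of log P. G is the Riemannian metric of information
#' geometry: for a small parameter step delta,
#' KL(P(q) || P(q + delta)) ~ delta' G delta / 2.
#'
#' @param family Function mapping a parameter vector q to a positive pmf
#'   vector over the support.
#' @param q Parameter vector; probability-type parameters must sit at least
#'   `h` away from 0 and 1.
#' @param h Finite-difference step.
#' @return Symmetric positive semi-definite matrix, dim length(q).
#' @export
#' @examples
#' bern <- function(q) c(1 - q[1], q[1])
#' fisher_information(bern, 0.5)  # 1 / (0.5 * 0.5) = 4
fisher_information <- function(family, q, h = 1e-5) {
  stopifnot(is.function(family), is.numeric(q), h > 0)
  if (any(q > 0 & q < 1 & (q < h | q > 1 - h)))
    stop("parameter within h of the 0/1 boundary", call. = FALSE)
  P0 <- family(q)
  if (any(P0 <= 0)) stop("pmf must be positive on its support", call. = FALSE)
  n <- length(q)
  # centered difference of log P per coordinate, each a vector over support
  dlog <- matrix(0, nrow = length(P0), ncol = n)
  for (i in seq_len(n)) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    dlog[, i] <- (log(family(qp)) - log(family(qm))) / (2 * h)
  }
  G <- crossprod(dlog, P0 * dlog)
  (G + t(G)) / 2
}
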