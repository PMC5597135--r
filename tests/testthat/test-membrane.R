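test_that("enumeration yields choose(n, k) constrained configurations", {
  cfgs <- enumerate_configs(membrane_spec(3, 4, 9))
  expect_identical(nrow(cfgs), as.integer(choose(12, 9)))
  expect_true(all(rowSums(cfgs) == 9))
  expect_identical(anyDuplicated(apply(cfgs, 1, paste, collapse = "")), 0L)
  # boundary cases
  one <- enumerate_configs(membrane_spec(1, 4, 4))
  expect_identical(nrow(one), 1L)
  expect_identical(attr(one, "open_channels"), 1L)
  none <- enumerate_configs(membrane_spec(3, 4, 0))
  expect_identical(nrow(none), 1L)
  expect_identical(attr(none, "open_channels"), 0L)
  # totals match binomial coefficients across a sweep of small specs
  for (k in c(1, 3, 6, 8)) {
    expect_identical(nrow(enumerate_configs(membrane_spec(2, 4, k))),
                     as.integer(choose(8, k)))
  }
  expect_error(enumerate_configs(membrane_spec(5, 5, 10)), "capped")
  expect_error(membrane_spec(3, 4, 13), "between 0")
})

test_that("open-channel pmf partitions the 9-of-12 ensemble as 64/144/12", {
  pmf <- open_channel_distribution(membrane_spec(3, 4, 9))
  expect_identical(attr(pmf, "counts"), c(64L, 144L, 12L, 0L))
  expect_identical(as.numeric(pmf), c(64, 144, 12, 0) / 220)
  expect_identical(sum(pmf), 1)
  # pmf equals the empirical distribution from the raw enumeration
  open <- attr(enumerate_configs(membrane_spec(3, 4, 9)), "open_channels")
  expect_identical(attr(pmf, "counts"), tabulate(open + 1L, 4L))
  # all gates open: the single all-open configuration
  expect_identical(as.numeric(open_channel_distribution(
    membrane_spec(3, 4, 12))), c(0, 0, 0, 1))
  # fewer open gates than one channel needs: no channel can conduct
  expect_identical(as.numeric(open_channel_distribution(
    membrane_spec(3, 4, 3))), c(1, 0, 0, 0))
})

test_that("configuration probabilities are Bernoulli products that normalize", {
  expect_identical(config_probability(rep(TRUE, 12), 0.5), 0.5^12)
  q <- c(rep(TRUE, 9), rep(FALSE, 3))
  expect_equal(config_probability(q, 0.75), 0.75^9 * 0.25^3,
               tolerance = 1e-15)
  # per-gate probabilities
  pv <- seq(0.1, 0.9, length.out = 4)
  expect_equal(config_probability(c(TRUE, FALSE, TRUE, FALSE), pv),
               pv[1] * (1 - pv[2]) * pv[3] * (1 - pv[4]), tolerance = 1e-15)
  # normalization over the full unconstrained space (8 gates)
  p <- 0.3
  states <- expand.grid(rep(list(c(FALSE, TRUE)), 8))
  total <- sum(apply(states, 1, config_probability, p_gate = p))
  expect_equal(total, 1, tolerance = 1e-12)
  expect_error(config_probability(q, 0), "p_gate")
  expect_error(config_probability(q, 1.2), "p_gate")
})

test_that("probability flux obeys the invariant and vanishes for constant P", {
  q <- c(0.3, 0.6, 0.8)
  for (j in 1:3) {
    expect_identical(probability_flux(function(q) 0.42, q, j, lam = 3), 0)
  }
  # linear field: exact derivative
  expect_equal(probability_flux(function(q) 2 * q[1] - q[2], q, 1, lam = 1),
               -2, tolerance = 1e-9)
  expect_equal(probability_flux(function(q) 2 * q[1] - q[2], q, 2, lam = 1),
               1, tolerance = 1e-9)
  # Bernoulli-product likelihood of an observed all-open configuration:
  # P(q) = prod q_i, dP/dq_j = prod_{i != j} q_i; lambda = 2
  P <- function(q) prod(q)
  for (j in 1:3) {
    expect_equal(probability_flux(P, q, j, lam = 2), -2 * prod(q[-j]),
                 tolerance = 1e-8)
  }
  # the invariant Phi_j + lambda dP/dq_j = 0 holds by construction
  h <- 1e-6
  num_grad <- (P(q + h * c(1, 0, 0)) - P(q - h * c(1, 0, 0))) / (2 * h)
  expect_equal(probability_flux(P, q, 1, lam = 5, h = h) + 5 * num_grad, 0)
})

test_that("KL divergence is a proper divergence", {
  p <- c(0.5, 0.5)
  expect_identical(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, c(0.75, 0.25)),
               0.5 * log(0.5 / 0.75) + 0.5 * log(0.5 / 0.25),
               tolerance = 1e-15)
  # non-negativity over random pmf pairs (Gibbs inequality)
  set.seed(7)
  for (i in 1:25) {
    a <- stats::rgamma(5, 1); a <- a / sum(a)
    b <- stats::rgamma(5, 1); b <- b / sum(b)
    expect_gte(kl_divergence(a, b), 0)
  }
  # zero entries in P are fine; zero in Q under P support is not
  expect_equal(kl_divergence(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)),
               0.5 * log(2) + 0.5 * log(2), tolerance = 1e-15)
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "positive")
  expect_error(kl_divergence(c(0.5, 0.5), c(0.2, 0.2, 0.6)), "support")
})

test_that("Fisher information matches Bernoulli closed forms and is PSD", {
  bern <- function(q) c(1 - q[1], q[1])
  expect_equal(fisher_information(bern, 0.5)[1, 1], 4, tolerance = 1e-6)
  for (p in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(fisher_information(bern, p)[1, 1], 1 / (p * (1 - p)),
                 tolerance = 1e-6)
  }
  # additivity: n iid gates sharing one open probability
  n <- 4
  prod_bern <- function(q) {
    k <- 0:n
    choose(n, k) * q[1]^k * (1 - q[1])^(n - k)
  }
  expect_equal(fisher_information(prod_bern, 0.3)[1, 1],
               n / (0.3 * 0.7), tolerance = 1e-5)
  # two-parameter family: symmetry and PSD
  fam2 <- function(q) {
    m <- outer(c(1 - q[1], q[1]), c(1 - q[2], q[2]))
    as.numeric(m)
  }
  G <- fisher_information(fam2, c(0.3, 0.65))
  expect_identical(G, t(G))
  expect_true(all(eigen(G, symmetric = TRUE)$values >= -1e-10))
  expect_error(fisher_information(bern, 1e-7), "boundary")
})

test_that("KL locally equals the Fisher quadratic form", {
  bern <- function(q) c(1 - q[1], q[1])
  for (p in c(0.2, 0.5, 0.8)) {
    d <- 1e-3
    kl <- kl_divergence(bern(p), bern(p + d))
    quad <- 0.5 * d^2 * fisher_information(bern, p)[1, 1]
    expect_equal(kl / quad, 1, tolerance = 0.05)
  }
})
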