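# Independent oracles used across the suite.

# Bivariate standard-normal orthant probability P(Z1 < a, Z2 < a | rho) by
# one-dimensional quadrature of the conditional normal CDF.
orthant_prob <- function(a, rho) {
  stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm((a - rho * z) / sqrt(1 - rho^2))
  }, -Inf, a, rel.tol = 1e-10)$value
}

# Exact outcome prevalence for a constant-effect scenario with independent
# exposures: integrate expit(intercept + beta * j) over j ~ Binomial(K, p).
constant_effect_prevalence <- function(intercept = -2.2, beta = 0.15,
                                       K = 10, p = 0.2) {
  j <- 0:K
  sum(stats::dbinom(j, K, p) * stats::plogis(intercept + beta * j))
}

# Monte-Carlo oracle for the variance of a linear combination t(T) %*% d,
# d ~ MVN(delta, cov): empirical SD over n draws.
mc_linear_sd <- function(basis_row, delta, cov, n = 1e6) {
  Z <- matrix(stats::rnorm(n * length(delta)), n) %*% chol(cov)
  d <- sweep(Z, 2, delta, "+")
  stats::sd(drop(d %*% basis_row))
}

# A small jittered-lag scenario-1 data set shared by several tests.
make_scenario1_data <- function(n = 10000, gamma = 0.975, seed = 101) {
  simulate_dlm_data(dlm_scenario(1), gamma = gamma, n = n, seed = seed)
}
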