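# Independent quadrature oracles used across the suite. These deliberately
# avoid the package's closed forms: everything is brute-force integration of
# densities, so agreement with the production code is a real check.

quad <- function(f, lower = -Inf, upper = Inf) {
  stats::integrate(f, lower, upper, rel.tol = 1e-12, abs.tol = 1e-14,
                   subdivisions = 500L)$value
}

# int p^a dlambda by quadrature
power_integral_quad <- function(mean, sd, a) {
  quad(function(x) dnorm(x, mean, sd)^a)
}

# Term-by-term quadrature of the pseudodistance between two normals
pseudodistance_quad <- function(p, q, gamma) {
  dp <- function(x) dnorm(x, p$mean, p$sd)
  dq <- function(x) dnorm(x, q$mean, q$sd)
  t1 <- log(quad(function(x) dp(x)^gamma * dp(x))) / (gamma + 1)
  t2 <- log(quad(function(x) dq(x)^gamma * dq(x))) / (gamma * (gamma + 1))
  t3 <- log(quad(function(x) dp(x)^gamma * dq(x))) / gamma
  t1 + t2 - t3
}

# Overall discrepancy W_theta at the true model theta0 = candidate theta,
# by quadrature of its defining integrals.
w_theta_quad <- function(theta, theta0, gamma) {
  dp <- function(x) dnorm(x, theta$mean, theta$sd)
  dq <- function(x) dnorm(x, theta0$mean, theta0$sd)
  log(quad(function(x) dp(x)^(gamma + 1))) / (gamma + 1) -
    log(quad(function(x) dp(x)^gamma * dq(x))) / gamma
}

# A small fixed regression design for reuse
toy_regression <- function(n = 120, p = 2, seed = 42, sigma = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- 1 + X %*% rep(1, p) + rnorm(n, 0, sigma)
  list(y = as.vector(y), X = X)
}
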