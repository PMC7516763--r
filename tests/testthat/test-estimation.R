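test_that("small-gamma normal fit reduces to maximum likelihood", {
  set.seed(11)
  x <- rnorm(150, 3, 2)
  fit <- fit_normal_mpe(x, gamma = 1e-3)
  ml_mean <- mean(x)
  ml_sd <- sqrt(mean((x - ml_mean)^2))
  expect_equal(fit$alpha, ml_mean, tolerance = 1e-3)
  expect_equal(fit$sigma, ml_sd, tolerance = 1e-3)
})

test_that("small-gamma regression fit reduces to ordinary least squares", {
  dat <- toy_regression(n = 120, p = 2, seed = 5)
  fit <- fit_regression_mpe(dat$y, dat$X, gamma = 1e-3)
  ols <- lm.fit(cbind(1, dat$X), dat$y)
  expect_equal(fit$alpha, unname(ols$coefficients[1]), tolerance = 1e-3)
  expect_equal(fit$beta, unname(ols$coefficients[-1]), tolerance = 1e-3)
  expect_equal(fit$sigma, sqrt(mean(ols$residuals^2)), tolerance = 1e-3)
})

test_that("the normal fit recovers known parameters within Monte Carlo error", {
  set.seed(21)
  x <- rnorm(500, 2, 1.5)
  fit <- fit_normal_mpe(x, gamma = 0.2)
  # asymptotic standard errors from the sandwich covariance at the truth
  V <- asymptotic_info(normal_spec(2, 1.5), 0.2)$V
  se <- sqrt(diag(V) / 500)
  expect_lt(abs(fit$alpha - 2), 3 * se[1])
  expect_lt(abs(fit$sigma - 1.5), 3 * se[2])
})

test_that("the regression fit recovers known coefficients within Monte Carlo error", {
  set.seed(22)
  n <- 500
  X <- cbind(rnorm(n, 1, 3), rnorm(n, 2, 3))
  y <- 1 + X[, 1] + X[, 2] + rnorm(n)
  fit <- fit_regression_mpe(y, X, gamma = 0.2)
  # OLS standard errors, inflated for the mild efficiency loss at gamma = 0.2
  se <- sqrt(diag(solve(crossprod(cbind(1, X))))) * 1.2
  expect_lt(abs(fit$alpha - 1), 3 * se[1])
  expect_lt(abs(fit$beta[1] - 1), 3 * se[2])
  expect_lt(abs(fit$beta[2] - 1), 3 * se[3])
  expect_lt(abs(fit$sigma - 1), 0.15)
})

test_that("estimates are equivariant under affine transformations", {
  set.seed(31)
  x <- rnorm(200, 1, 2)
  f0 <- fit_normal_mpe(x, gamma = 0.2)
  f1 <- fit_normal_mpe(-3 * x + 4, gamma = 0.2)
  expect_equal(f1$alpha, -3 * f0$alpha + 4, tolerance = 1e-4)
  expect_equal(f1$sigma, 3 * f0$sigma, tolerance = 1e-4)

  dat <- toy_regression(n = 150, p = 2, seed = 6)
  for (gamma in c(0.01, 0.1, 0.3)) {
    f0 <- fit_regression_mpe(dat$y, dat$X, gamma)
    a <- 2.5; cc <- c(-1, 0.5)
    y2 <- a * dat$y + dat$X %*% cc
    f1 <- fit_regression_mpe(as.vector(y2), dat$X, gamma)
    expect_equal(f1$alpha, a * f0$alpha, tolerance = 1e-4)
    expect_equal(f1$beta, a * f0$beta + cc, tolerance = 1e-4)
    expect_equal(f1$sigma, a * f0$sigma, tolerance = 1e-4)
  }
})

test_that("degenerate and invalid inputs raise informative errors", {
  expect_error(fit_normal_mpe(rep(1.3, 50), gamma = 0.2), "identical")
  expect_error(fit_normal_mpe(c(1, 2), gamma = 0.2), "at least 3")
  # noiseless regression: sigma floor
  X <- matrix(seq_len(30), 30, 1)
  expect_error(fit_regression_mpe(1 + X[, 1], X, gamma = 0.2), "degenerate")
  # rank-deficient design
  X2 <- cbind(rnorm(30), 0)
  X2 <- cbind(X2[, 1], X2[, 1])
  expect_error(fit_regression_mpe(rnorm(30), X2, gamma = 0.2), "rank deficient")
  expect_error(fit_regression_mpe(rnorm(4), matrix(rnorm(8), 4, 2), 0.2),
               "p \\+ 3")
})

test_that("the two Q statistic routes agree and q_value is the evaluated objective", {
  set.seed(41)
  x <- rnorm(200, 0, 1)
  fit <- fit_normal_mpe(x, gamma = 0.25)
  # q_statistic errors out if the direct route and -ln(Rhat)/gamma disagree
  # beyond 1e-8; on healthy input they agree to ~1e-12
  q <- q_statistic(fit, x)
  expect_equal(q, fit$q_value, tolerance = 1e-9)

  dat <- toy_regression(n = 100, p = 3, seed = 7)
  fitr <- fit_regression_mpe(dat$y, dat$X, gamma = 0.15)
  expect_equal(q_statistic(fitr, dat$y, dat$X), fitr$q_value, tolerance = 1e-9)
})

test_that("Q at the fit approaches the true overall discrepancy for large n", {
  set.seed(51)
  gamma <- 0.2
  x <- rnorm(5000, 1, 2)
  fit <- fit_normal_mpe(x, gamma)
  w0 <- w_theta_quad(normal_spec(1, 2), normal_spec(1, 2), gamma)
  # MC standard error of Q from the limit law: sigma(theta0)/(gamma R) / sqrt(n)
  ai <- asymptotic_info(normal_spec(1, 2), gamma)
  se <- sqrt(ai$sigma2_theta0) / (gamma * ai$r_gamma) / sqrt(5000)
  expect_lt(abs(fit$q_value - w0), 3 * se)
})

test_that("the optimizer never returns a worse objective than its starting points", {
  set.seed(61)
  n <- 60
  X <- cbind(rnorm(n, 1, 3), rnorm(n, 2, 3))
  y <- 1 + X[, 1] + X[, 2] + rnorm(n) + 6 * (runif(n) < 0.15) # outliers
  for (gamma in c(0.1, 0.3)) {
    fit <- fit_regression_mpe(y, X, gamma)
    Z <- cbind(1, X)
    ols <- lm.fit(Z, y)
    starts <- picsel:::mpe_starts(y, Z, ols)
    for (st in starts) {
      expect_lte(fit$q_value,
                 picsel:::mpe_objective(st, y, Z, gamma) + 1e-10)
    }
  }
})
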