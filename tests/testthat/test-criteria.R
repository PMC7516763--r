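test_that("the normal-model PIC penalty has the stated closed form", {
  # r(gamma) from the closed-form power integrals matches quadrature
  gamma <- 0.2
  spec <- normal_spec(0, 1)
  r_closed <- normal_power_integral(spec, 2 * gamma + 1) /
    normal_power_integral(spec, gamma + 1)^2
  r_quad <- power_integral_quad(0, 1, 2 * gamma + 1) /
    power_integral_quad(0, 1, gamma + 1)^2
  expect_equal(r_closed, r_quad, tolerance = 1e-8)
  expect_equal(r_closed, (gamma + 1) / sqrt(2 * gamma + 1), tolerance = 1e-12)

  # total correction at gamma = 0.2, n = 20, d = 2 by independent arithmetic
  set.seed(71)
  x <- rnorm(20)
  fit <- fit_normal_mpe(x, gamma)
  pen1 <- (1.2^2 / 1.4^1.5) * 2 / 20
  pen2 <- (1 - 1.2 / sqrt(1.4)) / (2 * 0.2 * 20)
  expect_equal(pic_normal(fit) - fit$q_value, pen1 + pen2, tolerance = 1e-12)

  # the leading penalty factor tends to 1, so the penalty tends to d/n
  g <- 1e-9
  expect_equal((g + 1)^2 / (2 * g + 1)^1.5, 1, tolerance = 1e-8)
  expect_error(pic_normal(fit_regression_mpe(x, matrix(rnorm(20), 20, 1), 0.2)),
               "normal fit")
})

test_that("regression PIC variants differ by a model-independent constant", {
  set.seed(72)
  n <- 40
  X <- cbind(rnorm(n, 1, 3), rnorm(n, 2, 3), rnorm(n, 2, 3), rnorm(n, 3, 3))
  y <- 1 + X[, 1] + X[, 2] + rnorm(n)
  gamma <- 0.2
  diffs <- sapply(list(1, c(1, 2), c(1, 2, 3), c(1, 2, 3, 4)), function(s) {
    fit <- fit_regression_mpe(y, X[, s, drop = FALSE], gamma)
    pic_regression(fit, "full") - pic_regression(fit, "reduced")
  })
  expect_lt(max(diffs) - min(diffs), 1e-12)
})

test_that("the regression PIC per-parameter penalty is strictly positive", {
  # per-d penalty from the stated formula, by independent arithmetic
  for (gamma in c(0.01, 0.05, 0.1, 0.2, 0.3)) {
    per_d <- (gamma + 1)^2 / (2 * gamma + 1)^1.5 +
      (1 - sqrt((gamma + 1) / (2 * gamma + 1))) / (2 * gamma)
    expect_gt(per_d, 0)
  }
  # hand value at gamma = 0.2: 1.44/1.4^1.5 + (1 - sqrt(1.2/1.4))/0.4
  expect_equal(1.44 / 1.4^1.5 + (1 - sqrt(1.2 / 1.4)) / 0.4,
               1.0547503, tolerance = 1e-6)
  # warning outside the derivation range
  dat <- toy_regression(n = 30, p = 1, seed = 8)
  fit <- suppressWarnings(fit_regression_mpe(dat$y, dat$X, gamma = 0.5))
  expect_warning(pic_regression(fit), "gamma")
})

test_that("AIC and BIC match hand arithmetic on a six-point table", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.2, 3.9, 6.1, 8.2, 9.8, 12.3)
  X <- matrix(x, ncol = 1)
  # independent route: explicit normal-equation algebra
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  expect_equal(aic_score(y, X), 6 * log(rss / 6) + 2 * 1 + 2, tolerance = 1e-12)
  expect_equal(aic_score(y, X, sigma2 = "unbiased"),
               6 * log(rss / 4) + 2 * 1 + 2, tolerance = 1e-12)
  expect_equal(bic_score(y, X), 6 * log(rss / 6) + 3 * log(6), tolerance = 1e-12)
})

test_that("BIC penalizes extra parameters more than AIC once log n > 2", {
  # per extra parameter AIC adds 2 and BIC adds log n
  for (n in 13:500) expect_gt(log(n), 2)
  # and on data: same sigma2 route, so the value difference is the penalty
  set.seed(73)
  n <- 100
  X <- matrix(rnorm(2 * n), n, 2)
  y <- 1 + X[, 1] + rnorm(n)
  gap2 <- bic_score(y, X) - aic_score(y, X)
  gap1 <- bic_score(y, X[, 1, drop = FALSE]) - aic_score(y, X[, 1, drop = FALSE])
  expect_gt(gap2, gap1)  # BIC's extra cost grows with p
})

test_that("duplicated regressors are rejected as rank deficient", {
  set.seed(74)
  X <- cbind(rnorm(30), rnorm(30))
  X <- cbind(X, X[, 1])
  y <- rnorm(30)
  expect_error(aic_score(y, X), "rank deficient")
  expect_error(fit_regression_mpe(y, X, 0.2), "rank deficient")
})

test_that("the BHHJ fit tends to OLS as alpha -> 0", {
  dat <- toy_regression(n = 100, p = 2, seed = 9)
  fit <- fit_bhhj(dat$y, dat$X, alpha = 1e-3)
  ols <- lm.fit(cbind(1, dat$X), dat$y)
  expect_equal(unname(fit$coefficients), unname(ols$coefficients),
               tolerance = 1e-3)
  expect_equal(fit$sigma, sqrt(mean(ols$residuals^2)), tolerance = 1e-3)
})

test_that("the MDIC penalty increases strictly with model dimension", {
  alpha <- 0.25
  pen <- function(p) (2 * pi)^(-alpha / 2) * (1 + alpha)^(2 + p / 2) * p
  expect_true(all(diff(sapply(1:10, pen)) > 0))
})

test_that("candidate enumeration counts and ordering are deterministic", {
  c15 <- enumerate_candidates(4)
  expect_length(c15, 15)
  expect_length(enumerate_candidates(4, 2), 11)
  expect_length(enumerate_candidates(1), 1)
  expect_identical(names(c15)[1:5], c("X1", "X2", "X3", "X4", "X1,X2"))
  expect_identical(c15[["X1,X2,X4"]], c(1L, 2L, 4L))
  expect_error(enumerate_candidates(4, 5), "min_size")
  expect_error(enumerate_candidates(0), "min_size")
})

test_that("selection is invariant to candidate ordering and handles singletons", {
  d <- hald()
  y <- d$Y; X <- as.matrix(d[, 1:4])
  cands <- enumerate_candidates(4, 2)
  s1 <- select_model(y, X, "BIC", candidates = cands)
  s2 <- select_model(y, X, "BIC", candidates = rev(cands))
  expect_identical(s1$chosen, s2$chosen)
  s3 <- select_model(y, X, "AIC", candidates = cands["X1,X2"])
  expect_identical(s3$chosen, c(1L, 2L))
  expect_identical(nrow(s3$ranking), 1L)
})

test_that("ties are broken toward the smaller model", {
  # two identical candidates up to a duplicated-index relabeling can't be
  # built, so construct a literal tie: same subset listed twice with an
  # extra regressor whose coefficient contribution is exactly zero is not
  # reproducible either; instead check the documented rule directly
  vals <- c(1.0, 1.0 + 5e-11, 2)
  cands <- list(c(1L, 2L, 3L), c(1L, 2L), c(3L))
  ord <- picsel:::rank_candidates(vals, cands)
  expect_identical(ord[1], 2L)  # smaller model wins the tie
})

test_that("all-subsets selection on the cement data behaves as documented", {
  d <- hald()
  y <- d$Y; X <- as.matrix(d[, 1:4])
  lab <- function(s) picsel:::model_label(s$chosen)
  # AIC under the two variance conventions
  expect_identical(lab(select_model(y, X, "AIC", min_size = 2)), "X1,X2,X4")
  expect_identical(lab(select_model(y, X, "AIC", min_size = 2,
                                    sigma2 = "unbiased")), "X1,X2")
  expect_identical(lab(select_model(y, X, "BIC", min_size = 2)), "X1,X2")
  # PIC: the three-variable models are nearly tied; gamma moves the choice
  expect_identical(lab(select_model(y, X, "PIC", gamma = 0.05, min_size = 2)),
                   "X1,X2,X4")
  expect_identical(lab(select_model(y, X, "PIC", gamma = 0.2, min_size = 2)),
                   "X1,X2,X3")
  # MDIC under the two penalty forms
  expect_identical(lab(select_model(y, X, "MDIC", min_size = 2)), "X1,X2")
  expect_identical(lab(select_model(y, X, "MDIC", min_size = 2,
                                    mdic_penalty = "no_p")), "X1,X2,X3")
})
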