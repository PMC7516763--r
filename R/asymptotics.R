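## Asymptotic covariance machinery for the minimum pseudodistance estimator of
## the univariate normal model, theta = (m, sigma), d = 2.
##
## With h(x, theta) = C_gamma(theta)^{-1} p_theta^gamma(x) and u = (x - m)/sigma,
##   d log h / d m     = gamma u / sigma
##   d log h / d sigma = gamma (u^2 - 1/(gamma+1)) / sigma
## and the second-order log-derivatives are
##   -gamma/sigma^2,  -2 gamma u / sigma^2,
##   gamma/((gamma+1) sigma^2) - 3 gamma u^2 / sigma^2.
## Everything below integrates these against the model density by adaptive
## quadrature, which serves as the production route for S and M (no closed
## form is attempted); M_gamma additionally has the closed form
## M_gamma = (gamma+1)^2/(2 gamma+1)^{3/2} A(gamma) V^{-1},
## A(gamma) = diag(1, (3 gamma^2 + 4 gamma + 2)/(2(2 gamma+1))).

h_logderivs <- function(x, mean, sd, gamma) {
  u <- (x - mean) / sd
  list(
    g1 = gamma * u / sd,
    g2 = gamma * (u^2 - 1 / (gamma + 1)) / sd,
    h11 = rep(-gamma / sd^2, length(x)),
    h12 = -2 * gamma * u / sd^2,
    h22 = gamma / ((gamma + 1) * sd^2) - 3 * gamma * u^2 / sd^2
  )
}

quad_norm <- function(f, mean, sd) {
  stats::integrate(f, lower = mean - 12 * sd, upper = mean + 12 * sd,
                   rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 400L)$value
}

#' Asymptotic information of the normal-model minimum pseudodistance estimator
#'
#' Computes, by adaptive quadrature at \eqn{\theta_0 = (m, \sigma)}:
#' the matrices \eqn{S = -\int \partial^2_\theta h \, dP_{\theta_0}} and
#' \eqn{M = \int \partial_\theta h \, \partial_\theta h^t \, dP_{\theta_0}},
#' the sandwich covariance \eqn{V = S^{-1} M S^{-1}} of
#' \eqn{\sqrt{n}(\hat\theta_n - \theta_0)}, the variance
#' \eqn{\sigma^2(\theta_0) = \int h^2 dP_{\theta_0} - (\int h\,dP_{\theta_0})^2}
#' driving the limit law of \eqn{\hat R_\gamma}, and the Hessian-of-discrepancy
#' matrix \eqn{M_\gamma(\theta_0)} (quadrature route), together with its
#' closed form
#' \eqn{M_\gamma = \frac{(\gamma+1)^2}{(2\gamma+1)^{3/2}} A(\gamma) V^{-1}},
#' \eqn{A(\gamma) = \mathrm{diag}(1,
#'   \frac{3\gamma^2+4\gamma+2}{2(\gamma+1)(2\gamma+1)})}.
#' (The closed form can be verified symbolically: the scale components obey
#' \eqn{M_{22} = 2/(\gamma+1)^2} and \eqn{V_{22} =
#' (\gamma+1)^5 (3/c^2 - 2/(bc) + 1/b^2) / (4\sqrt{c})\,\sigma^2} with
#' \eqn{b = \gamma+1}, \eqn{c = 2\gamma+1}, whose product reduces to the
#' stated \eqn{A_{22}} times the leading factor.)
#' As \eqn{\gamma \to 0}, \eqn{V} tends to the inverse Fisher information
#' \eqn{\mathrm{diag}(\sigma^2, \sigma^2/2)} and \eqn{A \to I}.
#'
#' @param spec A [normal_spec()] giving \eqn{\theta_0}.
#' @param gamma Pseudodistance order, \eqn{\gamma > 0}.
#'
#' @return A list of class `"mpe_asymptotics"`: `S`, `M`, `V` (2x2 matrices,
#'   parameter order (mean, sd)), `sigma2_theta0`, `r_gamma`
#'   (\eqn{R_\gamma(\theta_0) = \int h \, dP_{\theta_0}}), `M_gamma`
#'   (quadrature), `M_gamma_closed` and `A_gamma`.
#' @export
asymptotic_info <- function(spec, gamma) {
  check_gamma(gamma)
  m <- spec$mean; sd <- spec$sd
  if (is.null(sd) || sd <= 0) stop("invalid normal spec", call. = FALSE)

  dens <- function(x) stats::dnorm(x, m, sd)
  hfun <- function(x) h_weight(x, spec, gamma)

  ## S and M
  Sel <- function(which) {
    quad_norm(function(x) {
      ld <- h_logderivs(x, m, sd, gamma)
      g1 <- ld$g1; g2 <- ld$g2
      h2 <- switch(which,
                   "11" = g1 * g1 + ld$h11,
                   "12" = g1 * g2 + ld$h12,
                   "22" = g2 * g2 + ld$h22)
      -hfun(x) * h2 * dens(x)
    }, m, sd)
  }
  Mel <- function(which) {
    quad_norm(function(x) {
      ld <- h_logderivs(x, m, sd, gamma)
      gg <- switch(which,
                   "11" = ld$g1^2,
                   "12" = ld$g1 * ld$g2,
                   "22" = ld$g2^2)
      hfun(x)^2 * gg * dens(x)
    }, m, sd)
  }
  S <- matrix(c(Sel("11"), Sel("12"), Sel("12"), Sel("22")), 2, 2)
  M <- matrix(c(Mel("11"), Mel("12"), Mel("12"), Mel("22")), 2, 2)
  Sinv <- solve(S)
  V <- Sinv %*% M %*% Sinv
  V <- (V + t(V)) / 2

  r_gamma <- quad_norm(function(x) hfun(x) * dens(x), m, sd)
  h2int <- quad_norm(function(x) hfun(x)^2 * dens(x), m, sd)
  sigma2 <- h2int - r_gamma^2

  ## M_gamma by quadrature of its defining power-integral form, using the
  ## plain score s = (u/sigma, (u^2 - 1)/sigma) of the normal density.
  ip <- normal_power_integral(spec, gamma + 1)
  score <- function(x) {
    u <- (x - m) / sd
    list(s1 = u / sd, s2 = (u^2 - 1) / sd)
  }
  pg1 <- function(x) dens(x)^(gamma + 1)
  num_ss <- function(which) {
    quad_norm(function(x) {
      s <- score(x)
      ss <- switch(which, "11" = s$s1^2, "12" = s$s1 * s$s2, "22" = s$s2^2)
      pg1(x) * ss
    }, m, sd)
  }
  num_s <- function(j) {
    quad_norm(function(x) {
      s <- score(x)
      pg1(x) * (if (j == 1) s$s1 else s$s2)
    }, m, sd)
  }
  SS <- matrix(c(num_ss("11"), num_ss("12"), num_ss("12"), num_ss("22")), 2, 2)
  sv <- c(num_s(1), num_s(2))
  M_gamma <- (SS * ip - sv %*% t(sv)) / ip^2

  A_gamma <- diag(c(1, (3 * gamma^2 + 4 * gamma + 2) /
                         (2 * (gamma + 1) * (2 * gamma + 1))))
  M_gamma_closed <- (gamma + 1)^2 / (2 * gamma + 1)^1.5 * A_gamma %*% solve(V)

  structure(list(S = S, M = M, V = V, sigma2_theta0 = sigma2,
                 r_gamma = r_gamma, M_gamma = M_gamma,
                 M_gamma_closed = M_gamma_closed, A_gamma = A_gamma,
                 gamma = gamma, spec = spec),
            class = "mpe_asymptotics")
}

#' @export
print.mpe_asymptotics <- function(x, ...) {
  cat(sprintf("Asymptotics of the normal-model MPE at (m = %g, sd = %g), gamma = %g\n",
              x$spec$mean, x$spec$sd, x$gamma))
  cat("V = S^-1 M S^-1:\n"); print(signif(x$V, 6))
  cat(sprintf("sigma^2(theta0) = %.6g, R_gamma(theta0) = %.6g\n",
              x$sigma2_theta0, x$r_gamma))
  invisible(x)
}
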