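## Contaminated-regression Monte Carlo harness: data generator and the
## selection-proportion experiment over all candidate subsets.

#' Configuration of the contaminated-regression simulation
#'
#' Describes the study design: four Gaussian regressors, the true model
#' \eqn{Y = 1 + X_1 + X_2 + \epsilon} with \eqn{\epsilon \sim N(0,1)}, and
#' contamination by a shifted noise term \eqn{\epsilon^* \sim N(5,1)} blended
#' as \eqn{Y_i = d_1(1 + X_{1i} + X_{2i} + \epsilon_i) + d_2(1 + X_{1i} +
#' X_{2i} + \epsilon^*_i)} with \eqn{d_1 + d_2 = 1}. `d1 = 1` gives the
#' uncontaminated model. The default regressor laws are
#' \eqn{N(1,3), N(2,3), N(2,3), N(3,3)} (mean, standard deviation); only
#' \eqn{X_1, X_2} enter the truth, \eqn{X_3, X_4} are decoys.
#'
#' @param n Sample size per replicate (at least 8).
#' @param d1 Weight of the clean component, in `[0, 1]`; `d2 = 1 - d1`.
#' @param replicates Number of Monte Carlo replicates (default 50).
#' @param gamma Numeric vector of pseudodistance orders for the PIC rows.
#' @param criteria Character vector among `"PIC"`, `"AIC"`, `"BIC"`, `"MDIC"`.
#' @param scheme `"blend"` (default; the deterministic per-row noise blend
#'   \eqn{d_1\epsilon + d_2\epsilon^*}) or `"mixture"` (each row's noise is
#'   \eqn{\epsilon^*} with probability \eqn{d_2}).
#' @param regressor_means,regressor_sds Length-4 numeric vectors.
#' @param coef True coefficients \eqn{(a_0, a_1, a_2)}.
#' @param noise_mean,noise_sd Clean noise parameters (\eqn{N(0,1)}).
#' @param contam_mean,contam_sd Contaminating noise parameters (\eqn{N(5,1)}).
#' @param min_size Smallest candidate size (default 1: all 15 subsets of 4).
#' @param seed Base seed; every replicate seed is derived from it.
#' @param ... Further arguments stored as-is (e.g. `variant`, `sigma2`,
#'   `mdic_penalty`, `alpha`) and passed to [select_model()].
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n = 20L, d1 = 1, replicates = 50L,
                       gamma = c(0.01, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3),
                       criteria = c("PIC", "AIC", "BIC", "MDIC"),
                       scheme = c("blend", "mixture"),
                       regressor_means = c(1, 2, 2, 3),
                       regressor_sds = c(3, 3, 3, 3),
                       coef = c(1, 1, 1),
                       noise_mean = 0, noise_sd = 1,
                       contam_mean = 5, contam_sd = 1,
                       min_size = 1L, seed = 1L, ...) {
  scheme <- match.arg(scheme)
  criteria <- match.arg(criteria, several.ok = TRUE)
  stopifnot(n >= 8L, d1 >= 0, d1 <= 1, replicates >= 1L,
            length(regressor_means) == 4L, length(regressor_sds) == 4L,
            all(regressor_sds > 0), length(coef) == 3L,
            noise_sd > 0, contam_sd > 0)
  if ("PIC" %in% criteria) stopifnot(all(gamma > 0))
  structure(list(n = as.integer(n), d1 = d1, d2 = 1 - d1,
                 replicates = as.integer(replicates), gamma = gamma,
                 criteria = criteria, scheme = scheme,
                 regressor_means = regressor_means,
                 regressor_sds = regressor_sds, coef = coef,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 contam_mean = contam_mean, contam_sd = contam_sd,
                 min_size = as.integer(min_size), seed = as.integer(seed),
                 select_args = list(...)),
            class = "sim_config")
}

## Derive a valid 32-bit replicate seed from the base seed.
replicate_seed <- function(base_seed, r) {
  (abs(base_seed) %% 1000003L) * 2048L + r %% 2048L
}

#' Generate one replicate of the contaminated regression design
#'
#' Draws the four regressors and both noise terms, then forms the response
#' under the configured contamination scheme. With the blend scheme the noise
#' of every row is \eqn{d_1\epsilon_i + d_2\epsilon^*_i} — a deterministic
#' blend, so \eqn{E[Y - (1 + X_1 + X_2)] = 5 d_2} and the noise variance is
#' \eqn{d_1^2 + d_2^2} under the default noise laws. With `d1 = 1` the data
#' are identical to the clean model for the same seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this replicate (sets the RNG).
#'
#' @return A list with `y` (length n) and `X` (n x 4 matrix, columns
#'   `X1..X4`).
#' @export
generate_dataset <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  n <- config$n
  X <- vapply(1:4, function(j) {
    stats::rnorm(n, config$regressor_means[j], config$regressor_sds[j])
  }, numeric(n))
  colnames(X) <- paste0("X", 1:4)
  eps <- stats::rnorm(n, config$noise_mean, config$noise_sd)
  eps_star <- stats::rnorm(n, config$contam_mean, config$contam_sd)
  noise <- switch(config$scheme,
    blend = config$d1 * eps + config$d2 * eps_star,
    mixture = ifelse(stats::runif(n) < config$d2, eps_star, eps))
  mu <- config$coef[1] + config$coef[2] * X[, 1] + config$coef[3] * X[, 2]
  list(y = mu + noise, X = X)
}

#' Run the selection-proportion Monte Carlo experiment
#'
#' For each replicate, evaluates every configured criterion (one row per
#' \eqn{\gamma} for PIC) on all candidate subsets and records the chosen
#' model; aggregates to the percentage of replicates selecting each
#' candidate. Deterministic given the base seed. Replicates on which any
#' criterion fails to evaluate are redrawn with a derived seed; redraws are
#' capped at 5% of the replicate count.
#'
#' @param config A [sim_config()].
#'
#' @return A data frame of class `"selection_table"`: columns `criterion`,
#'   `gamma` (`NA` for the gamma-free criteria), one column per candidate
#'   model label, and `true_pct` (the percentage for the true model
#'   `"X1,X2"`). Each row's model percentages sum to exactly 100. The number
#'   of redraws is kept in `attr(, "n_redrawn")`.
#' @export
run_selection_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  candidates <- enumerate_candidates(4L, config$min_size)
  labels <- names(candidates)
  rows <- list()
  for (crit in config$criteria) {
    gl <- if (crit == "PIC") config$gamma else NA_real_
    for (g in gl) rows[[length(rows) + 1L]] <- list(criterion = crit, gamma = g)
  }
  R <- config$replicates
  counts <- matrix(0L, length(rows), length(labels),
                   dimnames = list(NULL, labels))
  max_redraw <- max(1L, ceiling(0.05 * R))
  n_redrawn <- 0L
  for (r in seq_len(R)) {
    attempt <- 0L
    repeat {
      seed_r <- replicate_seed(config$seed, r + attempt * (R + 1L))
      dat <- generate_dataset(config, seed_r)
      chosen <- tryCatch(
        lapply(rows, function(row) {
          args <- c(list(y = dat$y, X = dat$X, criterion = row$criterion,
                         candidates = candidates),
                    if (row$criterion == "PIC") list(gamma = row$gamma),
                    config$select_args)
          do.call(select_model, args)$chosen
        }),
        error = function(e) NULL)
      if (!is.null(chosen)) break
      attempt <- attempt + 1L
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_redraw) {
        stop("too many replicate redraws (fit failures exceeded 5% cap)",
             call. = FALSE)
      }
    }
    for (i in seq_along(rows)) {
      lab <- model_label(chosen[[i]])
      counts[i, lab] <- counts[i, lab] + 1L
    }
  }
  pct <- counts / R * 100
  out <- data.frame(
    criterion = vapply(rows, `[[`, character(1), "criterion"),
    gamma = vapply(rows, `[[`, numeric(1), "gamma"),
    pct, check.names = FALSE, stringsAsFactors = FALSE)
  out$true_pct <- if ("X1,X2" %in% labels) out[["X1,X2"]] else NA_real_
  structure(out, class = c("selection_table", "data.frame"),
            n = config$n, d1 = config$d1, replicates = R,
            seed = config$seed, n_redrawn = n_redrawn)
}

#' @export
print.selection_table <- function(x, ...) {
  cat(sprintf(
    "Selection proportions (%%): n = %d, d1 = %g, %d replicates, seed = %d\n",
    attr(x, "n"), attr(x, "d1"), attr(x, "replicates"), attr(x, "seed")))
  model_cols <- setdiff(names(x), c("criterion", "gamma", "true_pct"))
  nz <- model_cols[colSums(as.matrix(x[model_cols])) > 0]
  print.data.frame(x[, c("criterion", "gamma", nz)], digits = 3)
  invisible(x)
}
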