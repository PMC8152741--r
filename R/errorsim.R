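#' Fit a distributional-assumption regression
#'
#' Regresses the transformed error `LN(y + delta)` on the covariate
#' implied by a distributional assumption (log-normal: Blom normal
#' score; gamma: `ln[(r-3/8)/(n-r+5/8) + 1/4]`; beta: the logit of the
#' plotting position; uniform: the plotting position itself). With the
#' `"lognormal"` assumption this reproduces the rankit regression at the
#' fixed offset; the other assumptions quantify specification error.
#'
#' @param y Positive error values (ppm).
#' @param assumption One of `"lognormal"`, `"gamma"`, `"beta"`,
#'   `"uniform"`.
#' @param delta_hat Offset inherited from the three-parameter log-normal
#'   fit of `y`.
#' @return An object of class `assumption_fit`: list with `assumption`,
#'   `alpha_hat`, `beta_hat`, `mse`, `pseudo_r2`, `delta_hat`, `fitted`,
#'   `covariate`, `ranks`, `n`.
#' @export
fit_assumption_regression <- function(y, assumption = c("lognormal", "gamma", "beta", "uniform"),
                                      delta_hat) {
  assumption <- match.arg(assumption)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) abort("assumption regression needs n >= 10")
  if (min(y) + delta_hat <= 0) abort("min(y) + delta_hat must be positive")
  ranks <- rank(y, ties.method = "average")
  x <- specification_covariate(assumption, ranks, n)
  if (sd(x) == 0) abort("degenerate covariate")
  t <- log(y + delta_hat)
  b <- sum((x - mean(x)) * (t - mean(t))) / sum((x - mean(x))^2)
  a <- mean(t) - b * mean(x)
  fitted <- a + b * x
  res <- t - fitted
  structure(
    list(
      assumption = assumption, alpha_hat = a, beta_hat = b,
      mse = sum(res^2) / (n - 2),
      pseudo_r2 = 1 - sum(res^2) / sum((t - mean(t))^2),
      delta_hat = delta_hat, fitted = fitted, covariate = x,
      ranks = ranks, n = n
    ),
    class = "assumption_fit"
  )
}

#' @export
print.assumption_fit <- function(x, ...) {
  cat(sprintf("<assumption_fit> %s: alpha = %.4g, beta = %.4g, MSE = %.4g, R2 = %.4f\n",
              x$assumption, x$alpha_hat, x$beta_hat, x$mse, x$pseudo_r2))
  invisible(x)
}

#' @export
glance.assumption_fit <- function(x, ...) {
  tibble(
    assumption = x$assumption, n = x$n, alpha_hat = x$alpha_hat,
    beta_hat = x$beta_hat, mse = x$mse, pseudo_r2 = x$pseudo_r2,
    delta_hat = x$delta_hat
  )
}

#' Draw simulated assay errors under a fitted assumption
#'
#' For the log-normal, gamma and beta assumptions each sample's
#' transformed value is redrawn as `Normal(fitted_i, MSE)` and
#' back-transformed to `-delta + exp(z)`. Under the uniform assumption a
#' plotting-position probability is drawn from the sample's six-sigma
#' rank interval, pushed through the fitted regression line, and
#' back-transformed with no residual noise. Back-transformed draws that
#' would be non-positive are floored at `floor_eps` and counted in the
#' `"n_floored"` attribute.
#'
#' @param fit An `assumption_fit` or `rankit_fit` (treated as the
#'   log-normal assumption).
#' @param n_draws Number of replications (rows).
#' @param seed Optional seed.
#' @param add_residual_noise Add the `Normal(0, MSE)` residual for the
#'   non-uniform assumptions (default `TRUE`).
#' @param floor_eps Floor for non-positive back-transformed draws.
#' @return A `n_draws` by `n` matrix of ppm draws, with attribute
#'   `n_floored`.
#' @export
draw_errors <- function(fit, n_draws = 200, seed = NULL,
                        add_residual_noise = TRUE, floor_eps = 1e-12) {
  n_draws <- assert_scalar_count(n_draws, "n_draws")
  if (inherits(fit, "rankit_fit")) {
    assumption <- "lognormal"
    fitted <- fit$fitted; mse <- fit$mse; delta <- fit$delta_hat
    alpha <- fit$alpha_hat; beta <- fit$beta_hat; ranks <- fit$ranks; n <- fit$n
  } else if (inherits(fit, "assumption_fit")) {
    assumption <- fit$assumption
    fitted <- fit$fitted; mse <- fit$mse; delta <- fit$delta_hat
    alpha <- fit$alpha_hat; beta <- fit$beta_hat; ranks <- fit$ranks; n <- fit$n
  } else {
    abort("`fit` must be a rankit_fit or assumption_fit")
  }
  with_seed(seed, {
    z <- if (assumption == "uniform") {
      iv <- six_sigma_interval(ranks, n)
      p <- matrix(runif(n_draws * n), n_draws, n)
      p <- sweep(sweep(p, 2, iv$hi - iv$lo, `*`), 2, iv$lo, `+`)
      alpha + beta * p
    } else {
      z0 <- matrix(fitted, n_draws, n, byrow = TRUE)
      if (add_residual_noise) {
        z0 <- z0 + matrix(rnorm(n_draws * n, sd = sqrt(mse)), n_draws, n)
      }
      z0
    }
    e <- -delta + exp(z)
    n_floored <- sum(e <= 0)
    if (n_floored > 0) e[e <= 0] <- floor_eps
    structure(e, n_floored = n_floored)
  })
}

# tract-stratified resampling indices: within each tract, sample that
# tract's row positions with replacement, preserving per-tract counts
resample_indices <- function(tract_of) {
  idx <- seq_along(tract_of)
  groups <- split(idx, tract_of)
  out <- integer(length(tract_of))
  for (g in groups) {
    out[g] <- if (length(g) == 1L) g else sample(g, length(g), replace = TRUE)
  }
  out
}

#' Tract-stratified bootstrap resample of a survey
#'
#' Resamples, within each tract independently and with replacement, that
#' tract's samples, preserving per-tract counts — the resampling design
#' used to quantify soil-sampling error.
#'
#' @param samples A sample table.
#' @param seed Optional seed.
#' @return A sample table of the same dimensions.
#' @export
bootstrap_resample <- function(samples, seed = NULL) {
  if (!"tract_id" %in% names(samples)) abort("`samples` needs a tract_id column")
  if (any(table(samples$tract_id) < 1)) abort("every tract needs at least one sample")
  with_seed(seed, {
    idx <- resample_indices(samples$tract_id)
    out <- samples[idx, ]
    out$sample_id <- samples$sample_id
    out$tract_id <- samples$tract_id
    out
  })
}

#' Two-step mixture draws: bootstrap then analytical error
#'
#' The combined error-source experiment: each replication first draws a
#' tract-stratified bootstrap resample of the log-normal fitted values,
#' then generates simulated analytical errors from those resampled
#' values under the log-normal assumption
#' (`z = fitted[resampled] + Normal(0, MSE)`, back-transformed).
#'
#' @param samples A sample table (supplies the tract structure).
#' @param fit A `rankit_fit` for one metal of `samples`.
#' @param n_draws Number of replications.
#' @param seed Optional seed.
#' @param indices Optional `n_draws` by `n` matrix of precomputed
#'   resampling indices (to share one bootstrap across metals).
#' @return A `n_draws` by `n` matrix of ppm draws.
#' @export
mixture_draw <- function(samples, fit, n_draws = 200, seed = NULL, indices = NULL) {
  stopifnot(inherits(fit, "rankit_fit"))
  n_draws <- assert_scalar_count(n_draws, "n_draws")
  n <- fit$n
  with_seed(seed, {
    if (is.null(indices)) {
      indices <- t(vapply(seq_len(n_draws), function(i) resample_indices(samples$tract_id),
                          integer(n)))
    }
    z <- matrix(fit$fitted[indices], n_draws, n)
    z <- z + matrix(rnorm(n_draws * n, sd = sqrt(fit$mse)), n_draws, n)
    e <- -fit$delta_hat + exp(z)
    e[e <= 0] <- 1e-12
    e
  })
}

#' Replicated tract-averaged error fields
#'
#' The simulation engine behind the stability experiments: for one error
#' source, produces `n_draws` replications of the tract-by-metal matrix
#' of tract-averaged transformed errors `LN(y + delta)` — the input the
#' factor analysis and the spatial indices consume.
#'
#' Sources: `"analytical"` redraws each sample's transformed error from
#' its fitted log-normal conditional; `"sampling"` bootstrap-resamples
#' observed values within tracts; `"gamma"`, `"beta"` and `"uniform"`
#' redraw under the respective misspecified covariate regression; and
#' `"mixture"` composes a bootstrap resample with log-normal analytical
#' redraws.
#'
#' @param samples A sample table.
#' @param fits Output of [fit_assay_errors()] on `samples`.
#' @param source One of `"analytical"`, `"sampling"`, `"gamma"`,
#'   `"beta"`, `"uniform"`, `"mixture"`.
#' @param n_draws Number of replications.
#' @param seed Optional seed.
#' @return A list of `n_draws` matrices (tracts by metals, transformed
#'   scale), with tract ids as row names.
#' @export
replicate_tract_errors <- function(samples, fits,
                                   source = c("analytical", "sampling", "gamma",
                                              "beta", "uniform", "mixture"),
                                   n_draws = 200, seed = NULL) {
  source <- match.arg(source)
  n_draws <- assert_scalar_count(n_draws, "n_draws")
  metals <- fits$metal
  tract_of <- samples$tract_id
  tract_ids <- sort(unique(tract_of))
  counts <- as.vector(table(factor(tract_of, levels = tract_ids)))
  n <- nrow(samples)

  # per-metal ingredients on the transformed scale
  ingr <- lapply(seq_along(metals), function(j) {
    fit <- fits$fit[[j]]
    y <- samples[[paste0(metals[j], "_err")]]
    base <- list(t_obs = log(y + fit$delta_hat), fit = fit)
    if (source %in% c("gamma", "beta", "uniform")) {
      base$afit <- fit_assumption_regression(y, source, fit$delta_hat)
    }
    base
  })

  avg <- function(z) {
    m <- rowsum(z, tract_of) / counts
    rownames(m) <- tract_ids
    m
  }

  with_seed(seed, {
    lapply(seq_len(n_draws), function(r) {
      idx <- if (source %in% c("sampling", "mixture")) resample_indices(tract_of)
      z <- vapply(ingr, function(g) {
        switch(source,
          analytical = g$fit$fitted + rnorm(n, sd = sqrt(g$fit$mse)),
          sampling = g$t_obs[idx],
          mixture = g$fit$fitted[idx] + rnorm(n, sd = sqrt(g$fit$mse)),
          uniform = {
            iv <- six_sigma_interval(g$afit$ranks, n)
            p <- runif(n, iv$lo, iv$hi)
            g$afit$alpha_hat + g$afit$beta_hat * p
          },
          g$afit$fitted + rnorm(n, sd = sqrt(g$afit$mse))  # gamma, beta
        )
      }, numeric(n))
      colnames(z) <- metals
      avg(z)
    })
  })
}
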