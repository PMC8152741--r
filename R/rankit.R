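#' Fit a three-parameter log-normal by rankit regression
#'
#' Fits the error model `LN(y + delta) = alpha + beta * z(r) + eps`,
#' where `z(r)` is the Blom normal score of the observation's rank: an
#' order-statistics (rankit) regression of the log-shifted value on the
#' expected normal quantile of its plotting position. The offset `delta`
#' is chosen by a one-dimensional search minimizing the regression mean
#' squared error over `delta > -min(y)`; negative offsets are allowed as
#' long as `min(y) + delta` stays positive. `alpha`, `beta` and the MSE
#' come from the ordinary least-squares regression at the selected
#' offset.
#'
#' @param y Vector of positive values (ppm); `n >= 10`. Ties receive
#'   average ranks.
#' @param delta Optional fixed offset; skips the search.
#' @return An object of class `rankit_fit`: a list with `delta_hat`,
#'   `alpha_hat`, `beta_hat`, `mse` (SSE / (n - 2)), `r_squared`, `n`,
#'   `ranks`, `scores`, `fitted` (transformed scale), `residuals`, `y`.
#' @examples
#' z <- blom_scores(200)
#' y <- -5 + exp(2 + 0.5 * z)
#' fit <- fit_three_param_lognormal(y)
#' round(c(fit$delta_hat, fit$alpha_hat, fit$beta_hat), 3)
#' @export
fit_three_param_lognormal <- function(y, delta = NULL) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) abort("`y` must be finite")
  n <- length(y)
  if (n < 10) abort("rankit fitting needs n >= 10")
  if (diff(range(y)) == 0) abort("`y` is degenerate (all values equal)")
  y_min <- min(y)

  ranks <- rank(y, ties.method = "average")
  scores <- blom_scores(n, ranks = ranks)
  s_bar <- mean(scores)
  s_var <- sum((scores - s_bar)^2)

  reg <- function(d) {
    t <- log(y + d)
    t_bar <- mean(t)
    b <- sum((scores - s_bar) * (t - t_bar)) / s_var
    a <- t_bar - b * s_bar
    res <- t - (a + b * scores)
    sse <- sum(res^2)
    list(alpha = a, beta = b, mse = sse / (n - 2), res = res,
         fitted = a + b * scores, t = t,
         # scale-free objective: the raw MSE alone is degenerate (it
         # vanishes as delta grows because log(y + delta) flattens), so
         # the search minimizes the MSE relative to the transformed
         # variance, i.e. 1 - R^2 of the rankit regression
         obj = sse / sum((t - t_bar)^2))
  }
  obj_of <- function(d) reg(d)$obj

  if (is.null(delta)) {
    lo <- -y_min + 1e-6
    # generous upper bound: far enough out that the fit approaches its
    # normal limit (the offset is weakly identified for low skewness)
    hi <- -y_min + 1e3 * max(diff(range(y)), abs(y_min), 1)
    # coarse bracketing grid, concentrated near the lower support bound
    # where the objective curvature lives, then golden-section refinement
    u <- seq(0, 1, length.out = 61)
    grid <- lo + (hi - lo) * u^4
    vals <- vapply(grid, obj_of, numeric(1))
    i <- which.min(vals)
    bl <- grid[max(i - 1L, 1L)]
    bu <- grid[min(i + 1L, length(grid))]
    delta <- optimize(obj_of, c(bl, bu))$minimum
    w <- max(1e-3, 0.01 * (abs(delta) + 1))
    delta <- optimize(obj_of, c(max(lo, delta - w), delta + w))$minimum
  } else {
    if (y_min + delta <= 0) abort("fixed `delta` must satisfy min(y) + delta > 0")
  }

  fit <- reg(delta)
  if (fit$beta <= 0) {
    warn("rankit slope is non-positive; the transformed values do not increase with rank")
  }
  sst <- sum((fit$t - mean(fit$t))^2)
  structure(
    list(
      delta_hat = delta, alpha_hat = fit$alpha, beta_hat = fit$beta,
      mse = fit$mse, r_squared = 1 - sum(fit$res^2) / sst,
      n = n, ranks = ranks, scores = scores,
      fitted = fit$fitted, residuals = fit$res, y = y
    ),
    class = "rankit_fit"
  )
}

#' @export
print.rankit_fit <- function(x, ...) {
  cat(sprintf(
    "<rankit_fit> n = %d, delta = %.4g, alpha = %.4g, beta = %.4g, MSE = %.4g, R2 = %.4f\n",
    x$n, x$delta_hat, x$alpha_hat, x$beta_hat, x$mse, x$r_squared
  ))
  invisible(x)
}

#' Back-transform fitted values to the ppm scale
#'
#' Converts a transformed-scale mean `mu` into the expected value and
#' standard deviation on the original ppm scale under the fitted
#' log-normal: `y_hat = -delta + exp(mu + MSE/2)` and
#' `sd_hat = sqrt(exp(2 mu + MSE) (exp(MSE) - 1))`.
#'
#' @param fit A [fit_three_param_lognormal()] object.
#' @param mu Transformed-scale value(s); defaults to the fitted values.
#' @return A tibble with columns `y_hat` and `sd_hat` (ppm).
#' @export
backtransform <- function(fit, mu = fit$fitted) {
  stopifnot(inherits(fit, "rankit_fit"))
  tibble(
    y_hat = -fit$delta_hat + exp(mu + fit$mse / 2),
    sd_hat = sqrt(exp(2 * mu + fit$mse) * (exp(fit$mse) - 1))
  )
}

#' Outlier percentage by Huber M-estimation
#'
#' Robust location from the iterated Huber M-estimator (tuning constant
#' 1.345) with the median-absolute-deviation scale; observations whose
#' standardized residual exceeds 3 in absolute value are flagged.
#'
#' @param x Numeric vector, `n >= 10`.
#' @param k Huber tuning constant.
#' @param cutoff Standardized-residual cutoff.
#' @return Percentage of observations flagged (0-100).
#' @export
huber_outliers <- function(x, k = 1.345, cutoff = 3) {
  x <- as.numeric(x)
  if (length(x) < 10) abort("huber_outliers needs n >= 10")
  if (mad(x) == 0) abort("zero scale: values are (almost) all equal")
  h <- MASS::huber(x, k = k, tol = 1e-8)
  100 * mean(abs(x - h$mu) / h$s > cutoff)
}

#' Goodness-of-fit diagnostics for a rankit fit
#'
#' Kolmogorov-Smirnov and Anderson-Darling statistics of the transformed
#' values `LN(y + delta)` against a normal distribution with moments
#' estimated from those transformed values (descriptive statistics, no
#' small-sample correction), the rankit-regression pseudo-R-squared, the
#' back-transformed pseudo-R-squared (squared Pearson correlation of the
#' data with the back-transformed fitted values), and the Huber outlier
#' percentage.
#'
#' @param fit A `rankit_fit`.
#' @param y The data the fit was computed on (defaults to `fit$y`).
#' @return A one-row tibble of class `gof_report` with columns `ks_stat`,
#'   `ad_stat`, `pseudo_r2_transformed`, `pseudo_r2_backtransformed`,
#'   `outlier_pct`.
#' @export
goodness_of_fit <- function(fit, y = fit$y) {
  stopifnot(inherits(fit, "rankit_fit"))
  if (length(y) != fit$n) abort("`y` length does not match the fit")
  t <- log(y + fit$delta_hat)
  n <- length(t)
  m <- mean(t); s <- sd(t)
  ts <- sort(t)
  p <- pnorm(ts, m, s)
  i <- seq_len(n)
  ks <- max(pmax(i / n - p, p - (i - 1) / n))
  # tail-stable log probabilities for the A-D sum
  lp <- pnorm(ts, m, s, log.p = TRUE)
  lq <- pnorm(ts, m, s, lower.tail = FALSE, log.p = TRUE)
  ad <- -n - mean((2 * i - 1) * (lp + rev(lq)))
  bt <- backtransform(fit)$y_hat
  out <- tibble(
    ks_stat = ks,
    ad_stat = ad,
    pseudo_r2_transformed = fit$r_squared,
    pseudo_r2_backtransformed = cor(y, bt)^2,
    outlier_pct = huber_outliers(t)
  )
  class(out) <- c("gof_report", class(out))
  out
}

#' Fit every metal of a survey and tabulate diagnostics
#'
#' Runs the three-parameter log-normal rankit fit on each metal's assay
#' errors and collects descriptive statistics plus goodness-of-fit
#' diagnostics into one table (one row per metal).
#'
#' @param samples A sample table.
#' @param metals Metals to fit; defaults to all in `samples`.
#' @return A tibble with columns `metal`, `mean`, `sd`, `min`, `max`,
#'   `delta_hat`, `outlier_pct`, `ks`, `ad`, `pseudo_r2_t`,
#'   `pseudo_r2_bt`, and a list-column `fit` of `rankit_fit` objects.
#' @export
fit_assay_errors <- function(samples, metals = survey_metals(samples)) {
  rows <- lapply(metals, function(mt) {
    col <- paste0(mt, "_err")
    if (!col %in% names(samples)) abort(paste0("unknown metal label: ", mt))
    y <- samples[[col]]
    fit <- fit_three_param_lognormal(y)
    g <- goodness_of_fit(fit)
    tibble(
      metal = mt, mean = mean(y), sd = sd(y), min = min(y), max = max(y),
      delta_hat = fit$delta_hat, outlier_pct = g$outlier_pct,
      ks = g$ks_stat, ad = g$ad_stat,
      pseudo_r2_t = g$pseudo_r2_transformed,
      pseudo_r2_bt = g$pseudo_r2_backtransformed,
      fit = list(fit)
    )
  })
  bind_rows(rows)
}

#' @export
tidy.rankit_fit <- function(x, ...) {
  tibble(
    term = c("delta", "alpha", "beta"),
    estimate = c(x$delta_hat, x$alpha_hat, x$beta_hat)
  )
}

#' @export
glance.rankit_fit <- function(x, ...) {
  tibble(
    n = x$n, delta_hat = x$delta_hat, alpha_hat = x$alpha_hat,
    beta_hat = x$beta_hat, mse = x$mse, r_squared = x$r_squared
  )
}
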