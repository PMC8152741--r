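#' Moran coefficient and Geary ratio with standard errors and bounds
#'
#' Global spatial autocorrelation of a tract-level variable:
#' `MC = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` and
#' `GR = ((n-1)/(2 S0)) * sum_ij w_ij (x_i - x_j)^2 / sum_i z_i^2` with
#' `z` centered, plus their standard errors under both the randomization
#' and the normality null (the classical closed forms), and the extreme
#' attainable values `mc_max` and `gr_min` from the eigenvalues of the
#' doubly-centered symmetrized weights.
#'
#' @param x Values per tract (`n >= 4`, non-constant).
#' @param w A [spatial_weights()] object (binary weights match the
#'   classical index definitions).
#' @return A one-row tibble of class `spatial_indices` with columns
#'   `mc`, `gr`, `se_mc_randomization`, `se_mc_normality`,
#'   `se_gr_randomization`, `se_gr_normality`, `mc_max`, `gr_min`,
#'   `expected_mc` (= -1/(n-1)), `n`.
#' @export
moran_geary <- function(x, w) {
  stopifnot(inherits(w, "spatial_weights"))
  x <- as.numeric(x)
  n <- length(x)
  if (n != w$n) abort("`x` length must match the weights")
  if (n < 4) abort("need n >= 4")
  if (sd(x) == 0) abort("`x` is constant")
  wm <- w$w
  z <- x - mean(x)
  s0 <- sum(wm)
  m2 <- sum(z^2)
  mc <- (n / s0) * as.numeric(t(z) %*% wm %*% z) / m2
  d2 <- outer(x, x, `-`)^2
  gr <- ((n - 1) / (2 * s0)) * sum(wm * d2) / m2

  s1 <- 0.5 * sum((wm + t(wm))^2)
  s2 <- sum((rowSums(wm) + colSums(wm))^2)
  b2 <- n * sum(z^4) / m2^2
  e_mc <- -1 / (n - 1)

  var_mc_norm <- (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - e_mc^2
  var_mc_rand <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
                    b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - e_mc^2
  var_gr_norm <- ((2 * s1 + s2) * (n - 1) - 4 * s0^2) / (2 * (n + 1) * s0^2)
  var_gr_rand <- ((n - 1) * s1 * (n^2 - 3 * n + 3 - (n - 1) * b2) -
                    0.25 * (n - 1) * s2 * (n^2 + 3 * n - 6 - (n^2 - n + 2) * b2) +
                    s0^2 * (n^2 - 3 - (n - 1)^2 * b2)) /
    (n * (n - 2) * (n - 3) * s0^2)

  # extreme values: Rayleigh bounds on the subspace orthogonal to 1
  q <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  c_sym <- (wm + t(wm)) / 2
  mc_max <- (n / s0) * max(eigen(crossprod(q, c_sym %*% q),
                                 symmetric = TRUE, only.values = TRUE)$values)
  lap <- diag(rowSums(c_sym)) - c_sym
  gr_min <- ((n - 1) / s0) * min(eigen(crossprod(q, lap %*% q),
                                       symmetric = TRUE, only.values = TRUE)$values)

  out <- tibble(
    mc = mc, gr = gr,
    se_mc_randomization = sqrt(var_mc_rand),
    se_mc_normality = sqrt(var_mc_norm),
    se_gr_randomization = sqrt(max(var_gr_rand, 0)),
    se_gr_normality = sqrt(var_gr_norm),
    mc_max = mc_max, gr_min = gr_min,
    expected_mc = e_mc, n = n
  )
  class(out) <- c("spatial_indices", class(out))
  out
}

#' Fit the pure simultaneous autoregressive (SAR) model
#'
#' Maximum-likelihood fit of `x = mu + rho W (x - mu) + eps` with the
#' mean estimated by the sample mean and row-standardized weights. The
#' autocorrelation parameter maximizes the profile log-likelihood using
#' the eigenvalue form of `ln|I - rho W|`; the naive variance is the
#' (n-denominator) sample variance of `x`, and the adjusted —
#' spatially-filtered, uninflated — variance is
#' `n^-1 ||(I - rho_hat W)(x - mean(x))||^2`. Positive autocorrelation
#' makes the naive variance exceed the adjusted one (variance
#' inflation).
#'
#' @param x Values per tract (non-constant).
#' @param w Row-standardized [spatial_weights()].
#' @param eigenvalues Optional precomputed spectrum of the weights (from
#'   [weight_eigenvalues()]), to avoid re-decomposition in replicated
#'   fits on the same lattice.
#' @return An object of class `sar_fit`: list with `rho_hat`,
#'   `sigma2_hat` (naive), `sigma2_adjusted`, `shapiro_wilk_p` (of the
#'   filtered residuals), `loglik`, `n`, `residuals`.
#' @export
sar_fit <- function(x, w, eigenvalues = NULL) {
  stopifnot(inherits(w, "spatial_weights"))
  if (w$style != "row") abort("SAR fitting requires row-standardized weights")
  x <- as.numeric(x)
  n <- length(x)
  if (n != w$n) abort("`x` length must match the weights")
  if (sd(x) == 0) abort("`x` is constant")

  lam <- if (is.null(eigenvalues)) weight_eigenvalues(w) else eigenvalues
  lo <- 1 / min(lam) + 1e-9
  hi <- 1 - 1e-9

  xc <- x - mean(x)
  wx <- as.vector(w$w %*% xc)
  prof <- function(rho) {
    e <- xc - rho * wx
    sum(log(1 - rho * lam)) - n / 2 * log(sum(e^2) / n)
  }
  opt <- optimize(prof, c(lo, hi), maximum = TRUE)
  rho <- opt$maximum
  if (rho <= lo + 1e-6 || rho >= hi - 1e-6) {
    warn("SAR autocorrelation estimate is at the boundary of the parameter space")
  }
  e <- xc - rho * wx
  sw <- if (n >= 3 && n <= 5000) tryCatch(shapiro.test(e)$p.value, error = function(...) NA_real_) else NA_real_
  structure(
    list(
      rho_hat = rho,
      sigma2_hat = sum(xc^2) / n,
      sigma2_adjusted = sum(e^2) / n,
      shapiro_wilk_p = sw,
      loglik = opt$objective - n / 2 * (1 + log(2 * pi)),
      n = n, residuals = e
    ),
    class = "sar_fit"
  )
}

#' Spectrum of row-standardized contiguity weights
#'
#' Eigenvalues of `W = D^-1 B`, computed through the similar symmetric
#' matrix `D^-1/2 B D^-1/2` (so the spectrum is real); they bound the
#' SAR parameter space and enter the log-Jacobian of the likelihood.
#'
#' @param w A [spatial_weights()] object.
#' @return Numeric vector of eigenvalues, descending.
#' @export
weight_eigenvalues <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  dh <- 1 / sqrt(w$degree)
  eigen(w$b * (dh %o% dh), symmetric = TRUE, only.values = TRUE)$values
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf(
    "<sar_fit> n = %d, rho = %.3f, sigma2 = %.4g, sigma2_adjusted = %.4g (inflation %.1f%%)\n",
    x$n, x$rho_hat, x$sigma2_hat, x$sigma2_adjusted,
    100 * (x$sigma2_hat / x$sigma2_adjusted - 1)
  ))
  invisible(x)
}

#' @export
tidy.sar_fit <- function(x, ...) {
  tibble(
    term = c("rho", "sigma2", "sigma2_adjusted"),
    estimate = c(x$rho_hat, x$sigma2_hat, x$sigma2_adjusted)
  )
}

#' @export
glance.sar_fit <- function(x, ...) {
  tibble(
    n = x$n, rho_hat = x$rho_hat, sigma2_hat = x$sigma2_hat,
    sigma2_adjusted = x$sigma2_adjusted,
    variance_inflation_pct = 100 * (x$sigma2_hat / x$sigma2_adjusted - 1),
    shapiro_wilk_p = x$shapiro_wilk_p, loglik = x$loglik
  )
}

#' Decompose total variance across error sources
#'
#' Subtracts named error-source variance components from a total and
#' reports each component's share; a residual exceeding the total (a
#' negative remainder) is flagged with a warning but returned.
#'
#' @param total Positive total variance.
#' @param components Named numeric vector of non-negative component
#'   variances (may be empty).
#' @return A tibble with columns `component`, `variance`, `share`
#'   (fraction of total); the last row is the residual.
#' @export
variance_decomposition <- function(total, components = numeric(0)) {
  if (!is.numeric(total) || length(total) != 1 || total <= 0) {
    abort("`total` must be a positive scalar")
  }
  components <- unlist(components)
  if (length(components) > 0) {
    if (is.null(names(components)) || any(!nzchar(names(components)))) {
      abort("`components` must be named")
    }
    if (any(components < 0)) abort("components must be non-negative")
  }
  residual <- total - sum(components)
  if (residual < 0) {
    warn("components exceed the total variance: negative residual (ambiguous decomposition)")
  }
  tibble(
    component = c(names(components), "residual"),
    variance = c(unname(components), residual),
    share = c(unname(components), residual) / total
  )
}

#' Propagate replicated factor scores to spatial indices
#'
#' For one error source, computes the Moran coefficient and Geary ratio
#' of each replication's tract-level factor scores and summarizes their
#' mean and standard deviation per factor — how error propagation
#' perturbs spatial autocorrelation index values.
#'
#' @param score_reps List of replicated score matrices (tracts by
#'   factors), at least 2.
#' @param w Binary [spatial_weights()] for the tracts.
#' @return A tibble with columns `factor`, `mc_mean`, `mc_sd`,
#'   `gr_mean`, `gr_sd`, `n_replications`.
#' @export
propagate_to_indices <- function(score_reps, w) {
  if (length(score_reps) < 2) abort("need at least 2 replications")
  k <- ncol(score_reps[[1]])
  per_rep <- lapply(score_reps, function(s) {
    vapply(seq_len(k), function(j) {
      idx <- moran_geary(s[, j], w)
      c(idx$mc, idx$gr)
    }, numeric(2))
  })
  arr <- array(unlist(per_rep), dim = c(2, k, length(per_rep)))
  tibble(
    factor = paste0("F", seq_len(k)),
    mc_mean = apply(arr[1, , , drop = FALSE], 2, mean),
    mc_sd = apply(arr[1, , , drop = FALSE], 2, sd),
    gr_mean = apply(arr[2, , , drop = FALSE], 2, mean),
    gr_sd = apply(arr[2, , , drop = FALSE], 2, sd),
    n_replications = length(score_reps)
  )
}

#' SAR variance-inflation simulation experiment
#'
#' Simulates replicated zero-mean pure SAR processes
#' `x = rho W x + eps` on a queen-contiguity lattice with
#' row-standardized weights, fits each by maximum likelihood, and
#' records the percentage by which the naive variance exceeds the
#' spatially-adjusted variance — the variance-inflation cost of ignoring
#' positive spatial autocorrelation.
#'
#' @param rho True autocorrelation parameter.
#' @param rows,cols Lattice dimensions.
#' @param n_rep Number of replicates.
#' @param seed Optional seed.
#' @return A tibble with one row per replicate: `rho_hat`, `sigma2_hat`,
#'   `sigma2_adjusted`, `inflation_pct`.
#' @export
sar_inflation_experiment <- function(rho = 0.4, rows = 30, cols = 30,
                                     n_rep = 200, seed = NULL) {
  tess <- make_tessellation(rows, cols)
  w <- spatial_weights(tess, style = "row")
  n <- w$n
  lam <- weight_eigenvalues(w)
  a_inv <- solve(diag(n) - rho * w$w)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_rep), function(r) {
      x <- as.vector(a_inv %*% rnorm(n))
      f <- sar_fit(x, w, eigenvalues = lam)
      tibble(
        rho_hat = f$rho_hat, sigma2_hat = f$sigma2_hat,
        sigma2_adjusted = f$sigma2_adjusted,
        inflation_pct = 100 * (f$sigma2_hat / f$sigma2_adjusted - 1)
      )
    })
  })
}
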