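#' Default per-metal error-distribution parameters
#'
#' Reference values for the marginal distribution of XRF analytical assay
#' error in an urban multi-metal soil survey: per-metal mean, standard
#' deviation, range (ppm), and the three-parameter log-normal offset
#' `delta` (the error plus the offset is log-normally distributed).
#' Used as the planted truth of the synthetic survey generator.
#'
#' @return A tibble with columns `metal`, `mean_ppm`, `sd_ppm`, `min_ppm`,
#'   `max_ppm`, `delta_ppm`, and derived transformed-scale intercept
#'   `alpha` and slope `beta` (moment-matched so that
#'   `log(error + delta)` has the stated mean and SD).
#' @export
default_metal_params <- function() {
  path <- system.file("extdata", "metal_error_params.csv", package = "geoassay")
  p <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  m_shift <- p$mean_ppm + p$delta_ppm
  stopifnot(all(m_shift > 0))
  # moment matching for a log-normal shifted variable:
  # sdlog^2 = log(1 + cv^2), meanlog = log(m) - sdlog^2 / 2
  b2 <- log(1 + (p$sd_ppm / m_shift)^2)
  p$beta <- sqrt(b2)
  p$alpha <- log(m_shift) - b2 / 2
  p
}

#' Default planted factor loadings
#'
#' A 15-metal by 4-factor varimax-style simple-structure loading matrix
#' typical of the correlation structure among trace-metal assay errors
#' (four dimensions: an urban/traffic group, a fertilizer group, a
#' treatment-chemical group As/Pb/Zn, and a geogenic Mo/Zr pair).
#'
#' @return A numeric 15 x 4 matrix with metal row names.
#' @export
default_loadings <- function() {
  path <- system.file("extdata", "metal_error_loadings.csv", package = "geoassay")
  l <- read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(l[, c("F1", "F2", "F3", "F4")])
  rownames(m) <- l$metal
  m
}

#' Configure the synthetic survey landscape
#'
#' Bundles every parameter of the synthetic point-sample survey generator:
#' the planted factor-loading structure of the 15 metal error variables,
#' their three-parameter log-normal marginals, the SAR autocorrelation of
#' tract-level factor scores, and the coupling of assay values to assay
#' errors. Defaults emulate a ~3300-sample, 57-tract urban survey.
#'
#' @param metals Character vector of metal labels (default: the 15-metal
#'   reference set).
#' @param loadings 15 x 4 factor loading matrix (rows = metals).
#' @param uniqueness Per-metal unique variance; defaults to
#'   `1 - rowSums(loadings^2)` so communality + uniqueness = 1.
#' @param factor_rho Length-4 SAR autocorrelation parameter for the
#'   tract-level factor scores; default `c(0.264, 0.435, 0.527, 0.484)`.
#' @param delta,alpha,beta Per-metal log-normal offset (ppm) and
#'   transformed-scale intercept/slope; defaults from
#'   [default_metal_params()].
#' @param samples_per_tract Either a single number, interpreted as the
#'   mean of a truncated (minimum 5) Poisson draw of per-tract counts, or
#'   a vector of exact per-tract counts. Default 58 (about 3300 samples
#'   over 57 tracts).
#' @param value_coupling Slope linking the log assay value to the
#'   transformed (log-scale) assay error; positive, default 0.5.
#' @param value_noise_sd SD of independent log-scale noise on assay
#'   values, default 0.25.
#' @param on_nonpositive `"regenerate"` (redraw the unique noise of any
#'   sample whose back-transformed error is non-positive, the default) or
#'   `"fail"`.
#' @param seed Master integer seed; each stochastic stage of the generator
#'   consumes a derived substream.
#' @return An object of class `landscape_config` (a validated list).
#' @export
landscape_config <- function(metals = NULL,
                             loadings = NULL,
                             uniqueness = NULL,
                             factor_rho = c(0.264, 0.435, 0.527, 0.484),
                             delta = NULL, alpha = NULL, beta = NULL,
                             samples_per_tract = 58,
                             value_coupling = 0.5,
                             value_noise_sd = 0.25,
                             on_nonpositive = c("regenerate", "fail"),
                             seed = 1L) {
  params <- default_metal_params()
  if (is.null(metals)) metals <- params$metal
  if (is.null(loadings) || is.null(delta) || is.null(alpha) || is.null(beta)) {
    unknown <- setdiff(metals, params$metal)
    if (length(unknown) > 0) {
      abort(paste0(
        "unknown metal label(s) for the default parameterization: ",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  if (is.null(loadings)) loadings <- default_loadings()[metals, , drop = FALSE]
  loadings <- as.matrix(loadings)
  if (nrow(loadings) != length(metals)) {
    abort("`loadings` must have one row per metal")
  }
  rownames(loadings) <- metals
  communality <- rowSums(loadings^2)
  if (is.null(uniqueness)) uniqueness <- 1 - communality
  if (any(communality + uniqueness - 1 > 1e-9) || any(uniqueness < -1e-9)) {
    abort("communality + uniqueness must equal 1 for every metal")
  }
  uniqueness <- pmax(uniqueness, 0)
  if (any(abs(factor_rho) >= 1)) abort("|factor_rho| must be < 1")
  if (length(factor_rho) != ncol(loadings)) {
    abort("`factor_rho` needs one entry per factor")
  }
  idx <- match(metals, params$metal)
  if (is.null(delta)) delta <- params$delta_ppm[idx]
  if (is.null(alpha)) alpha <- params$alpha[idx]
  if (is.null(beta)) beta <- params$beta[idx]
  if (anyNA(delta) || anyNA(alpha) || anyNA(beta)) {
    abort("unknown metal label: delta/alpha/beta must be supplied for non-default metals")
  }
  if (any(beta <= 0)) abort("`beta` must be positive for every metal")
  if (value_coupling < 0) abort("`value_coupling` must be non-negative")
  structure(
    list(
      metals = metals, loadings = loadings, uniqueness = uniqueness,
      factor_rho = factor_rho,
      delta = setNames(delta, metals),
      alpha = setNames(alpha, metals),
      beta = setNames(beta, metals),
      samples_per_tract = samples_per_tract,
      value_coupling = value_coupling,
      value_noise_sd = value_noise_sd,
      on_nonpositive = match.arg(on_nonpositive),
      seed = as.integer(seed)
    ),
    class = "landscape_config"
  )
}

#' @export
print.landscape_config <- function(x, ...) {
  cat(sprintf(
    "<landscape_config> %d metals, %d factors, rho = (%s), seed = %d\n",
    length(x$metals), ncol(x$loadings),
    paste(format(x$factor_rho), collapse = ", "), x$seed
  ))
  invisible(x)
}
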