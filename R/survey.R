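#' Generate a synthetic point-sample survey
#'
#' Simulates a multi-metal soil survey over a tract tessellation with the
#' statistical structure the downstream analysis assumes:
#' tract-level factor scores follow a zero-mean simultaneous
#' autoregressive (SAR) process per factor (`score = rho W score + noise`
#' with row-standardized contiguity weights `W`, rescaled to unit
#' variance); each sample's transformed log-error for metal m is
#' `alpha_m + beta_m * (loadings_m . scores(tract) + unique noise)`; the
#' assay error back-transforms as `-delta_m + exp(transformed)`; and the
#' assay value is positively coupled to the error on the log scale.
#' Deterministic given `config$seed`.
#'
#' @param tess A [make_tessellation()] tessellation.
#' @param config A [landscape_config()].
#' @return A tibble of class `sample_table` with columns `sample_id`,
#'   `x`, `y`, `tract_id`, and `<metal>_err` / `<metal>_val` pairs (ppm).
#' @export
generate_survey <- function(tess, config = landscape_config()) {
  stopifnot(inherits(tess, "tessellation"), inherits(config, "landscape_config"))
  n_tracts <- tess$n_tracts
  k <- ncol(config$loadings)
  w <- spatial_weights(tess, style = "row")

  # per-tract sample counts
  counts <- with_seed(substream_seed(config$seed, "counts"), {
    spt <- config$samples_per_tract
    if (length(spt) == 1L) {
      pmax(5L, rpois(n_tracts, spt))
    } else {
      if (length(spt) != n_tracts) abort("per-tract counts must match the number of tracts")
      as.integer(spt)
    }
  })

  # tract-level SAR factor scores, standardized to unit variance
  scores <- with_seed(substream_seed(config$seed, "scores"), {
    vapply(seq_len(k), function(j) {
      a <- diag(n_tracts) - config$factor_rho[j] * w$w
      f <- solve(a, rnorm(n_tracts))
      as.vector(scale(f))
    }, numeric(n_tracts))
  })

  n <- sum(counts)
  tract_of <- rep(seq_len(n_tracts), counts)
  common <- scores[tract_of, , drop = FALSE] %*% t(config$loadings)  # n x metals

  m <- length(config$metals)
  latent <- with_seed(substream_seed(config$seed, "noise"), {
    lat <- common + matrix(rnorm(n * m), n, m) %*% diag(sqrt(config$uniqueness))
    for (j in seq_len(m)) {
      e_j <- -config$delta[j] + exp(config$alpha[j] + config$beta[j] * lat[, j])
      bad <- which(e_j <= 0)
      tries <- 0L
      while (length(bad) > 0 && config$on_nonpositive == "regenerate" && tries < 100L) {
        lat[bad, j] <- common[bad, j] +
          rnorm(length(bad), sd = sqrt(config$uniqueness[j]))
        e_j[bad] <- -config$delta[j] + exp(config$alpha[j] + config$beta[j] * lat[bad, j])
        bad <- bad[e_j[bad] <= 0]
        tries <- tries + 1L
      }
      if (length(bad) > 0) {
        abort(sprintf("non-positive assay error generated for %s (%d samples)",
                      config$metals[j], length(bad)))
      }
    }
    lat
  })
  err <- sweep(exp(sweep(sweep(latent, 2, config$beta, `*`), 2, config$alpha, `+`)),
               2, config$delta, `-`)

  # assay values: positively coupled to the transformed error plus noise,
  # anchored at a metal-specific baseline magnitude
  baseline <- log(pmax(8 * default_metal_params()$mean_ppm[
    match(config$metals, default_metal_params()$metal)], 1))
  baseline[is.na(baseline)] <- log(100)
  vals <- with_seed(substream_seed(config$seed, "values"), {
    noise <- matrix(rnorm(n * m, sd = config$value_noise_sd), n, m)
    logv <- sweep(config$value_coupling * sweep(latent, 2, config$beta, `*`) + noise,
                  2, baseline, `+`)
    exp(logv)
  })

  xy <- with_seed(substream_seed(config$seed, "placement"), {
    tr <- tess$tracts[tract_of, ]
    tibble(
      x = runif(n, tr$xmin, tr$xmax),
      y = runif(n, tr$ymin, tr$ymax)
    )
  })

  out <- tibble(sample_id = seq_len(n), x = xy$x, y = xy$y, tract_id = tract_of)
  for (j in seq_along(config$metals)) {
    out[[paste0(config$metals[j], "_err")]] <- err[, j]
    out[[paste0(config$metals[j], "_val")]] <- vals[, j]
  }
  class(out) <- c("sample_table", class(out))
  attr(out, "metals") <- config$metals
  out
}

#' Metal labels of a sample table
#'
#' @param samples A sample table (tibble with `<metal>_err` columns).
#' @return Character vector of metal labels.
#' @export
survey_metals <- function(samples) {
  m <- attr(samples, "metals")
  if (!is.null(m)) return(m)
  sub("_err$", "", grep("_err$", names(samples), value = TRUE))
}

#' Count samples exceeding per-metal thresholds
#'
#' Counts, per metal, how many assay values strictly exceed a maximum
#' permissible level or other threshold.
#'
#' @param samples A sample table.
#' @param thresholds Named numeric vector of per-metal thresholds (ppm);
#'   names must be metal labels present in `samples`.
#' @return A tibble with columns `metal`, `threshold`, `n_exceeding`.
#' @export
exceedance_counts <- function(samples, thresholds) {
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds)))) {
    abort("`thresholds` must be a named per-metal vector")
  }
  if (any(thresholds <= 0)) abort("thresholds must be positive")
  metals <- survey_metals(samples)
  unknown <- setdiff(names(thresholds), metals)
  if (length(unknown) > 0) {
    abort(paste0("unknown metal label(s): ", paste(unknown, collapse = ", ")))
  }
  tibble(
    metal = names(thresholds),
    threshold = unname(thresholds),
    n_exceeding = unname(vapply(names(thresholds), function(mt) {
      sum(samples[[paste0(mt, "_val")]] > thresholds[[mt]])
    }, integer(1)))
  )
}

#' Read and write sample-table CSV files
#'
#' `write_survey()` writes one row per sample with columns
#' `sample_id,x,y,tract_id,<metal>_err,<metal>_val`; `read_survey()`
#' reads that schema back, validating it and rejecting non-positive
#' assay errors with the offending row numbers.
#'
#' @param samples A sample table.
#' @param path CSV file path.
#' @return `read_survey()` returns a `sample_table` tibble;
#'   `write_survey()` returns `path` invisibly.
#' @export
write_survey <- function(samples, path) {
  write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "x", "y", "tract_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("survey file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  err_cols <- grep("_err$", names(df), value = TRUE)
  val_cols <- grep("_val$", names(df), value = TRUE)
  if (length(err_cols) == 0) abort("survey file has no `<metal>_err` columns")
  if (!setequal(sub("_err$", "", err_cols), sub("_val$", "", val_cols))) {
    abort("`<metal>_err` and `<metal>_val` columns do not pair up")
  }
  for (col in err_cols) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf("non-positive assay error in column %s at row(s): %s",
                    col, paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  out <- as_tibble(df)
  class(out) <- c("sample_table", class(out))
  attr(out, "metals") <- sub("_err$", "", err_cols)
  out
}
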