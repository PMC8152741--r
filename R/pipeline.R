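#' Configure a full error-geography experiment
#'
#' One configuration object driving the end-to-end pipeline: synthetic
#' survey generation, per-metal rankit log-normal fits, the error-source
#' simulation experiments, factor-dimension stability summaries, spatial
#' index propagation, SAR variance accounting, and uncertainty-aware
#' classification.
#'
#' @param rows,cols Tessellation grid dimensions (default 3 x 19 = 57
#'   tracts).
#' @param landscape A [landscape_config()]; its seed is overridden by
#'   `seed`.
#' @param sources Error sources to simulate, a subset of
#'   `c("analytical", "sampling", "gamma", "beta", "uniform",
#'   "mixture")`.
#' @param n_draws Replications per source (>= 2).
#' @param k_factors Number of error dimensions (default 4).
#' @param k_classes Classes for the uncertainty-aware maps (default 5).
#' @param threshold Prominent-loading threshold (default 0.49).
#' @param classify_metals Metals to classify; default the first three.
#' @param seed Master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(rows = 3, cols = 19,
                              landscape = landscape_config(),
                              sources = c("analytical", "sampling", "gamma",
                                          "beta", "uniform", "mixture"),
                              n_draws = 200, k_factors = 4, k_classes = 5,
                              threshold = 0.49,
                              classify_metals = NULL,
                              seed = 1L) {
  known <- c("analytical", "sampling", "gamma", "beta", "uniform", "mixture")
  if (length(sources) > 0 && !all(sources %in% known)) {
    abort(paste0("unknown source(s): ", paste(setdiff(sources, known), collapse = ", ")))
  }
  if (length(sources) > 0) n_draws <- assert_scalar_count(n_draws, "n_draws")
  if (length(sources) > 0 && n_draws < 2) abort("n_draws must be >= 2")
  landscape$seed <- as.integer(seed)
  structure(
    list(
      rows = rows, cols = cols, landscape = landscape, sources = sources,
      n_draws = n_draws, k_factors = k_factors, k_classes = k_classes,
      threshold = threshold, classify_metals = classify_metals,
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Run the full error-geography experiment
#'
#' Executes every stage in order on one synthetic survey: generation,
#' per-metal three-parameter log-normal fits with diagnostics, the
#' reference varimax factor solution of the tract-averaged transformed
#' errors, replicated simulations per error source with aligned-loading
#' stability summaries, propagation to Moran/Geary indices, SAR variance
#' estimates and a variance decomposition, and uncertainty-aware
#' classifications. Fully reproducible given the config seed.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_report`: list with `tables`
#'   (named tibbles: `fits`, `reference_loadings`,
#'   `loading_stability`, `spatial_indices`, `sar_variance`,
#'   `variance_decomposition`, `dimension_comparison`,
#'   `classification`), `objects` (fitted objects, solutions, classed
#'   maps, the survey and tessellation), `config`, and `timings`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }

  tess <- make_tessellation(config$rows, config$cols)
  survey <- generate_survey(tess, config$landscape)
  tick("generate")

  fits <- fit_assay_errors(survey)
  fits_table <- fits[setdiff(names(fits), "fit")]
  delta <- setNames(fits$delta_hat, fits$metal)
  tick("fit")

  tract_mat <- tract_average(survey, log = TRUE, delta = delta)
  reference <- factor_solution(tract_mat, k = config$k_factors)
  ref_loadings_tbl <- tidy(reference)
  w_bin <- spatial_weights(tess, style = "binary")
  w_row <- spatial_weights(tess, style = "row")

  mat0 <- as_value_matrix(tract_mat)
  mu0 <- colMeans(mat0)
  sd0 <- apply(mat0, 2, sd)
  score_of <- function(m) {
    z <- sweep(sweep(m, 2, mu0, `-`), 2, sd0, `/`)
    z %*% solve(reference$cor, reference$loadings)
  }
  scores0 <- score_of(mat0)
  score_sd0 <- apply(scores0, 2, sd)
  scores0_std <- sweep(scores0, 2, score_sd0, `/`)
  tick("reference")

  orig_idx <- propagate_to_indices(list(scores0_std, scores0_std), w_bin) %>%
    mutate(source = "original", mc_sd = NA_real_, gr_sd = NA_real_,
           n_replications = NA_integer_)
  sar_rows <- list(sar_dataset_rows("original", scores0_std, score_sd0 * 0 + 1, w_row))
  idx_rows <- list(orig_idx)
  stab_rows <- list()
  summaries <- list()
  frob <- list()

  for (s_i in seq_along(config$sources)) {
    src <- config$sources[s_i]
    reps <- replicate_tract_errors(
      survey, fits, source = src, n_draws = config$n_draws,
      seed = substream_seed(config$seed, 700L + s_i)
    )
    sols <- lapply(reps, function(m) {
      align_factors(reference, factor_solution(m, k = config$k_factors))
    })
    summ <- replication_summary(sols, reference, threshold = config$threshold)
    summaries[[src]] <- summ
    stab_rows[[src]] <- tidy(summ) %>% mutate(source = src)
    frob[[src]] <- median(vapply(sols, function(s) {
      sqrt(sum((s$loadings - reference$loadings)^2))
    }, numeric(1)))

    score_reps <- lapply(reps, function(m) {
      sweep(score_of(m), 2, score_sd0, `/`)
    })
    idx_rows[[src]] <- propagate_to_indices(score_reps, w_bin) %>%
      mutate(source = src)

    mean_field <- Reduce(`+`, reps) / length(reps)
    scores_src <- sweep(score_of(mean_field), 2, score_sd0, `/`)
    sar_rows[[src]] <- sar_dataset_rows(src, scores_src, NULL, w_row)
  }
  tick("sources")

  sar_tbl <- bind_rows(sar_rows)
  vdec <- if (all(c("analytical", "sampling") %in% config$sources)) {
    purrr::map_dfr(seq_len(config$k_factors), function(j) {
      fac <- paste0("F", j)
      tot <- sar_tbl$sigma2[sar_tbl$source == "original" & sar_tbl$factor == fac]
      comp <- c(
        analytical = tot - sar_tbl$sigma2[sar_tbl$source == "analytical" & sar_tbl$factor == fac],
        sampling = tot - sar_tbl$sigma2[sar_tbl$source == "sampling" & sar_tbl$factor == fac]
      )
      variance_decomposition(tot, pmax(comp, 0)) %>% mutate(factor = fac)
    })
  } else {
    tibble()
  }

  comparison <- dimension_comparison(reference, summaries, config$threshold)
  tick("spatial")

  classify_metals <- config$classify_metals
  if (is.null(classify_metals)) classify_metals <- utils::head(fits$metal, 3)
  class_objects <- list()
  class_rows <- list()
  an_sd <- resamp_sd <- NULL
  if ("analytical" %in% config$sources || "sampling" %in% config$sources) {
    # per-tract uncertainty: SD of the tract average across replications
    unc <- lapply(intersect(c("analytical", "sampling"), config$sources), function(src) {
      reps <- replicate_tract_errors(
        survey, fits, source = src, n_draws = max(50, min(config$n_draws, 200)),
        seed = substream_seed(config$seed, 650L + match(src, c("analytical", "sampling")))
      )
      arr <- array(unlist(reps), dim = c(dim(reps[[1]]), length(reps)))
      sdm <- apply(arr, c(1, 2), sd)
      dimnames(sdm) <- dimnames(reps[[1]])
      sdm
    })
    names(unc) <- intersect(c("analytical", "sampling"), config$sources)
    for (mt in classify_metals) {
      vals <- mat0[, mt]
      for (src in names(unc)) {
        cm <- optimize_breaks(vals, unc[[src]][, mt], k = config$k_classes,
                              criterion = "combined")
        key <- paste(mt, src, sep = "_")
        class_objects[[key]] <- cm
        class_rows[[key]] <- tibble(
          metal = mt, error_source = src,
          tract_id = as.integer(rownames(mat0)),
          value = vals, class = cm$assignment
        )
      }
      class_objects[[paste0(mt, "_tertile")]] <- quantile_breaks(vals, k = 3)
    }
  }
  tick("classify")

  structure(
    list(
      tables = list(
        fits = fits_table,
        reference_loadings = ref_loadings_tbl,
        reference_pct_variance = tibble(
          factor = paste0("F", seq_len(config$k_factors)),
          pct_variance = reference$pct_variance
        ),
        loading_stability = bind_rows(stab_rows),
        spatial_indices = bind_rows(idx_rows),
        sar_variance = sar_tbl,
        variance_decomposition = vdec,
        dimension_comparison = comparison,
        classification = bind_rows(class_rows),
        loading_distance = tibble(
          source = names(frob),
          median_frobenius = unlist(frob)
        )
      ),
      objects = list(
        tessellation = tess, survey = survey, fits = fits,
        reference = reference, summaries = summaries,
        classed_maps = class_objects
      ),
      config = config,
      timings = tibble(stage = names(timings), seconds = unlist(timings))
    ),
    class = "experiment_report"
  )
}

# per-dataset SAR rows of the variance table: one row per factor with
# the naive variance, rho, adjusted variance and Shapiro-Wilk p.
# sigma2 is reported on the scale where the original scores have unit
# variance, and the adjusted variance is rescaled accordingly.
sar_dataset_rows <- function(source, scores, sigma2 = NULL, w_row) {
  k <- ncol(scores)
  purrr::map_dfr(seq_len(k), function(j) {
    f <- sar_fit(scores[, j], w_row)
    s2 <- if (!is.null(sigma2)) unname(sigma2[j]) else unname(var(scores[, j]))
    tibble(
      source = source, factor = paste0("F", j),
      sigma2 = s2,
      rho_hat = f$rho_hat,
      sigma2_adjusted = f$sigma2_adjusted * s2 / f$sigma2_hat,
      shapiro_wilk_p = f$shapiro_wilk_p
    )
  })
}

# cross-source dimension assignment comparison (which factor each metal
# loads on, per dataset, with the observed prominence threshold)
dimension_comparison <- function(reference, summaries, threshold) {
  ld <- reference$loadings
  is_max <- t(apply(abs(ld), 1, function(r) seq_along(r) == which.max(r)))
  prom <- is_max & abs(ld) >= threshold
  ref_dim <- apply(prom, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  out <- tibble(variable = rownames(ld), original = unname(ref_dim))
  for (src in names(summaries)) {
    out[[src]] <- summaries[[src]]$assignment$dimension
  }
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n  seed:", x$config$seed,
      "\n  sources:", paste(x$config$sources, collapse = ", "),
      "\n  tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

#' Write the report tables to CSV files
#'
#' @param report An [run_experiment()] report.
#' @param dir Output directory (created if absent).
#' @return Tibble of table names and file paths, invisibly.
#' @export
write_tables <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::imap(report$tables, function(tbl, nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(as.data.frame(tbl), p, row.names = FALSE)
    p
  })
  invisible(tibble(table = names(paths), path = unlist(paths)))
}
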