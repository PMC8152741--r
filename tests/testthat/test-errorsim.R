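test_that("the log-normal assumption regression reproduces the rankit fit", {
  withr::with_seed(4, {
    y <- -2 + exp(1 + 0.5 * rnorm(300))
    fit <- fit_three_param_lognormal(y)
    af <- fit_assumption_regression(y, "lognormal", fit$delta_hat)
    expect_equal(af$alpha_hat, fit$alpha_hat, tolerance = 1e-12)
    expect_equal(af$beta_hat, fit$beta_hat, tolerance = 1e-12)
    expect_equal(af$mse, fit$mse, tolerance = 1e-12)
    expect_equal(af$pseudo_r2, fit$r_squared, tolerance = 1e-12)
  })
})

test_that("data built on the beta covariate favour the beta assumption", {
  n <- 150
  x_beta <- specification_covariate("beta", 1:n, n)
  y <- -2 + exp(0.5 + 0.3 * x_beta)
  bf <- fit_assumption_regression(y, "beta", delta_hat = 2)
  lf <- fit_assumption_regression(y, "lognormal", delta_hat = 2)
  expect_equal(bf$pseudo_r2, 1, tolerance = 1e-9)
  expect_lt(lf$pseudo_r2, 1 - 1e-6)
})

test_that("on log-normal data the log-normal covariate usually wins", {
  withr::with_seed(14, {
    wins <- replicate(100, {
      y <- exp(0.5 * rnorm(200))
      ln <- fit_assumption_regression(y, "lognormal", 0.5)
      be <- fit_assumption_regression(y, "beta", 0.5)
      ln$pseudo_r2 >= be$pseudo_r2
    })
    expect_gte(mean(wins), 0.90)
  })
})

test_that("draws collapse to the fitted values when the MSE vanishes", {
  z <- blom_scores(60)
  y <- -1 + exp(0.8 + 0.3 * z)
  fit <- fit_three_param_lognormal(y)
  expect_lt(fit$mse, 1e-10)
  d <- draw_errors(fit, n_draws = 5, seed = 1)
  for (i in 1:5) {
    expect_equal(unname(d[i, ]), -fit$delta_hat + exp(fit$fitted),
                 tolerance = 1e-6)
  }
})

test_that("the empirical draw mean matches the log-normal closed form", {
  withr::with_seed(16, {
    y <- 2 + exp(1 + 0.5 * rnorm(40))
    fit <- fit_three_param_lognormal(y)
    d <- draw_errors(fit, n_draws = 1e5, seed = 2)
    i <- 7
    expected <- -fit$delta_hat + exp(fit$fitted[i] + fit$mse / 2)
    mc_se <- sd(d[, i]) / sqrt(nrow(d))
    expect_lt(abs(mean(d[, i]) - expected), 5 * mc_se)
  })
})

test_that("uniform-assumption draws are far tighter than log-normal draws", {
  fits <- test_fits()
  y <- test_survey()$As_err
  delta <- fits$delta_hat[fits$metal == "As"]
  ln <- draw_errors(fits$fit[[which(fits$metal == "As")]], n_draws = 100, seed = 3)
  un <- draw_errors(fit_assumption_regression(y, "uniform", delta),
                    n_draws = 100, seed = 3)
  sd_ratio <- apply(un, 2, sd) / apply(ln, 2, sd)
  expect_lt(median(sd_ratio), 0.75)
})

test_that("draws are reproducible given the seed", {
  y <- -1 + exp(0.5 + 0.4 * rnorm(50))
  fit <- fit_three_param_lognormal(y)
  expect_identical(draw_errors(fit, 10, seed = 5), draw_errors(fit, 10, seed = 5))
  af <- fit_assumption_regression(y, "uniform", fit$delta_hat)
  expect_identical(draw_errors(af, 10, seed = 5), draw_errors(af, 10, seed = 5))
})

test_that("tract-stratified bootstrap preserves the design", {
  sv <- tiny_survey(err = c(5, 1, 2, 3), tract = c(1L, 2L, 2L, 2L))
  bs <- bootstrap_resample(sv, seed = 1)
  expect_equal(bs$As_err[1], 5)                      # singleton tract repeats
  expect_equal(table(bs$tract_id), table(sv$tract_id))
  expect_true(all(bs$As_err[2:4] %in% c(1, 2, 3)))   # within-tract support
  expect_identical(bootstrap_resample(sv, seed = 9), bootstrap_resample(sv, seed = 9))
})

test_that("bootstrap tract means are unbiased for the sample tract mean", {
  withr::with_seed(31, {
    vals <- rnorm(40, 10, 3)
    sv <- tiny_survey(err = exp(vals / 10), tract = rep(1L, 40))
    reps <- replicate(4000, mean(bootstrap_resample(sv)$As_err))
    mc_se <- sd(sv$As_err) / sqrt(40) / sqrt(4000)
    expect_equal(mean(reps), mean(sv$As_err), tolerance = 5 * mc_se / mean(sv$As_err))
  })
})

test_that("a zero-MSE mixture reduces to a pure bootstrap of fitted values", {
  z <- blom_scores(30)
  y <- -1 + exp(1.2 + 0.3 * z)
  sv <- tiny_survey(err = y, tract = rep(1:3, each = 10))
  fit <- fit_three_param_lognormal(y)
  expect_lt(fit$mse, 1e-10)
  idx <- matrix(rep(seq_len(30), 4), 4, 30, byrow = TRUE)
  idx[2, ] <- rev(idx[2, ])
  mx <- mixture_draw(sv, fit, n_draws = 4, seed = 6, indices = idx)
  bt <- -fit$delta_hat + exp(fit$fitted)
  expect_equal(unname(mx[1, ]), bt, tolerance = 1e-6)
  expect_equal(unname(mx[2, ]), rev(bt), tolerance = 1e-6)
})

test_that("mixture draws carry at least the analytical-draw variance", {
  fits <- test_fits()
  sv <- test_survey()
  j <- which(fits$metal == "Rb")
  ln <- draw_errors(fits$fit[[j]], n_draws = 400, seed = 7)
  mx <- mixture_draw(sv, fits$fit[[j]], n_draws = 400, seed = 7)
  extra <- apply(mx, 2, var) - apply(ln, 2, var)
  expect_gt(median(extra), 0)
})

test_that("replicated tract fields have the right shape and determinism", {
  fits <- test_fits()
  sv <- test_survey()
  for (src in c("analytical", "sampling", "gamma", "beta", "uniform", "mixture")) {
    reps <- replicate_tract_errors(sv, fits, source = src, n_draws = 3, seed = 10)
    expect_length(reps, 3)
    expect_equal(dim(reps[[1]]), c(57, 15))
    expect_true(all(is.finite(reps[[1]])))
  }
  a <- replicate_tract_errors(sv, fits, "analytical", n_draws = 2, seed = 1)
  b <- replicate_tract_errors(sv, fits, "analytical", n_draws = 2, seed = 1)
  expect_identical(a, b)
})

test_that("resampling disperses tract means more than analytical error does", {
  fits <- test_fits()
  sv <- test_survey()
  an <- replicate_tract_errors(sv, fits, "analytical", n_draws = 60, seed = 12)
  bs <- replicate_tract_errors(sv, fits, "sampling", n_draws = 60, seed = 13)
  sd_of <- function(reps) {
    arr <- array(unlist(reps), dim = c(dim(reps[[1]]), length(reps)))
    apply(arr, c(1, 2), sd)
  }
  expect_gt(median(sd_of(bs) / sd_of(an)), 1)
})
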