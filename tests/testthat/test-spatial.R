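# independent double-loop oracle for the two indices
oracle_indices <- function(x, wm) {
  n <- length(x)
  z <- x - mean(x)
  s0 <- 0; num_mc <- 0; num_gr <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      s0 <- s0 + wm[i, j]
      num_mc <- num_mc + wm[i, j] * z[i] * z[j]
      num_gr <- num_gr + wm[i, j] * (x[i] - x[j])^2
    }
  }
  c(
    mc = (n / s0) * num_mc / sum(z^2),
    gr = ((n - 1) / (2 * s0)) * num_gr / sum(z^2)
  )
}

test_that("the 2x2 rook checkerboard gives MC = -1 and GR = 1.5 exactly", {
  tess <- make_tessellation(2, 2, contiguity = "rook")
  w <- spatial_weights(tess, "binary")
  x <- c(1, -1, -1, 1)  # alternating by grid position
  idx <- moran_geary(x, w)
  expect_equal(idx$mc, -1)
  expect_equal(idx$gr, 1.5)
})

test_that("MC and GR agree with the brute-force double sums", {
  withr::with_seed(30, {
    for (rep in 1:20) {
      w <- random_weights()
      x <- rnorm(w$n)
      idx <- moran_geary(x, w)
      oc <- oracle_indices(x, w$w)
      expect_equal(idx$mc, unname(oc["mc"]), tolerance = 1e-12)
      expect_equal(idx$gr, unname(oc["gr"]), tolerance = 1e-12)
      expect_gte(idx$mc_max, idx$mc - 1e-10)
      expect_gte(idx$gr, idx$gr_min - 1e-10)
      expect_gte(idx$gr_min, -1e-10)
    }
  })
})

test_that("randomization SEs track permutation standard deviations", {
  withr::with_seed(33, {
    w <- spatial_weights(make_tessellation(5, 8), "binary")
    x <- rnorm(w$n)
    idx <- moran_geary(x, w)
    perms <- replicate(4000, {
      xp <- sample(x)
      i <- moran_geary(xp, w)
      c(i$mc, i$gr)
    })
    expect_equal(idx$se_mc_randomization, sd(perms[1, ]), tolerance = 0.08)
    expect_equal(idx$se_gr_randomization, sd(perms[2, ]), tolerance = 0.08)
  })
})

test_that("degenerate spatial inputs are rejected", {
  w <- spatial_weights(make_tessellation(2, 2), "binary")
  expect_error(moran_geary(rep(1, 4), w), "constant")
  expect_error(moran_geary(rnorm(5), w), "length")
  expect_error(sar_fit(rnorm(4), w), "row-standardized")
})

test_that("SAR fitting finds no autocorrelation in independent noise", {
  tess <- make_tessellation(15, 15)
  w <- spatial_weights(tess, "row")
  lam <- weight_eigenvalues(w)
  withr::with_seed(40, {
    rhos <- replicate(100, sar_fit(rnorm(225), w, eigenvalues = lam)$rho_hat)
    # centred at zero, with the sampling spread this lattice size implies
    expect_lt(abs(mean(rhos)), 0.05)
    expect_gte(mean(abs(rhos) < 0.25), 0.9)
    # adjusted and naive variances agree on average when rho is null
    f <- sar_fit(rnorm(225), w, eigenvalues = lam)
    expect_equal(f$sigma2_adjusted / f$sigma2_hat, 1, tolerance = 0.15)
  })
})

test_that("SAR fitting recovers a planted rho of 0.4 on a 20x20 lattice", {
  tess <- make_tessellation(20, 20)
  w <- spatial_weights(tess, "row")
  a_inv <- solve(diag(400) - 0.4 * w$w)
  withr::with_seed(41, {
    rhos <- replicate(50, {
      x <- as.vector(a_inv %*% rnorm(400))
      sar_fit(x, w)$rho_hat
    })
    expect_gte(mean(rhos), 0.33)
    expect_lte(mean(rhos), 0.47)
  })
})

test_that("variance inflation grows monotonically with rho", {
  tess <- make_tessellation(15, 15)
  w <- spatial_weights(tess, "row")
  withr::with_seed(42, {
    med_ratio <- vapply(c(0, 0.2, 0.4, 0.6), function(rho) {
      a_inv <- solve(diag(225) - rho * w$w)
      median(replicate(50, {
        f <- sar_fit(as.vector(a_inv %*% rnorm(225)), w)
        f$sigma2_hat / f$sigma2_adjusted
      }))
    }, numeric(1))
    expect_true(all(diff(med_ratio) > 0))
  })
})

test_that("the adjusted variance stays below the naive one for positive rho", {
  tess <- make_tessellation(10, 10)
  w <- spatial_weights(tess, "row")
  a_inv <- solve(diag(100) - 0.5 * w$w)
  withr::with_seed(43, {
    for (i in 1:5) {
      f <- sar_fit(as.vector(a_inv %*% rnorm(100)), w)
      if (f$rho_hat > 0) expect_lte(f$sigma2_adjusted, f$sigma2_hat)
    }
  })
})

test_that("variance decomposition follows the subtraction arithmetic", {
  d <- variance_decomposition(1, c(analytical = 0.002, sampling = 0.122))
  expect_equal(d$variance[d$component == "residual"], 0.876)
  expect_equal(sum(d$variance), 1)

  empty <- variance_decomposition(1)
  expect_equal(empty$variance, 1)
  expect_equal(empty$component, "residual")

  expect_warning(
    over <- variance_decomposition(1, c(a = 0.7, b = 0.6)),
    "negative residual"
  )
  expect_lt(over$variance[over$component == "residual"], 0)
  expect_error(variance_decomposition(-1), "positive")
  expect_error(variance_decomposition(1, c(0.1)), "named")
})

test_that("index propagation summarizes replications per factor", {
  w <- spatial_weights(make_tessellation(4, 5), "binary")
  withr::with_seed(44, {
    base <- matrix(rnorm(40), 20, 2)
    same <- propagate_to_indices(list(base, base, base), w)
    expect_equal(same$mc_sd, c(0, 0))
    expect_equal(same$gr_sd, c(0, 0))
    reps <- lapply(1:5, function(i) base + matrix(rnorm(40, sd = 0.3), 20, 2))
    out <- propagate_to_indices(reps, w)
    expect_equal(nrow(out), 2)
    expect_true(all(out$mc_sd > 0))
    expect_error(propagate_to_indices(list(base), w), "at least 2")
  })
})
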