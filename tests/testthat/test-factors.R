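test_that("tract averaging equals brute-force group means", {
  sv <- tiny_survey(err = c(2, 4), tract = c(1L, 1L))
  expect_equal(tract_average(sv)$As, 3)
  sv1 <- tiny_survey(err = c(5, 7, 9), tract = 1:3)
  expect_equal(tract_average(sv1)$As, c(5, 7, 9))

  withr::with_seed(20, {
    sv2 <- tiny_survey(err = runif(100, 1, 10), tract = sample(1:7, 100, TRUE))
    got <- tract_average(sv2)
    oracle <- tapply(sv2$As_err, sv2$tract_id, mean)
    expect_equal(got$As, as.vector(oracle[as.character(got$tract_id)]),
                 tolerance = 1e-12)
    # log-shift transform averages log(y + delta)
    got_log <- tract_average(sv2, log = TRUE, delta = c(As = 2))
    oracle_log <- tapply(log(sv2$As_err + 2), sv2$tract_id, mean)
    expect_equal(got_log$As, as.vector(oracle_log[as.character(got_log$tract_id)]),
                 tolerance = 1e-12)
  })
  expect_error(tract_average(sv, log = TRUE), "delta")
})

# exactly whitened scores: empirical mean 0, identity covariance
whitened_scores <- function(n, k) {
  s <- svd(scale(matrix(rnorm(n * k), n, k), scale = FALSE))
  sqrt(n - 1) * s$u
}

test_that("varimax recovers planted axes mixed by a 45-degree rotation", {
  withr::with_seed(23, {
    l0 <- rbind(
      cbind(c(0.97, 0.94, 0.955), 0),
      cbind(0, c(0.96, 0.945, 0.95))
    )
    theta <- pi / 4
    mix <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    s <- whitened_scores(400, 8)
    # exact factor-model covariance: common part mixed by 45 degrees,
    # plus orthogonal unique parts filling each variable to unit variance
    uniq <- sqrt(1 - rowSums(l0^2))
    x <- s[, 1:2] %*% t(l0 %*% mix) + s[, 3:8] %*% diag(uniq)
    sol <- factor_solution(x, k = 2)
    aligned <- align_factors(l0, sol$loadings)
    expect_true(all(diag(tucker_congruence(l0, aligned)) >= 0.999))
  })
})

test_that("data with perfect simple structure are a varimax fixed point", {
  withr::with_seed(24, {
    l0 <- rbind(
      cbind(c(0.95, 0.9, 0.92, 0.88), 0),
      cbind(0, c(0.9, 0.93, 0.91, 0.89))
    )
    s <- whitened_scores(300, 10)
    uniq <- sqrt(1 - rowSums(l0^2))
    x <- s[, 1:2] %*% t(l0) + s[, 3:10] %*% diag(uniq)
    sol <- factor_solution(x, k = 2)
    aligned <- align_factors(l0, sol$loadings)
    # block pattern preserved: cross-loadings stay near zero
    expect_lt(max(abs(aligned[1:4, 2])), 1e-3)
    expect_lt(max(abs(aligned[5:8, 1])), 1e-3)
    expect_true(all(diag(tucker_congruence(l0, aligned)) >= 0.999))
  })
})

test_that("rotation preserves total communality", {
  tm <- test_tract_matrix()
  sol <- factor_solution(tm, k = 4)
  ev <- eigen(sol$cor, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(sol$communalities), sum(ev[1:4]), tolerance = 1e-9)
  expect_true(all(abs(sol$loadings) <= 1 + 1e-9))
  expect_true(all(sol$pct_variance > 0))
  expect_lte(sum(sol$pct_variance), 100 + 1e-9)
  expect_true(all(diff(sol$pct_variance) <= 0))  # ordered descending
})

test_that("alignment undoes permutations and sign flips exactly", {
  tm <- test_tract_matrix()
  ref <- factor_solution(tm, k = 4)
  shuffled <- ref$loadings[, c(3, 1, 4, 2)]
  shuffled[, 2] <- -shuffled[, 2]
  restored <- align_factors(ref$loadings, shuffled)
  expect_equal(restored, ref$loadings, ignore_attr = TRUE)

  # idempotence, and percentage-of-variance multiset invariance
  sol2 <- withr::with_seed(25, factor_solution(tm[, c(1, sample(2:16))], k = 4))
  a1 <- align_factors(ref, sol2)
  a2 <- align_factors(ref, a1)
  expect_equal(a1$loadings, a2$loadings)
  expect_equal(sort(a1$pct_variance), sort(sol2$pct_variance))

  # small perturbations keep high congruence
  noisy <- ref$loadings + matrix(rnorm(60, sd = 0.02), 15, 4)
  expect_true(all(diag(tucker_congruence(ref$loadings,
                                         align_factors(ref$loadings, noisy))) >= 0.99))
  expect_error(align_factors(ref$loadings, ref$loadings[, 1:2]), "dimension")
})

test_that("replication summaries average, flag and assign correctly", {
  tm <- test_tract_matrix()
  ref <- factor_solution(tm, k = 4)
  identical_sols <- list(ref, ref, ref)
  summ <- replication_summary(identical_sols, ref)
  expect_true(all(summ$sd_loadings == 0))
  expect_equal(summ$mean_loadings, ref$loadings)
  # at most one prominent factor per metal
  expect_true(all(rowSums(summ$prominent) <= 1))
  # Mo and Zr co-assigned to the planted geogenic dimension
  a <- summ$assignment
  expect_equal(unname(a$dimension[a$variable == "Mo"]),
               unname(a$dimension[a$variable == "Zr"]))

  high <- replication_summary(identical_sols, ref, threshold = 1.5)
  expect_true(all(is.na(high$assignment$dimension)))
  expect_error(replication_summary(list(ref), ref), "at least 2")
})

test_that("factor scores reproduce structure on the fitting data", {
  tm <- test_tract_matrix()
  sol <- factor_solution(tm, k = 4)
  sc <- factor_scores(sol, tm)
  expect_equal(dim(sc), c(57, 4))
  # scores correlate strongly with the dimension's top-loading metal
  top <- rownames(sol$loadings)[which.max(abs(sol$loadings[, 1]))]
  m <- as.matrix(tm[, -1])
  expect_gt(abs(cor(sc[, 1], m[, top])), 0.8)
})
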