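test_that("confidence intervals follow the normal closed form and nest", {
  iv <- tract_intervals(10, 1)
  expect_equal(iv$lo, 8.04, tolerance = 1e-3)
  expect_equal(iv$hi, 11.96, tolerance = 1e-3)
  deg <- tract_intervals(c(3, 5), c(0, 0))
  expect_equal(deg$lo, deg$hi)
  wide <- tract_intervals(1:5, rep(1, 5), level = 0.95)
  narrow <- tract_intervals(1:5, rep(1, 5), level = 0.50)
  expect_true(all(narrow$lo > wide$lo & narrow$hi < wide$hi))
  expect_error(tract_intervals(1, 1, level = 1.2), "level")
  expect_error(tract_intervals(1, -1), "non-negative")
})

test_that("break separability scores overlap as designed", {
  iv <- tibble::tibble(value = c(1, 10), lo = c(0.9, 9.9), hi = c(1.1, 10.1))
  expect_equal(break_separability(iv, 1), 1)          # disjoint
  iv2 <- tibble::tibble(value = c(5, 5), lo = c(4, 4), hi = c(6, 6))
  expect_equal(break_separability(iv2, 1), 0)         # identical
  iv3 <- tibble::tibble(value = c(1, 2), lo = c(0, 1), hi = c(2, 3))
  expect_equal(break_separability(iv3, 1), 2 / 3)     # 1 - overlap/union
  expect_error(break_separability(iv, 2), "between two observations")
})

test_that("separability is invariant under joint affine rescaling", {
  withr::with_seed(50, {
    v <- sort(runif(15)); e <- runif(15, 0.01, 0.2)
    cm1 <- optimize_breaks(v, e, k = 3)
    cm2 <- optimize_breaks(5 + 7 * v, 7 * e, k = 3)
    expect_equal(cm1$separability, cm2$separability, tolerance = 1e-10)
    expect_equal(cm1$assignment, cm2$assignment)
  })
})

test_that("two well-separated clusters split at the gap with objective 1", {
  v <- c(1, 1.1, 1.2, 9, 9.1, 9.2)
  cm <- optimize_breaks(v, rep(0.05, 6), k = 2)
  expect_gt(cm$breaks, 1.2)
  expect_lt(cm$breaks, 9)
  expect_equal(cm$objective, 1)
  expect_equal(cm$assignment, c(1, 1, 1, 2, 2, 2))
})

test_that("dynamic programming equals exhaustive search on small instances", {
  brute <- function(v, e, k, criterion, w = 0.5) {
    n <- length(v)
    iv <- tract_intervals(sort(v), e[order(v)])
    sep <- vapply(seq_len(n - 1), function(i) break_separability(iv, i), numeric(1))
    sv <- sort(v)
    sst <- sum((sv - mean(sv))^2)
    best <- -Inf
    for (cut_set in asplit(utils::combn(n - 1, k - 1), 2)) {
      bounds <- c(0, cut_set, n)
      ssw <- sum(vapply(seq_len(k), function(c) {
        seg <- sv[(bounds[c] + 1):bounds[c + 1]]
        sum((seg - mean(seg))^2)
      }, numeric(1)))
      obj <- if (criterion == "separability") {
        mean(sep[cut_set])
      } else {
        w * (1 - ssw / sst) + (1 - w) * mean(sep[cut_set])
      }
      best <- max(best, obj)
    }
    best
  }
  withr::with_seed(51, {
    for (rep in 1:12) {
      n <- sample(6:12, 1)
      k <- sample(2:4, 1)
      v <- runif(n)
      e <- runif(n, 0.01, 0.3)
      for (crit in c("separability", "combined")) {
        cm <- optimize_breaks(v, e, k = k, criterion = crit)
        expect_equal(cm$objective, brute(v, e, k, crit), tolerance = 1e-9)
      }
    }
  })
})

test_that("with small constant errors the optimal breaks maximize gaps", {
  withr::with_seed(52, {
    v <- sort(runif(20))
    gaps <- diff(v)
    # errors small enough that neighbouring intervals always overlap:
    # separability is then strictly increasing in the gap size
    e <- rep(max(gaps) / (2 * qnorm(0.975)) * 1.05, 20)
    cm <- optimize_breaks(v, e, k = 4, criterion = "separability")
    top_gaps <- sort(order(gaps, decreasing = TRUE)[1:3])
    cut_positions <- findInterval(cm$breaks, v)
    expect_equal(sort(cut_positions), top_gaps)
    # every chosen break sits at a sizeable value separation
    expect_true(all(gaps[cut_positions] >= median(gaps)))
  })
})

test_that("quantile breaks reproduce sort-and-slice classes", {
  cm <- quantile_breaks(1:9, k = 3)
  expect_equal(cm$assignment, rep(1:3, each = 3))
  expect_error(quantile_breaks(1:9, k = 1), "at least 2")
  withr::with_seed(53, {
    v <- rnorm(1000)
    cm <- quantile_breaks(v, k = 4)
    oracle <- cut(v, c(-Inf, quantile(v, c(0.25, 0.5, 0.75)), Inf), labels = FALSE)
    expect_equal(cm$assignment, oracle)
  })
  expect_warning(quantile_breaks(rep(c(1, 2), c(50, 2)), k = 3), "ties")
})

test_that("classed maps expose tidy, glance and autoplot views", {
  withr::with_seed(54, {
    v <- runif(30); e <- runif(30, 0.01, 0.1)
    cm <- optimize_breaks(v, e, k = 3, criterion = "combined")
    expect_equal(nrow(tidy(cm)), 30)
    gl <- glance(cm)
    expect_equal(gl$k, 3)
    expect_gte(gl$min_class_size, 1)
    p <- autoplot(cm)
    expect_s3_class(p, "ggplot")
  })
})
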