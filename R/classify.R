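#' Per-tract confidence intervals
#'
#' Symmetric normal-theory intervals `value +- z * error` at the given
#' confidence level; the uncertainty input to separability-based map
#' classification. The error may be an analytical measurement error or a
#' resampling (bootstrap) error.
#'
#' @param values Tract-level values.
#' @param errors Non-negative per-tract standard errors.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A tibble with columns `value`, `lo`, `hi`.
#' @export
tract_intervals <- function(values, errors, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must lie in (0, 1)")
  }
  if (length(errors) != length(values)) abort("length mismatch")
  if (any(errors < 0)) abort("errors must be non-negative")
  zq <- qnorm((1 + level) / 2)
  tibble(value = values, lo = values - zq * errors, hi = values + zq * errors)
}

# separability of two intervals: 1 - overlap/union (interval Jaccard
# distance). 0 for identical intervals, 1 for disjoint ones, partial
# otherwise; invariant under joint affine rescaling.
interval_separability <- function(lo1, hi1, lo2, hi2) {
  overlap <- pmax(0, pmin(hi1, hi2) - pmax(lo1, lo2))
  union <- pmax(hi1, hi2) - pmin(lo1, lo2)
  ifelse(union <= 0,
         ifelse(lo1 == lo2, 0, 1),  # degenerate point intervals
         pmin(pmax(1 - overlap / union, 0), 1))
}

#' Separability of a class break
#'
#' Scores the break between two consecutive sorted observations by the
#' non-overlap of their confidence intervals: `1 - overlap/union` of the
#' two straddling intervals, in [0, 1] (0 when the intervals coincide, 1
#' when they are disjoint). A break is defensible under uncertainty when
#' the observations on either side are distinguishable.
#'
#' @param intervals A [tract_intervals()] tibble, sorted by `value`.
#' @param after Break position: between sorted observation `after` and
#'   `after + 1`.
#' @return Separability score in [0, 1].
#' @export
break_separability <- function(intervals, after) {
  n <- nrow(intervals)
  if (any(after < 1 | after >= n)) abort("breaks must fall between two observations")
  if (is.unsorted(intervals$value)) abort("`intervals` must be sorted by value")
  interval_separability(
    intervals$lo[after], intervals$hi[after],
    intervals$lo[after + 1], intervals$hi[after + 1]
  )
}

#' Optimal uncertainty-aware class breaks
#'
#' Exact optimum over placements of `k - 1` class breaks on the sorted
#' observations, by dynamic programming. The `"separability"` criterion
#' maximizes the mean break separability; the `"combined"` criterion
#' maximizes `w * GVF + (1 - w) * mean separability`, where GVF is the
#' goodness-of-variance fit `1 - SSW/SST` (the Jenks objective), so
#' breaks account for both the values and their uncertainty. Ties are
#' broken toward equal class sizes.
#'
#' @param values Tract-level values.
#' @param errors Per-tract standard errors (uncertainty input).
#' @param k Number of classes (>= 2, <= number of observations).
#' @param criterion `"separability"` or `"combined"`.
#' @param w Weight on the variance term of the combined criterion,
#'   default 0.5.
#' @param level Confidence level for the intervals.
#' @return An object of class `classed_map`: list with `k`, `breaks`
#'   (k - 1 cut values at midpoints), `assignment` (class per input
#'   observation, original order), `separability` (per break),
#'   `objective`, `criterion`, and the sorted `intervals`.
#' @export
optimize_breaks <- function(values, errors, k = 5,
                            criterion = c("separability", "combined"),
                            w = 0.5, level = 0.95) {
  criterion <- match.arg(criterion)
  k <- assert_scalar_count(k, "k")
  n <- length(values)
  if (k < 2) abort("k must be at least 2")
  if (k > n) abort("more classes than observations")
  if (diff(range(values)) == 0) abort("all values equal: no breaks exist")
  ord <- order(values)
  iv <- tract_intervals(values[ord], errors[ord], level = level)
  v <- iv$value

  sep <- vapply(seq_len(n - 1), function(i) {
    interval_separability(iv$lo[i], iv$hi[i], iv$lo[i + 1], iv$hi[i + 1])
  }, numeric(1))

  sst <- sum((v - mean(v))^2)
  csum <- cumsum(v); csq <- cumsum(v^2)
  ssw <- function(i, j) {  # within-class sum of squares for sorted v[i..j]
    s <- csum[j] - if (i > 1) csum[i - 1] else 0
    q <- csq[j] - if (i > 1) csq[i - 1] else 0
    q - s^2 / (j - i + 1)
  }
  # class score contribution (additive across classes and breaks)
  w_var <- if (criterion == "combined") w else 0
  w_sep <- if (criterion == "combined") (1 - w) / (k - 1) else 1 / (k - 1)

  # dp[j, c]: best score of first j observations split into c classes;
  # a break after position i adds w_sep * sep[i]
  dp <- matrix(-Inf, n, k)
  sizesq <- matrix(Inf, n, k)  # tie-break: sum of squared class sizes
  back <- matrix(NA_integer_, n, k)
  for (j in seq_len(n)) {
    dp[j, 1] <- -w_var * ssw(1, j) / sst
    sizesq[j, 1] <- j^2
  }
  if (k > 1) {
    for (c in 2:k) {
      for (j in c:n) {
        best <- -Inf; best_sz <- Inf; best_i <- NA_integer_
        for (i in (c - 1):(j - 1)) {
          cand <- dp[i, c - 1] - w_var * ssw(i + 1, j) / sst + w_sep * sep[i]
          sz <- sizesq[i, c - 1] + (j - i)^2
          if (cand > best + 1e-12 || (abs(cand - best) <= 1e-12 && sz < best_sz)) {
            best <- cand; best_sz <- sz; best_i <- i
          }
        }
        dp[j, c] <- best; sizesq[j, c] <- best_sz; back[j, c] <- best_i
      }
    }
  }
  cuts <- integer(k - 1)
  j <- n
  for (c in k:2) {
    cuts[c - 1] <- back[j, c]
    j <- back[j, c]
  }
  objective <- dp[n, k] + if (criterion == "combined") w else 0

  breaks <- (v[cuts] + v[cuts + 1]) / 2
  # assignment by position in the sorted order (robust to ties at breaks)
  cls_sorted <- rep(seq_len(k), times = diff(c(0, cuts, n)))
  assignment <- integer(n)
  assignment[ord] <- cls_sorted

  structure(
    list(
      k = k, breaks = breaks, assignment = assignment,
      separability = sep[cuts], objective = objective,
      criterion = criterion, w = if (criterion == "combined") w else NA_real_,
      intervals = iv
    ),
    class = "classed_map"
  )
}

#' Quantile (and tertile) class breaks
#'
#' Baseline classification ignoring uncertainty: breaks at the `j/k`
#' empirical quantiles. `k = 3` gives the tertile maps.
#'
#' @param values Tract-level values.
#' @param k Number of classes (>= 2).
#' @return A `classed_map` (separability and objective are `NA`).
#' @export
quantile_breaks <- function(values, k = 3) {
  k <- assert_scalar_count(k, "k")
  if (k < 2) abort("k must be at least 2")
  n <- length(values)
  if (k > n) abort("more classes than observations")
  breaks <- unname(quantile(values, probs = seq_len(k - 1) / k))
  if (anyDuplicated(breaks)) {
    warn("massive ties: falling back to quantiles of the distinct values")
    breaks <- unname(quantile(unique(values), probs = seq_len(k - 1) / k))
  }
  assignment <- findInterval(values, c(-Inf, breaks, Inf), left.open = TRUE)
  assignment[assignment < 1] <- 1L
  structure(
    list(
      k = k, breaks = breaks, assignment = assignment,
      separability = rep(NA_real_, k - 1), objective = NA_real_,
      criterion = "quantile", w = NA_real_,
      intervals = tibble(value = sort(values),
                         lo = sort(values), hi = sort(values))
    ),
    class = "classed_map"
  )
}

#' @export
print.classed_map <- function(x, ...) {
  cat(sprintf("<classed_map> %s, k = %d\nbreaks: %s\n", x$criterion, x$k,
              paste(signif(x$breaks, 4), collapse = ", ")))
  if (!all(is.na(x$separability))) {
    cat("separability:", paste(signif(x$separability, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.classed_map <- function(x, ...) {
  tibble(
    observation = seq_along(x$assignment),
    class = x$assignment
  )
}

#' @export
glance.classed_map <- function(x, ...) {
  tibble(
    k = x$k, criterion = x$criterion, objective = x$objective,
    mean_separability = mean(x$separability),
    min_class_size = min(table(x$assignment))
  )
}

#' Plot a classified error sequence with its uncertainty
#'
#' Sorted tract values with confidence-interval bars, coloured by class,
#' with vertical lines at the class breaks — the standard diagnostic
#' view of an uncertainty-aware classification.
#'
#' @param object A `classed_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classed_map <- function(object, ...) {
  iv <- object$intervals
  d <- tibble(
    rank = seq_len(nrow(iv)), value = iv$value, lo = iv$lo, hi = iv$hi,
    class = factor(sort(object$assignment))
  )
  cuts <- which(diff(sort(object$assignment)) > 0) + 0.5
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 1.5) +
    ggplot2::geom_vline(xintercept = cuts, linetype = 2, colour = "grey30") +
    ggplot2::labs(x = "tract (sorted)", y = "value",
                  colour = "class") +
    ggplot2::theme_minimal()
}
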