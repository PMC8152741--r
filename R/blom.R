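#' Rank probabilities and Blom (rankit) normal scores
#'
#' `rank_probability()` maps a rank to its plotting position
#' `p = (r - 3/8) / (n + 1/4)`; `blom_scores()` returns the standard
#' normal quantile of that position, the covariate of the rankit
#' regression. For a value from outside the sample the denominator uses
#' `n + 1` in place of `n` (`(r - 3/8) / (n + 1 + 1/4)`).
#'
#' @param r Rank(s) in `1..n`; fractional ranks (average ranks for ties)
#'   are accepted.
#' @param n Sample size (>= 1).
#' @param out_of_sample Use the out-of-sample denominator `n + 1 + 1/4`.
#' @return `rank_probability()`: probabilities in (0, 1);
#'   `blom_scores()`: normal scores.
#' @examples
#' rank_probability(5, 9)   # exactly 0.5
#' blom_scores(10)[10]      # ~1.5466
#' @export
rank_probability <- function(r, n, out_of_sample = FALSE) {
  n <- assert_scalar_count(n, "n")
  if (any(r < 1 - 1e-9 | r > n + 1e-9)) abort("ranks must lie in 1..n")
  denom <- if (out_of_sample) n + 1 + 1 / 4 else n + 1 / 4
  (r - 3 / 8) / denom
}

#' @rdname rank_probability
#' @param ranks Ranks to score; defaults to `1:n`.
#' @export
blom_scores <- function(n, ranks = seq_len(n), out_of_sample = FALSE) {
  qnorm(rank_probability(ranks, n, out_of_sample = out_of_sample))
}

#' Six-sigma interval for an order-statistic probability
#'
#' The probability integral transform of the r-th order statistic of an
#' i.i.d. sample follows a beta distribution; combining its variance
#' `r (n - r + 1) / ((n + 2) (n + 1/4)^2)` with the six-sigma principle
#' gives the interval `p +- 3 sd`, clipped away from 0 and 1. Uniform
#' specification-error draws sample from this interval.
#'
#' @inheritParams rank_probability
#' @return A tibble with columns `lo` and `hi`; always contains
#'   `rank_probability(r, n)`.
#' @examples
#' six_sigma_interval(5, 9)  # half-width ~0.4889
#' @export
six_sigma_interval <- function(r, n) {
  p <- rank_probability(r, n)
  v <- r * (n - r + 1) / ((n + 2) * (n + 1 / 4)^2)
  half <- 3 * sqrt(v)
  eps <- 1e-9
  tibble(
    lo = pmin(pmax(p - half, eps), 1 - eps),
    hi = pmax(pmin(p + half, 1 - eps), eps)
  )
}

#' Specification-error regression covariates
#'
#' The covariate each distributional assumption uses in the regression of
#' the transformed error on rank order: the log-normal assumption uses
#' the Blom normal score; the gamma assumption uses
#' `ln[(r - 3/8)/(n - r + 5/8) + 1/4]`; the beta assumption uses the
#' logit of the plotting position, `ln[(r - 3/8)/(n - r + 5/8)]`; and the
#' uniform assumption uses the plotting position itself.
#'
#' @param assumption One of `"lognormal"`, `"gamma"`, `"beta"`,
#'   `"uniform"`.
#' @inheritParams rank_probability
#' @return Numeric covariate values.
#' @export
specification_covariate <- function(assumption = c("lognormal", "gamma", "beta", "uniform"),
                                    r, n) {
  assumption <- match.arg(assumption)
  n <- assert_scalar_count(n, "n")
  if (any(r < 1 - 1e-9 | r > n + 1e-9)) abort("ranks must lie in 1..n")
  ratio <- (r - 3 / 8) / (n - r + 5 / 8)
  switch(assumption,
    lognormal = blom_scores(n, ranks = r),
    gamma = log(ratio + 1 / 4),
    beta = log(ratio),
    uniform = rank_probability(r, n)
  )
}
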