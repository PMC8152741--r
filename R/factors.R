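#' Tract-level averages of assay errors
#'
#' Aggregates a point-sample survey to the tract level: the arithmetic
#' mean per tract of each metal's assay error, optionally after the
#' log-shift transform `LN(y + delta)` (the scale the dimension analysis
#' uses).
#'
#' @param samples A sample table.
#' @param log Transform each error to `log(error + delta)` before
#'   averaging.
#' @param delta Named per-metal offsets; required when `log = TRUE`
#'   (typically the `delta_hat` column of [fit_assay_errors()]).
#' @return A tibble with `tract_id` and one column per metal.
#' @export
tract_average <- function(samples, log = FALSE, delta = NULL) {
  metals <- survey_metals(samples)
  tract_of <- samples$tract_id
  tract_ids <- sort(unique(tract_of))
  counts <- as.vector(table(factor(tract_of, levels = tract_ids)))
  vals <- vapply(metals, function(mt) {
    y <- samples[[paste0(mt, "_err")]]
    if (log) {
      if (is.null(delta) || is.null(delta[[mt]])) {
        abort("`delta` must supply an offset per metal when log = TRUE")
      }
      y <- base::log(y + delta[[mt]])
    }
    y
  }, numeric(nrow(samples)))
  m <- rowsum(vals, tract_of) / counts
  out <- as_tibble(as.data.frame(m))
  names(out) <- metals
  dplyr::bind_cols(tibble(tract_id = tract_ids), out)
}

as_value_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  df <- as.data.frame(x)
  if ("tract_id" %in% names(df)) {
    rn <- df$tract_id
    df <- df[setdiff(names(df), "tract_id")]
    m <- as.matrix(df)
    rownames(m) <- rn
    m
  } else {
    as.matrix(df)
  }
}

#' Extract and rotate the error dimensions
#'
#' Principal-component extraction of the correlation matrix of the
#' tract-by-metal error matrix: the first `k` components scaled by the
#' square roots of their eigenvalues, followed by a Kaiser-normalized
#' varimax rotation. Columns are sign-aligned (column sum positive) and
#' ordered by percentage of variance accounted for, descending.
#'
#' @param x Tract-by-metal matrix or tibble (as from [tract_average()]).
#' @param k Number of factors (default 4).
#' @return An object of class `factor_solution`: list with `loadings`
#'   (variables by `k`, row-named), `pct_variance` (column sums of
#'   squared rotated loadings over the number of variables, in percent),
#'   `communalities`, `k`, `rotation` matrix, and the correlation matrix
#'   `cor`.
#' @export
factor_solution <- function(x, k = 4) {
  m <- as_value_matrix(x)
  k <- assert_scalar_count(k, "k")
  if (nrow(m) < k + 2) abort("need at least k + 2 rows")
  if (any(apply(m, 2, sd) == 0)) abort("constant column: correlation undefined")
  r <- cor(m)
  e <- eigen(r, symmetric = TRUE)
  if (e$values[k] <= 1e-12) abort("correlation matrix is singular at the requested k")
  l <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(e$values[seq_len(k)]), k)
  rot <- varimax(l, normalize = TRUE, eps = 1e-8)
  ld <- l %*% rot$rotmat
  # sign convention: each dimension positively oriented
  sgn <- ifelse(colSums(ld) < 0, -1, 1)
  ld <- sweep(ld, 2, sgn, `*`)
  pct <- 100 * colSums(ld^2) / ncol(m)
  ord <- order(pct, decreasing = TRUE)
  ld <- ld[, ord, drop = FALSE]
  pct <- pct[ord]
  rownames(ld) <- colnames(m)
  colnames(ld) <- paste0("F", seq_len(k))
  structure(
    list(
      loadings = ld, pct_variance = pct, communalities = rowSums(ld^2),
      k = k, rotation = rot$rotmat[, ord, drop = FALSE] %*% diag(sgn[ord], k),
      cor = r
    ),
    class = "factor_solution"
  )
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution> %d variables, k = %d\n%% variance: %s\n",
              nrow(x$loadings), x$k,
              paste(sprintf("%.1f", x$pct_variance), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.factor_solution <- function(x, ...) {
  ld <- x$loadings
  tibble(
    variable = rep(rownames(ld), times = ncol(ld)),
    factor = rep(colnames(ld), each = nrow(ld)),
    loading = as.vector(ld)
  )
}

#' @export
glance.factor_solution <- function(x, ...) {
  tibble(
    k = x$k,
    total_pct_variance = sum(x$pct_variance),
    min_communality = min(x$communalities)
  )
}

#' Tucker congruence between loading matrices
#'
#' Column-wise cosine similarity; the factor-matching criterion.
#'
#' @param a,b Loading matrices with identical dimensions.
#' @return A `ncol(a)` by `ncol(b)` matrix of congruence coefficients.
#' @export
tucker_congruence <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  num <- crossprod(a, b)
  den <- sqrt(colSums(a^2)) %o% sqrt(colSums(b^2))
  num / den
}

# all permutations of 1..k (k small: used for 4! = 24 assignments)
permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(setdiff(seq_len(k), i)[sub], nrow(sub), k - 1L))
  }))
}

#' Align a factor solution to a reference
#'
#' Permutes and sign-flips the candidate's columns to maximize the total
#' absolute Tucker congruence with the reference (exact optimal
#' assignment over all column permutations) — the matching step needed
#' before loadings can be averaged across simulation replications.
#' Alignment is deterministic and idempotent.
#'
#' @param reference,candidate `factor_solution` objects (or loading
#'   matrices) of identical dimensions.
#' @return The aligned candidate (same class as supplied).
#' @export
align_factors <- function(reference, candidate) {
  ref_ld <- if (inherits(reference, "factor_solution")) reference$loadings else as.matrix(reference)
  cand_is_fs <- inherits(candidate, "factor_solution")
  cand_ld <- if (cand_is_fs) candidate$loadings else as.matrix(candidate)
  if (!all(dim(ref_ld) == dim(cand_ld))) abort("dimension mismatch")
  k <- ncol(ref_ld)
  cg <- tucker_congruence(ref_ld, cand_ld)
  perms <- permutations(k)
  tot <- apply(perms, 1, function(p) sum(abs(cg[cbind(seq_len(k), p)])))
  p <- perms[which.max(tot), ]
  sgn <- sign(cg[cbind(seq_len(k), p)])
  sgn[sgn == 0] <- 1
  aligned <- sweep(cand_ld[, p, drop = FALSE], 2, sgn, `*`)
  colnames(aligned) <- colnames(ref_ld)
  if (!cand_is_fs) return(aligned)
  out <- candidate
  out$loadings <- aligned
  out$pct_variance <- candidate$pct_variance[p]
  out$communalities <- rowSums(aligned^2)
  out
}

#' Summarize loadings over simulation replications
#'
#' Element-wise mean and standard deviation of the (aligned) loadings
#' across replications, prominence flags, and the per-variable dimension
#' assignment: a variable is assigned to the factor holding its largest
#' absolute mean loading, provided that loading exceeds the prominence
#' threshold; otherwise it is unassigned.
#'
#' @param solutions List of `factor_solution` objects, all aligned to
#'   `reference`.
#' @param reference The reference `factor_solution`.
#' @param threshold Prominence cut on the absolute mean loading
#'   (default 0.49).
#' @return An object of class `replication_summary`: list with
#'   `mean_loadings`, `sd_loadings`, `prominent` (logical matrix),
#'   `assignment` (tibble: `variable`, `dimension` with `NA` for
#'   unassigned), `mean_pct_variance`, `threshold`, and
#'   `threshold_observed` (smallest prominent absolute mean loading).
#' @export
replication_summary <- function(solutions, reference, threshold = 0.49) {
  if (length(solutions) < 2) abort("need at least 2 replications")
  lds <- lapply(solutions, function(s) {
    if (inherits(s, "factor_solution")) s$loadings else as.matrix(s)
  })
  dm <- dim(lds[[1]])
  if (!all(vapply(lds, function(l) all(dim(l) == dm), logical(1)))) {
    abort("replication loading matrices differ in dimension")
  }
  arr <- array(unlist(lds), dim = c(dm, length(lds)))
  mean_ld <- apply(arr, c(1, 2), mean)
  sd_ld <- apply(arr, c(1, 2), sd)
  dimnames(mean_ld) <- dimnames(sd_ld) <- dimnames(lds[[1]])
  is_max <- t(apply(abs(mean_ld), 1, function(r) seq_along(r) == which.max(r)))
  prominent <- is_max & abs(mean_ld) >= threshold
  dim_of <- apply(prominent, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  pv <- vapply(solutions, function(s) {
    if (inherits(s, "factor_solution")) s$pct_variance else rep(NA_real_, dm[2])
  }, numeric(dm[2]))
  structure(
    list(
      mean_loadings = mean_ld, sd_loadings = sd_ld, prominent = prominent,
      assignment = tibble(variable = rownames(mean_ld),
                          dimension = unname(dim_of)),
      mean_pct_variance = rowMeans(pv),
      threshold = threshold,
      threshold_observed = if (any(prominent)) min(abs(mean_ld)[prominent]) else NA_real_,
      n_replications = length(solutions)
    ),
    class = "replication_summary"
  )
}

#' @export
print.replication_summary <- function(x, ...) {
  cat(sprintf("<replication_summary> %d replications, threshold %.2f\n",
              x$n_replications, x$threshold))
  print(x$assignment, n = nrow(x$assignment))
  invisible(x)
}

#' @export
tidy.replication_summary <- function(x, ...) {
  m <- x$mean_loadings
  tibble(
    variable = rep(rownames(m), times = ncol(m)),
    factor = rep(colnames(m), each = nrow(m)),
    mean_loading = as.vector(m),
    sd_loading = as.vector(x$sd_loadings),
    prominent = as.vector(x$prominent)
  )
}

#' Factor scores by the regression (Thomson) method
#'
#' @param solution A `factor_solution`.
#' @param x The tract-by-metal matrix the solution was fitted to (or new
#'   data on the same variables).
#' @return A matrix of tract-level factor scores (rows match `x`).
#' @export
factor_scores <- function(solution, x) {
  stopifnot(inherits(solution, "factor_solution"))
  m <- as_value_matrix(x)
  z <- scale(m)
  z %*% solve(solution$cor, solution$loadings)
}
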