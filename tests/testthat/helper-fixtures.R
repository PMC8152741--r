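# shared fixtures, built once per test run

.fix <- new.env()

test_tess <- function() {
  if (is.null(.fix$tess)) .fix$tess <- make_tessellation(3, 19)
  .fix$tess
}

# default synthetic survey: 57 tracts, ~58 samples per tract, 15 metals
test_survey <- function() {
  if (is.null(.fix$survey)) {
    .fix$survey <- generate_survey(test_tess(), landscape_config(seed = 1))
  }
  .fix$survey
}

test_fits <- function() {
  if (is.null(.fix$fits)) .fix$fits <- fit_assay_errors(test_survey())
  .fix$fits
}

test_tract_matrix <- function() {
  if (is.null(.fix$tm)) {
    f <- test_fits()
    .fix$tm <- tract_average(test_survey(), log = TRUE,
                             delta = stats::setNames(f$delta_hat, f$metal))
  }
  .fix$tm
}

# small sample table built by hand (one metal) for interface tests
tiny_survey <- function(err, val = err, tract = rep(1L, length(err))) {
  out <- tibble::tibble(
    sample_id = seq_along(err), x = runif(length(err)),
    y = runif(length(err)), tract_id = tract,
    As_err = err, As_val = val
  )
  class(out) <- c("sample_table", class(out))
  out
}

# random connected spatial weights for oracle tests: queen grid of random
# shape, so connectivity is guaranteed
random_weights <- function(n_max = 25, style = "binary") {
  repeat {
    r <- sample(2:5, 1); c <- sample(2:5, 1)
    if (r * c <= n_max && r * c >= 4) break
  }
  spatial_weights(make_tessellation(r, c), style = style)
}
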