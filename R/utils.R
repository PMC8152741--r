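# internal helpers shared across modules

# Derive a reproducible substream seed from a master seed so each stochastic
# stage of a pipeline can be rerun independently. Result stays inside the
# 32-bit integer range R requires of set.seed().
substream_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  offsets <- c(
    tessellation = 101L, counts = 211L, scores = 307L, noise = 401L,
    values = 503L, placement = 601L, draws = 701L, bootstrap = 809L,
    mixture = 907L
  )
  off <- if (is.character(stage)) {
    if (!stage %in% names(offsets)) abort(paste0("unknown stage '", stage, "'"))
    offsets[[stage]]
  } else {
    as.integer(stage)
  }
  as.integer((abs(as.numeric(master)) * 31 + off) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort(paste0("`", name, "` must be a single positive integer"))
  }
  as.integer(x)
}
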