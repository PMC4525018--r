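# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. A NULL seed runs `code` against the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Circular distance between orientations on the 180-degree domain.
orientation_dist <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
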