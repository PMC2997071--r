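# Reproducible RNG streams.
#
# All user-facing sampling functions accept a `seed`; internally a root seed
# initialises the L'Ecuyer-CMRG generator and independent substreams are
# derived with parallel::nextRNGStream. Substream j depends only on (seed, j),
# so ensemble members are reproducible independently of how many other paths
# are generated. Within a stream, draws are consumed sequentially in a fixed
# documented order (mixture components in declaration order; zero-weight
# components are skipped and consume nothing).

get_rand_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

set_rand_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(state)
}

# .Random.seed vector for substream `substream` of root `seed`
rng_state <- function(seed, substream = 0L) {
  orig <- get_rand_state()
  on.exit(set_rand_state(orig), add = TRUE)
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  s <- get_rand_state()
  substream <- as.integer(substream)
  while (substream > 0L) {
    s <- parallel::nextRNGStream(s)
    substream <- substream - 1L
  }
  s
}

# Evaluate `code` under substream (seed, substream), restoring the caller's
# RNG state afterwards. seed = NULL means: use the current RNG state.
with_seed <- function(seed, code, substream = 0L) {
  if (is.null(seed)) {
    return(code)
  }
  orig <- get_rand_state()
  on.exit(set_rand_state(orig), add = TRUE)
  set_rand_state(rng_state(seed, substream))
  code
}

# Evaluate `code` with .Random.seed set to `state`, restoring afterwards.
# Used by ensemble drivers that advance substreams incrementally (one
# nextRNGStream call per path) instead of re-deriving each from the root.
with_state <- function(state, code) {
  orig <- get_rand_state()
  on.exit(set_rand_state(orig), add = TRUE)
  set_rand_state(state)
  code
}
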