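# Named random substreams derived from one master seed.
#
# Every stochastic component of the package (informative-region placement,
# condition patterns, block order, noise, fold shuffling) draws from its own
# stream so that, e.g., changing the noise realization never perturbs region
# placement. A stream is an isolated RNG state seeded from a deterministic
# hash of (master seed, stream name); drawing from it saves and restores the
# global .Random.seed, so package code never disturbs the user's RNG.

derive_seed <- function(seed, name) {
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

substream_rng <- function(seed, name) {
  state <- NULL
  run_in_stream <- function(expr) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) set.seed(derive_seed(seed, name))
    else assign(".Random.seed", state, envir = globalenv())
    out <- expr()
    state <<- get(".Random.seed", globalenv())
    out
  }
  list(
    rnorm = function(n) run_in_stream(function() stats::rnorm(n)),
    sample_int = function(n, size = n, replace = FALSE)
      run_in_stream(function() sample.int(n, size, replace = replace)),
    permute = function(x) run_in_stream(function() x[sample.int(length(x))])
  )
}
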