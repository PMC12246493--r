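# Run code under a temporary RNG state; restores the caller's stream so
# simulation functions are deterministic in `seed` without clobbering the
# session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Small-sample corrected Akaike Information Criterion from a least-squares
# residual sum of squares (Gaussian likelihood up to an additive constant).
aicc_ls <- function(ss, n, k) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1", call. = FALSE)
  n * log(ss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}
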