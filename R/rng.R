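# Deterministic RNG plumbing: every stochastic operation takes a seed (or a
# noise model carrying one) and runs under a locally scoped RNG state, so the
# caller's .Random.seed is never disturbed and identical seeds give identical
# tables.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stage-specific sub-seed from a master seed. Keeps results of one
# stage independent of how many draws an earlier stage consumed. Constants are
# from the classic Knuth LCG; result is kept inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.double(seed) * 69069 + h * 101 + 1) %% 2147483647)
}

# Multiplicative lognormal noise with unit mean and the requested coefficient
# of variation (cv = sd/mean). cv = 0 returns exactly 1.
rlnorm_cv <- function(n, cv) {
  if (cv < 0) stop_invalid("cv must be >= 0")
  if (cv == 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  exp(rnorm(n, mean = -sigma2 / 2, sd = sqrt(sigma2)))
}
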