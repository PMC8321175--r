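# RNG scoping: run code under a given seed and restore the caller's RNG
# state afterwards, so package functions never clobber the user's stream.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %%
             .Machine$integer.max)
}

# Population SD (divide by n) -- the convention for pixel statistics.
popSd <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

stopQc <- function(stage, ...) {
  msg <- paste0("[", stage, "] ", ...)
  stop(errorCondition(msg, class = c(paste0("acrqc_", stage, "_error"),
                                     "acrqc_error")))
}
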