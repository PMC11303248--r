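# Seed handling: one master seed fans out to named substreams so each
# stochastic component (bout structure, velocity noise, sensor noise, point
# patterns, cohort draws) is independently reproducible.

.substreams <- c(bouts = 101L, noise = 211L, sensor = 307L, foci = 401L,
                 cohort = 503L)

#' Derive a substream seed from a master seed
#'
#' @param seed Master integer seed.
#' @param stream One of `"bouts"`, `"noise"`, `"sensor"`, `"foci"`, `"cohort"`.
#' @return An integer seed below 2^31, distinct across streams.
#' @keywords internal
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stream <- match.arg(stream, names(.substreams))
  as.integer((abs(as.numeric(seed)) * 1009 + .substreams[[stream]] * 9973) %%
               2147483629)
}

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}
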