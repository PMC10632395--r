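# Internal helpers: seeding and argument checks.

# Run `code` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's stream.
with_seed <- function(seed, code) {
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

# Deterministic substream seed derived from a root seed; stays < 2^31.
substream <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 69621) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
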