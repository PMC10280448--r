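# Internal helpers.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_state <- function(m, expected, op) {
  if (!inherits(m, "interval_matrix")) stop(op, ": not an interval_matrix")
  if (m$state != expected) {
    stop(op, ": requires state '", expected, "', got '", m$state, "'")
  }
}
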