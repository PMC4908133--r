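# Internal helpers.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  hasOld <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (hasOld) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (hasOld) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
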