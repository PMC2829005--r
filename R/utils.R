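## Evaluate `code` under a fixed seed without disturbing the caller's RNG
## stream. A NULL seed leaves the RNG untouched.
run_seeded <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}
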