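# Evaluate expr with a local RNG state: seeds deterministically, restores
# the caller's .Random.seed afterwards. RNG kinds are pinned so results
# are reproducible across platforms.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}
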