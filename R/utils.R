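## Run code with a temporarily seeded RNG, restoring global state afterwards.
## seed = NULL leaves the current RNG stream untouched (used by experiment
## drivers that manage one seed for many inner draws).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

spearman <- function(a, b) stats::cor(a, b, method = "spearman")
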