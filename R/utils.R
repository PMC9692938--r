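# run expr under a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-stage seed derivation from a master seed; keeps results
# of one stage insensitive to how much randomness another stage consumed
.stage_seed <- function(master, stage) {
  offsets <- c(prep = 101L, split = 211L, autoencoder = 307L,
               aco = 401L, classify = 503L, synth = 601L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(master) %% 1000000L) * 1000L + offsets[[stage]]
}
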