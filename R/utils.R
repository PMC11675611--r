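# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic k-fold assignment of n items.
foldAssignments <- function(n, k, seed) {
  k <- max(2L, min(as.integer(k), n))
  withSeed(seed, sample(rep_len(seq_len(k), n)))
}

# Root-mean-square CV residual used internally for model tuning.
cvRmse <- function(residuals) sqrt(mean(residuals^2))

assertMatrix <- function(X, name = deparse(substitute(X))) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop(name, " must not contain missing values")
  X
}
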