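# Run expr with a local RNG stream: the global .Random.seed is restored on
# exit, so package functions never perturb the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# id-keyed symmetric matrix -> PairwiseMatrix, with names enforced
newPairwiseMatrix <- function(values, ids, kind) {
  dimnames(values) <- list(ids, ids)
  new("PairwiseMatrix", ids = as.character(ids), values = values, kind = kind)
}

pairNames <- function(ids) {
  n <- length(ids)
  # row-major lower triangle: for i = 2..n, j = 1..i-1
  ii <- rep(2:n, times = 1:(n - 1L))
  jj <- unlist(lapply(2:n, function(k) 1:(k - 1L)), use.names = FALSE)
  paste(ids[ii], ids[jj], sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
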