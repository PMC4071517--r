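# Small in-code fixtures shared across test files.

toyGenotypes <- function(m = matrix(c(1, 1, 0,
                                      1, 1, 0,
                                      0, 0, 1,
                                      0, 1, 1), nrow = 4, byrow = TRUE)) {
  dimnames(m) <- list(paste0("ind", seq_len(nrow(m))),
                      paste0("L", seq_len(ncol(m))))
  DominantGenotypes(m)
}

toySamples <- function(n = 5, seed = 42) {
  withr::with_seed(seed, {
    SampleTable(data.frame(
      id = paste0("ind", seq_len(n)),
      lon = runif(n, 159.0, 159.1), lat = runif(n, -31.6, -31.5),
      association = rep_len(c("Aa", "Ab"), n),
      altitude = runif(n, 0, 800), soil_ph = runif(n, 4, 7),
      light = runif(n, 0, 1)))
  })
}

# symmetric zero-diagonal matrix from an unfolded vector, shifted positive so
# it passes the distance validity checks
distFromVector <- function(v, ids) {
  kinMMRR:::newPairwiseMatrix(refold(v - min(v) + 0.1, ids), ids, "distance")
}

randomPolymorphicGenotypes <- function(n, L, seed) {
  withr::with_seed(seed, {
    repeat {
      g <- matrix(rbinom(n * L, 1, runif(L, 0.2, 0.8)[rep(seq_len(L),
                                                          each = n)]),
                  n, L, dimnames = list(paste0("i", seq_len(n)),
                                        paste0("L", seq_len(L))))
      f <- colMeans(g)
      if (all(f > 0 & f < 1)) return(DominantGenotypes(g))
    }
  })
}
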