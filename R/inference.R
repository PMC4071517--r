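#' Mantel-style permutation of a pairwise matrix
#'
#' Rows and columns are permuted by the same random permutation of the
#' individual labels, preserving the matrix's internal structure (the
#' off-diagonal value multiset is conserved exactly).
#'
#' @param x a \linkS4class{PairwiseMatrix}.
#' @param seed integer seed, or \code{NULL} to use the current RNG stream.
#' @param perm optional explicit permutation of \code{seq_along(ids)}
#'   (overrides \code{seed}).
#' @return the permuted \linkS4class{PairwiseMatrix} (ids keep their original
#'   order; values move).
#' @export
permuteResponse <- function(x, seed = NULL, perm = NULL) {
  n <- length(x@ids)
  if (is.null(perm))
    perm <- withSeed(seed, sample.int(n))
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  newPairwiseMatrix(x@values[perm, perm, drop = FALSE], x@ids, x@kind)
}

# Map for permuting an unfolded vector: position of pair (i,j) in unfold
# order, as a full n x n index matrix (diagonal NA).
pairIndexMatrix <- function(n) {
  M <- matrix(NA_integer_, n, n)
  pos <- 0L
  for (i in 2:n) for (j in 1:(i - 1L)) {
    pos <- pos + 1L
    M[i, j] <- pos
    M[j, i] <- pos
  }
  M
}

#' Permutation test for model-averaged matrix-regression coefficients
#'
#' The observed model-averaged estimate of every term is compared with its
#' null distribution under \code{B} Mantel-style permutations of the kinship
#' response (predictors held fixed; the whole all-subsets fit and averaging
#' is re-run per permutation). Reported per term: the permutation z-score
#' \eqn{z = (\hat\theta - \bar\theta_{null}) / sd_{null}}, its normal-theory
#' two-sided p, and the empirical two-sided
#' \eqn{p = (1 + \#\{|\theta_{null}| \ge |\hat\theta|\})/(1 + B)}
#' (pseudo-count form, never exactly 0). If a term's null sd is zero the
#' z-score is undefined and only the empirical p is reported, with a warning.
#'
#' A single \code{seed} governs the whole permutation stream, so results are
#' exactly reproducible.
#'
#' @param response a \linkS4class{PairwiseMatrix} (kinship) or an already
#'   unfolded numeric vector.
#' @param predictors a \linkS4class{PredictorSet} or a named matrix of
#'   unfolded predictor vectors.
#' @param B number of permutations (default 1000; >= 99 required).
#' @param seed integer seed for the permutation stream.
#' @param standardize standardize response and predictor vectors first
#'   (default TRUE when matrix inputs are given). Standardization constants
#'   are permutation-invariant, so this commutes with permuting.
#' @param method averaging method passed on (conditional/full).
#' @return list of class \code{"PermutationResult"}: \code{effects}
#'   (data.frame: term, estimate, null_mean, null_sd, z, p_z, p), \code{null}
#'   (B x p matrix of permuted estimates), \code{B}, \code{seed}.
#' @export
permutationTest <- function(response, predictors, B = 1000, seed = 1,
                            standardize = NULL, method = "conditional") {
  if (B < 99) stop("B must be >= 99")
  if (is(response, "PairwiseMatrix")) {
    if (is(predictors, "PredictorSet")) {
      standardize <- standardize %||% TRUE
      if (standardize) {
        sp <- standardizePredictors(predictors, response)
        y <- sp$response
        X <- sp$vectors
      } else {
        X <- vapply(names(predictors), function(nm) unfold(predictors[[nm]]),
                    numeric(length(response@ids) * (length(response@ids) - 1L) / 2L))
        y <- unfold(response)
      }
    } else stop("matrix response requires a PredictorSet")
    n <- length(response@ids)
  } else {
    y <- response
    X <- as.matrix(predictors)
    n <- (1 + sqrt(1 + 8 * length(y))) / 2
    if (abs(n - round(n)) > 1e-8)
      stop("response length is not a pair count n(n-1)/2")
    n <- as.integer(round(n))
  }
  p <- ncol(X)
  terms <- colnames(X)

  constantY <- stats::sd(y) == 0
  if (constantY) {
    warning("constant response: all model-averaged estimates are 0 and p = 1")
    eff <- data.frame(term = terms, estimate = 0, null_mean = 0, null_sd = 0,
                      z = NA_real_, p_z = NA_real_, p = 1)
    return(structure(list(effects = eff,
                          null = matrix(0, B, p, dimnames = list(NULL, terms)),
                          B = B, seed = seed), class = "PermutationResult"))
  }

  idx <- pairIndexMatrix(n)
  perms <- withSeed(seed, replicate(B, sample.int(n), simplify = FALSE))
  Y <- matrix(0, length(y), B + 1L)
  Y[, 1L] <- y
  for (b in seq_len(B)) {
    pr <- perms[[b]]
    Y[, b + 1L] <- y[unfold(idx[pr, pr])]
  }
  TH <- averageManyResponses(Y, X, method = method)
  obs <- TH[, 1L]
  nullTH <- t(TH[, -1L, drop = FALSE]) # B x p
  nullMean <- colMeans(nullTH)
  nullSd <- apply(nullTH, 2L, stats::sd)
  z <- (obs - nullMean) / nullSd
  if (any(nullSd == 0)) {
    warning(sprintf("null sd is zero for term(s) %s; z undefined, empirical p only",
                    paste(terms[nullSd == 0], collapse = ", ")))
    z[nullSd == 0] <- NA_real_
  }
  pz <- 2 * stats::pnorm(-abs(z))
  pEmp <- vapply(seq_len(p), function(j)
    (1 + sum(abs(nullTH[, j]) >= abs(obs[j]))) / (1 + B), numeric(1))
  eff <- data.frame(term = terms, estimate = unname(obs),
                    null_mean = unname(nullMean), null_sd = unname(nullSd),
                    z = unname(z), p_z = unname(pz), p = unname(pEmp))
  structure(list(effects = eff, null = nullTH, B = B, seed = seed),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("PermutationResult: %d permutations (seed %s)\n", x$B,
              format(x$seed)))
  print(x$effects, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values via \code{stats::p.adjust(method = "BH")}; a term is a
#' discovery when its q-value is at or below \code{level}.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @param level FDR level (default 0.05).
#' @return data.frame with \code{p}, \code{q}, \code{discovery}.
#' @export
fdrAdjust <- function(pvalues, level = 0.05) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, q = q, discovery = !is.na(q) & q <= level)
}
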