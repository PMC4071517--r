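#' Allele frequencies and dosage expectations under Hardy-Weinberg
#'
#' For a dominant marker the band-absence phenotype identifies the recessive
#' homozygote, so under Hardy-Weinberg equilibrium the band frequency
#' \eqn{f = 1 - (1-p)^2} yields the presence-allele frequency
#' \eqn{p = 1 - \sqrt{1 - f}}. The expected allele dosage (individual allele
#' frequency) given the phenotype is 0 for band-absent individuals and
#' \eqn{1/(2-p)} for band carriers (the HWE posterior mean over AA and Aa).
#'
#' @param genotypes a \linkS4class{DominantGenotypes} with polymorphic loci
#'   only (see \code{\link{dropMonomorphic}}).
#' @return list with per-locus vectors \code{fBand}, \code{p}, \code{nObs}
#'   (non-missing sample size) and the matrix \code{dosage} (individuals x
#'   loci, \code{NA} where the genotype is missing).
#' @export
estimateFrequencies <- function(genotypes) {
  g <- genotypeValues(genotypes)
  fBand <- colMeans(g, na.rm = TRUE)
  if (any(fBand <= 0 | fBand >= 1))
    stop(sprintf("monomorphic locus '%s' (band frequency %g); run dropMonomorphic first",
                 colnames(g)[which(fBand <= 0 | fBand >= 1)[1L]],
                 fBand[which(fBand <= 0 | fBand >= 1)[1L]]))
  p <- 1 - sqrt(1 - fBand)
  dosage <- sweep(g, 2L, 1 / (2 - p), "*") # phenotype 0 -> 0, 1 -> 1/(2-p)
  list(fBand = fBand, p = p, nObs = colSums(!is.na(g)), dosage = dosage)
}

#' Pairwise kinship from dominant markers
#'
#' Loiselle-type moment estimator on HWE dosage expectations, referenced to
#' sample allele frequencies:
#' \deqn{F_{ij} = \frac{\sum_l (x_{il}-p_l)(x_{jl}-p_l) + c_l}{\sum_l p_l (1-p_l)}}
#' with sums over the loci non-missing in both individuals and a per-locus
#' small-sample correction \eqn{c_l} offsetting the negative expectation of
#' the cross-product for unrelated pairs. Two corrections are available:
#' \describe{
#'   \item{\code{"dosage"} (default)}{\eqn{c_l = \widehat{Var}(x_l)/(n_l-1)}
#'     with the in-sample (ML) variance of the dosage expectations actually
#'     entering the estimator. This centres the estimator exactly: with no
#'     missing data the mean off-diagonal kinship is 0 by construction.}
#'   \item{\code{"allelic"}}{\eqn{c_l = p_l(1-p_l)/(n_l-1)}, the codominant
#'     allele-sampling variance. Because dominance shrinks the dosage
#'     variance below \eqn{p(1-p)}, this overshoots and leaves a small
#'     positive bias of order \eqn{1/((2-\bar p)(n-1))}.}
#' }
#' \eqn{n_l} is the non-missing sample size at locus \eqn{l}. The diagonal is
#' \code{NA} (self-kinship is not used downstream).
#'
#' @param x a \linkS4class{DominantGenotypes}.
#' @param freqs optional precomputed result of
#'   \code{\link{estimateFrequencies}}.
#' @param correction bias-correction variant, see Details.
#' @param ... unused.
#' @return a \linkS4class{PairwiseMatrix} of kind \code{"kinship"}.
#' @rdname kinshipMatrix
#' @export
setMethod("kinshipMatrix", "DominantGenotypes",
          function(x, freqs = NULL, correction = c("dosage", "allelic"), ...) {
  correction <- match.arg(correction)
  freqs <- freqs %||% estimateFrequencies(x)
  g <- genotypeValues(x)
  n <- nrow(g)
  if (n < 2L) stop("at least 2 individuals are required")
  p <- freqs$p
  X <- freqs$dosage
  Xc <- sweep(X, 2L, p)       # x - p, NA where missing
  M <- !is.na(g)              # observation mask
  Xc0 <- Xc
  Xc0[!M] <- 0
  nl <- freqs$nObs
  if (any(nl < 2L))
    stop("every locus needs >= 2 non-missing individuals")
  cl <- switch(correction,
    dosage  = colSums(Xc0^2) / nl / (nl - 1),
    allelic = p * (1 - p) / (nl - 1))
  Mn <- M * 1
  num <- Xc0 %*% t(Xc0) + Mn %*% (cl * t(Mn))
  den <- Mn %*% (p * (1 - p) * t(Mn))
  shared <- Mn %*% t(Mn)
  zero <- which(shared == 0 & row(shared) != col(shared), arr.ind = TRUE)
  if (nrow(zero))
    stop(sprintf("individuals '%s' and '%s' share no non-missing locus",
                 rownames(g)[zero[1L, 1L]], rownames(g)[zero[1L, 2L]]))
  F <- num / den
  F <- (F + t(F)) / 2 # symmetric by construction; enforce exact bit equality
  diag(F) <- NA_real_
  newPairwiseMatrix(F, rownames(g), "kinship")
})
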