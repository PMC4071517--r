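#' @rdname DominantGenotypes-class
#' @param x an object.
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname DominantGenotypes-class
#' @export
setGeneric("locusIds", function(x) standardGeneric("locusIds"))

#' @rdname DominantGenotypes-class
#' @export
setGeneric("genotypeValues", function(x) standardGeneric("genotypeValues"))

#' @rdname PairwiseMatrix-class
#' @param x an object.
#' @export
setGeneric("pairValues", function(x) standardGeneric("pairValues"))

#' @rdname PairwiseMatrix-class
#' @export
setGeneric("matrixKind", function(x) standardGeneric("matrixKind"))

#' Unfold a symmetric pairwise matrix into its lower-triangle vector
#'
#' Returns the strict lower triangle (i > j) in row-major order, i.e. pairs
#' (2,1), (3,1), (3,2), (4,1), ... The ordering is a function of id order
#' only, so all matrices over the same individuals unfold in the same pair
#' order -- the requirement for distance-matrix regression.
#'
#' @param x a \linkS4class{PairwiseMatrix} or a square symmetric matrix.
#' @param ... unused.
#' @return numeric vector of length \code{n(n-1)/2}, with names "i|j".
#' @export
setGeneric("unfold", function(x, ...) standardGeneric("unfold"))

#' @rdname kinshipMatrix
#' @export
setGeneric("kinshipMatrix", function(x, ...) standardGeneric("kinshipMatrix"))
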