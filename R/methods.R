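#' Construct a DominantGenotypes object
#'
#' @param geno numeric/integer matrix, individuals in rows (rownames = ids),
#'   loci in columns (colnames = locus ids), entries 0/1/\code{NA}.
#' @return a \linkS4class{DominantGenotypes}.
#' @examples
#' g <- DominantGenotypes(matrix(c(1, 0, 1, 1, 0, 0), nrow = 3, byrow = TRUE,
#'        dimnames = list(c("a", "b", "c"), c("L1", "L2"))))
#' individualIds(g)
#' @export
DominantGenotypes <- function(geno) {
  storage.mode(geno) <- "double"
  if (ncol(geno) == 0L && is.null(colnames(geno)))
    dimnames(geno) <- list(rownames(geno), character(0))
  new("DominantGenotypes", geno = geno)
}

#' @rdname DominantGenotypes-class
#' @export
setMethod("individualIds", "DominantGenotypes", function(x) rownames(x@geno))

#' @rdname DominantGenotypes-class
#' @export
setMethod("locusIds", "DominantGenotypes",
          function(x) colnames(x@geno) %||% character(0))

#' @rdname DominantGenotypes-class
#' @export
setMethod("genotypeValues", "DominantGenotypes", function(x) x@geno)

#' @rdname DominantGenotypes-class
#' @export
setMethod("dim", "DominantGenotypes", function(x) dim(x@geno))

setMethod("show", "DominantGenotypes", function(object) {
  g <- object@geno
  cat(sprintf("DominantGenotypes: %d individuals x %d loci (%d missing entries)\n",
              nrow(g), ncol(g), sum(is.na(g))))
})

#' Construct a SampleTable
#'
#' @param data data.frame with columns \code{id}, \code{lon}, \code{lat},
#'   \code{association} plus environmental columns.
#' @param envVars names of the environmental columns; by default every
#'   numeric column other than \code{lon}/\code{lat}.
#' @return a \linkS4class{SampleTable}.
#' @export
SampleTable <- function(data, envVars = NULL) {
  data <- as.data.frame(data)
  data$id <- as.character(data$id)
  if (is.null(envVars)) {
    cand <- setdiff(names(data), c("id", "lon", "lat", "association"))
    envVars <- cand[vapply(data[cand], is.numeric, logical(1))]
  }
  new("SampleTable", data = data, envVars = as.character(envVars))
}

#' @rdname SampleTable-class
#' @param x a \code{SampleTable}.
#' @export
setMethod("individualIds", "SampleTable", function(x) x@data$id)

#' Environmental variable names of a SampleTable
#' @param x a \linkS4class{SampleTable}.
#' @export
envVars <- function(x) x@envVars

#' Underlying data.frame of a SampleTable
#' @param x a \linkS4class{SampleTable}.
#' @export
sampleData <- function(x) x@data

setMethod("show", "SampleTable", function(object) {
  cat(sprintf("SampleTable: %d individuals, %d environmental variables (%s), %d associations\n",
              nrow(object@data), length(object@envVars),
              paste(utils::head(object@envVars, 3), collapse = ", "),
              length(unique(object@data$association))))
})

#' @rdname PairwiseMatrix-class
#' @export
setMethod("individualIds", "PairwiseMatrix", function(x) x@ids)

#' @rdname PairwiseMatrix-class
#' @export
setMethod("pairValues", "PairwiseMatrix", function(x) x@values)

#' @rdname PairwiseMatrix-class
#' @export
setMethod("matrixKind", "PairwiseMatrix", function(x) x@kind)

#' @rdname PairwiseMatrix-class
#' @export
setMethod("dim", "PairwiseMatrix", function(x) dim(x@values))

setMethod("show", "PairwiseMatrix", function(object) {
  v <- unfold(object)
  cat(sprintf("PairwiseMatrix (%s): %d individuals; off-diagonal range [%.4g, %.4g]\n",
              object@kind, length(object@ids), min(v), max(v)))
})

#' @rdname unfold
#' @export
setMethod("unfold", "matrix", function(x, ...) {
  if (nrow(x) != ncol(x)) stop("matrix must be square")
  off <- x
  diag(off) <- 0
  if (any(abs(off - t(off)) > 1e-8, na.rm = TRUE))
    stop("matrix is asymmetric beyond tolerance; cannot unfold")
  tx <- t(x)
  v <- tx[upper.tri(tx)] # == row-major strict lower triangle of x
  if (!is.null(rownames(x))) names(v) <- pairNames(rownames(x))
  v
})

#' @rdname unfold
#' @export
setMethod("unfold", "PairwiseMatrix", function(x, ...) {
  v <- unfold(x@values)
  names(v) <- pairNames(x@ids)
  v
})

#' Refold an unfolded vector into a symmetric matrix
#'
#' Inverse of \code{\link{unfold}} up to the (unstored) diagonal, which is set
#' to \code{diagValue}.
#'
#' @param v vector of length n(n-1)/2 in unfold order.
#' @param ids individual ids (length n).
#' @param diagValue value for the diagonal (default 0).
#' @return symmetric matrix with dimnames \code{ids}.
#' @export
refold <- function(v, ids, diagValue = 0) {
  n <- length(ids)
  if (length(v) != n * (n - 1L) / 2L)
    stop("vector length does not match n(n-1)/2")
  m <- matrix(diagValue, n, n, dimnames = list(ids, ids))
  tm <- t(m)
  tm[upper.tri(tm)] <- v
  m <- t(tm)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

#' Predictor set constructor
#'
#' @param predictors named list of \linkS4class{PairwiseMatrix} objects over
#'   identical individuals. Conventional names: \code{"geography"} for the
#'   isolation-by-distance predictor, \code{"community"} for
#'   isolation-by-community, environmental predictors by variable name or
#'   \code{"environment_combined"}.
#' @param standardized,scaling,vifLog bookkeeping slots, normally left at
#'   their defaults and filled by \code{\link{standardizePredictors}} and
#'   \code{\link{vifScreen}}.
#' @return a \linkS4class{PredictorSet}.
#' @export
PredictorSet <- function(predictors, standardized = FALSE,
                         scaling = NULL, vifLog = NULL) {
  new("PredictorSet", predictors = predictors, standardized = standardized,
      scaling = scaling %||% data.frame(name = character(), mean = numeric(),
                                        sd = numeric()),
      vifLog = vifLog %||% data.frame(name = character(), vif = numeric(),
                                      dropped = logical()))
}

#' @rdname PredictorSet-class
#' @param x a \code{PredictorSet}.
#' @export
setMethod("names", "PredictorSet", function(x) names(x@predictors))

#' @rdname PredictorSet-class
#' @export
setMethod("length", "PredictorSet", function(x) length(x@predictors))

#' @rdname PredictorSet-class
#' @param i predictor name or index.
#' @export
setMethod("[[", "PredictorSet", function(x, i) x@predictors[[i]])

#' @rdname PredictorSet-class
#' @export
setMethod("individualIds", "PredictorSet", function(x) x@predictors[[1L]]@ids)

#' VIF screening log of a PredictorSet
#' @param x a \linkS4class{PredictorSet}.
#' @export
vifLog <- function(x) x@vifLog

#' Standardization parameters of a PredictorSet
#' @param x a \linkS4class{PredictorSet}.
#' @export
scalingParams <- function(x) x@scaling

setMethod("show", "PredictorSet", function(object) {
  cat(sprintf("PredictorSet: %d predictors (%s); standardized: %s; VIF-dropped: %s\n",
              length(object@predictors),
              paste(names(object@predictors), collapse = ", "),
              object@standardized,
              if (any(object@vifLog$dropped))
                paste(object@vifLog$name[object@vifLog$dropped], collapse = ", ")
              else "none"))
})

setMethod("show", "RasterGrid", function(object) {
  cat(sprintf("RasterGrid: %d x %d cells of %g, origin (%g, %g), %d NODATA\n",
              object@nrows, object@ncols, object@cellsize,
              object@xllcorner, object@yllcorner, sum(is.na(object@values))))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: n=%d, loci=%d, side=%gm, %d env vars, %d associations\n",
              object@n, object@loci, object@side, object@nEnv,
              object@nAssociations))
  cat(sprintf("  effects: gammaG=%g (rhoG=%gm), gammaE=%g, gammaC=%g%s; seed=%d\n",
              object@gammaG, object@rhoG, object@gammaE, object@gammaC,
              if (object@counterGradient) " [counter-gradient]" else "",
              object@seed))
})
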