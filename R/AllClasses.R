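#' @import methods
NULL

#' Dominant binary genotypes
#'
#' Individuals-by-loci matrix of dominant marker phenotypes (band
#' presence/absence, 0/1, \code{NA} for missing), as produced by AFLP-style
#' scoring. Heterozygotes are indistinguishable from dominant homozygotes, so
#' a 1 means "band present" and a 0 "homozygous band-absent" under
#' Hardy-Weinberg assumptions.
#'
#' @slot geno numeric matrix with unique individual ids as rownames and unique
#'   locus ids as colnames; entries 0, 1 or \code{NA}.
#' @export
setClass("DominantGenotypes", representation(geno = "matrix"))

setValidity("DominantGenotypes", function(object) {
  g <- object@geno
  msg <- character()
  if (is.null(rownames(g)) || (ncol(g) > 0L && is.null(colnames(g))))
    msg <- c(msg, "genotype matrix must have individual (row) and locus (column) names")
  if (!is.null(rownames(g)) && anyDuplicated(rownames(g)))
    msg <- c(msg, sprintf("duplicated individual id: %s",
                          rownames(g)[duplicated(rownames(g))][1L]))
  if (!is.null(colnames(g)) && anyDuplicated(colnames(g)))
    msg <- c(msg, sprintf("duplicated locus id: %s",
                          colnames(g)[duplicated(colnames(g))][1L]))
  if (nrow(g) < 2L)
    msg <- c(msg, "at least 2 individuals are required")
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% c(0, 1)))
    msg <- c(msg, "genotype values must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' Per-individual sample metadata
#'
#' One row per individual: id, geographic coordinates in decimal degrees, a
#' vegetation-association label, and a named set of environmental variables
#' (altitude, distance to creek/coast, light, soil water, soil pH, wind
#' exposure, slope, ruggedness, ... -- whatever the study measured).
#'
#' @slot data data.frame with columns \code{id}, \code{lon}, \code{lat},
#'   \code{association} and one numeric column per environmental variable.
#' @slot envVars character vector naming the environmental columns.
#' @export
setClass("SampleTable", representation(data = "data.frame", envVars = "character"))

setValidity("SampleTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("id", "lon", "lat", "association")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$id))
    msg <- c(msg, sprintf("duplicated individual id: %s", d$id[duplicated(d$id)][1L]))
  if (!all(is.finite(d$lon)) || !all(is.finite(d$lat)))
    msg <- c(msg, "coordinates must be finite")
  bad <- setdiff(object@envVars, names(d))
  if (length(bad))
    msg <- c(msg, sprintf("environmental variable(s) not in table: %s",
                          paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Symmetric pairwise matrix keyed by individual ids
#'
#' Holds either a kinship matrix (diagonal unused, stored as \code{NA}) or a
#' distance/dissimilarity matrix (zero diagonal, non-negative entries;
#' Jaccard dissimilarities additionally bounded by 1).
#'
#' @slot ids character vector of individual ids (row/column order).
#' @slot values symmetric numeric matrix.
#' @slot kind one of \code{"kinship"}, \code{"distance"},
#'   \code{"dissimilarity"}.
#' @export
setClass("PairwiseMatrix",
         representation(ids = "character", values = "matrix", kind = "character"))

setValidity("PairwiseMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (length(object@kind) != 1L ||
      !object@kind %in% c("kinship", "distance", "dissimilarity"))
    msg <- c(msg, "kind must be one of 'kinship', 'distance', 'dissimilarity'")
  if (nrow(v) != ncol(v) || nrow(v) != length(object@ids))
    msg <- c(msg, "values must be square with one row per id")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "ids must be unique")
  off <- v
  diag(off) <- 0
  if (any(abs(off - t(off)) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "matrix is not symmetric (tolerance 1e-12)")
  if (length(object@kind) == 1L && object@kind != "kinship") {
    if (any(abs(diag(v)) > 1e-12))
      msg <- c(msg, "distance/dissimilarity diagonal must be zero")
    if (any(v < -1e-12, na.rm = TRUE))
      msg <- c(msg, "distance/dissimilarity entries must be non-negative")
    if (length(object@kind) == 1L && object@kind == "dissimilarity" &&
        any(v > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "dissimilarity entries must be <= 1")
  }
  if (length(msg)) msg else TRUE
})

#' ESRI ASCII grid raster
#'
#' @slot ncols,nrows grid dimensions.
#' @slot xllcorner,yllcorner coordinates of the lower-left corner.
#' @slot cellsize cell edge length (> 0).
#' @slot nodataValue value standing for missing cells in the file.
#' @slot values numeric matrix \code{nrows x ncols}; the FIRST row is the
#'   northernmost (ESRI ASCII convention); \code{NA} marks NODATA cells.
#' @export
setClass("RasterGrid",
         representation(ncols = "integer", nrows = "integer",
                        xllcorner = "numeric", yllcorner = "numeric",
                        cellsize = "numeric", nodataValue = "numeric",
                        values = "matrix"))

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (object@cellsize <= 0) msg <- c(msg, "cellsize must be > 0")
  if (nrow(object@values) != object@nrows || ncol(object@values) != object@ncols)
    msg <- c(msg, "value matrix dimensions must match nrows x ncols")
  if (length(msg)) msg else TRUE
})

#' Named set of explanatory pairwise matrices
#'
#' The explanatory side of the multiple matrix regression: geographic
#' distance ("geography"), community dissimilarity ("community") and one or
#' more environmental distance matrices (per variable, or
#' "environment_combined" for the PCA-combined metric), all over the same
#' individuals in the same order.
#'
#' @slot predictors named list of \linkS4class{PairwiseMatrix}.
#' @slot standardized have the unfolded vectors been standardized?
#' @slot scaling data.frame (name, mean, sd) of standardization parameters,
#'   on the unfolded-vector scale; includes the response when standardized
#'   together.
#' @slot vifLog data.frame (name, vif, dropped) recording collinearity
#'   screening decisions.
#' @export
setClass("PredictorSet",
         representation(predictors = "list", standardized = "logical",
                        scaling = "data.frame", vifLog = "data.frame"),
         prototype(standardized = FALSE,
                   scaling = data.frame(name = character(), mean = numeric(),
                                        sd = numeric()),
                   vifLog = data.frame(name = character(), vif = numeric(),
                                       dropped = logical())))

setValidity("PredictorSet", function(object) {
  ps <- object@predictors
  msg <- character()
  if (!length(ps)) return("at least one predictor is required")
  if (is.null(names(ps)) || anyDuplicated(names(ps)) || any(!nzchar(names(ps))))
    msg <- c(msg, "predictors must have unique non-empty names")
  if (!all(vapply(ps, is, logical(1), "PairwiseMatrix")))
    msg <- c(msg, "all predictors must be PairwiseMatrix objects")
  else {
    id0 <- ps[[1L]]@ids
    same <- vapply(ps, function(p) identical(p@ids, id0), logical(1))
    if (!all(same))
      msg <- c(msg, "all predictor matrices must share the same ids in the same order")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic-data generator configuration
#'
#' The stated world of the simulator: individuals scattered uniformly over a
#' square landscape; environmental variables realized as a linear gradient or
#' a smooth Gaussian random field; vegetation associations obtained by
#' thresholding one environmental variable into contiguous classes; dominant
#' genotypes drawn under Hardy-Weinberg with locus-wise allele frequencies
#' perturbed on the logit scale by a spatial field (isolation-by-distance
#' signal, sd \code{gammaG}), an environmental slope (isolation-by-environment
#' signal, sd \code{gammaE}) and an association-level effect
#' (isolation-by-community signal, sd \code{gammaC}).
#'
#' @slot n number of individuals (>= 10).
#' @slot loci number of loci (>= 50).
#' @slot side landscape side length in metres.
#' @slot nEnv number of environmental variables.
#' @slot envForm per-variable spatial form, \code{"gradient"} or
#'   \code{"field"} (recycled to \code{nEnv}).
#' @slot rhoEnv range (m) of the squared-exponential covariance of
#'   environmental fields.
#' @slot nAssociations number of vegetation associations (contiguous classes
#'   of \code{assocVar}).
#' @slot assocVar index of the environmental variable whose quantiles define
#'   the associations.
#' @slot envEffectVar index of the environmental variable carrying the
#'   \code{gammaE} effect.
#' @slot gammaG sd (logit scale) of the spatial genetic field; \code{rhoG}
#'   its range in metres.
#' @slot gammaE sd of the per-locus environmental slope (per sd of the
#'   standardized variable, logit scale).
#' @slot gammaC sd of the per-locus association effect (logit scale).
#' @slot gammaCG sd (logit scale) of a counter-gradient effect: an
#'   anisotropic genetic field whose correlation is long-ranged ALONG the
#'   gradient variable \code{cgVar} and short-ranged (\code{rhoG}) across it,
#'   a caricature of dispersal following the gradient axis (e.g. wind). At a
#'   given geographic distance, pairs farther apart along the gradient are
#'   then MORE related, producing a positive (counter-gradient) coefficient
#'   on that variable once geography is controlled.
#' @slot cgVar index of the (gradient-form) environmental variable carrying
#'   the \code{gammaCG} effect.
#' @slot baseFreqRange range of the uniform base allele frequency per locus.
#' @slot speciesPool,speciesPerAssociation global species pool size and
#'   species per association; neighbouring associations get overlapping
#'   windows of the pool so Jaccard overlap decays with environmental
#'   separation.
#' @slot seed integer seed; a fixed seed makes every output byte-identical.
#' @export
setClass("SimulationConfig",
         representation(n = "integer", loci = "integer", side = "numeric",
                        nEnv = "integer", envForm = "character",
                        rhoEnv = "numeric", nAssociations = "integer",
                        assocVar = "integer", envEffectVar = "integer",
                        gammaG = "numeric", rhoG = "numeric",
                        gammaE = "numeric", gammaC = "numeric",
                        gammaCG = "numeric", cgVar = "integer",
                        baseFreqRange = "numeric",
                        speciesPool = "integer",
                        speciesPerAssociation = "integer",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@n < 10L) msg <- c(msg, "n must be >= 10")
  if (object@loci < 50L) msg <- c(msg, "loci must be >= 50")
  if (object@side <= 0) msg <- c(msg, "side must be > 0")
  if (object@nEnv < 1L) msg <- c(msg, "nEnv must be >= 1")
  if (!all(object@envForm %in% c("gradient", "field")))
    msg <- c(msg, "envForm entries must be 'gradient' or 'field'")
  if (any(c(object@gammaG, object@gammaE, object@gammaC, object@gammaCG) < 0))
    msg <- c(msg, "effect sds must be >= 0")
  if (object@gammaCG > 0 &&
      (object@cgVar < 1L || object@cgVar > object@nEnv ||
       object@envForm[object@cgVar] != "gradient"))
    msg <- c(msg, "gammaCG requires cgVar to index a gradient-form variable")
  if (object@nAssociations < 1L) msg <- c(msg, "nAssociations must be >= 1")
  if (object@assocVar < 1L || object@assocVar > object@nEnv)
    msg <- c(msg, "assocVar must index an environmental variable")
  if (object@envEffectVar < 1L || object@envEffectVar > object@nEnv)
    msg <- c(msg, "envEffectVar must index an environmental variable")
  if (length(object@baseFreqRange) != 2L ||
      object@baseFreqRange[1L] <= 0 || object@baseFreqRange[2L] >= 1 ||
      diff(object@baseFreqRange) < 0)
    msg <- c(msg, "baseFreqRange must be an increasing pair inside (0, 1)")
  if (object@speciesPerAssociation > object@speciesPool)
    msg <- c(msg, "speciesPerAssociation cannot exceed speciesPool")
  if (length(msg)) msg else TRUE
})
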