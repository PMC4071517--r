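#' Pairwise geographic distances between individuals
#'
#' Great-circle (haversine) distance in metres on a sphere of radius
#' 6,371,000 m; planar Euclidean distance on the raw coordinates is available
#' for projected inputs. At a within-island scale the two agree to well under
#' 0.1\%.
#'
#' @param samples a \linkS4class{SampleTable} with \code{lon}/\code{lat} in
#'   decimal degrees (haversine) or projected metres (euclidean).
#' @param method \code{"haversine"} (default) or \code{"euclidean"}.
#' @return a \linkS4class{PairwiseMatrix} of kind \code{"distance"}.
#' @export
geographicDistances <- function(samples, method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  d <- sampleData(samples)
  if (method == "haversine") {
    if (any(abs(d$lat) > 90) || any(abs(d$lon) > 180))
      stop("coordinates out of range: |lat| <= 90 and |lon| <= 180 required")
    m <- haversineMatrix(d$lon, d$lat)
  } else {
    m <- as.matrix(stats::dist(cbind(d$lon, d$lat)))
  }
  newPairwiseMatrix(m, d$id, "distance")
}

haversineMatrix <- function(lon, lat, radius = 6371000) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  m <- 2 * radius * asin(sqrt(a))
  diag(m) <- 0
  m
}

#' Northeasterly wind-exposure transform of slope aspect
#'
#' Converts a compass aspect (degrees clockwise from north) into angular
#' closeness to the prevailing northeasterly wind direction (45 deg),
#' rescaled so a southwest aspect (225 deg, fully sheltered) maps to 0 and a
#' northeast aspect (45 deg, fully exposed) maps to 180.
#'
#' @param aspect aspect in degrees, in [0, 360).
#' @return exposure in [0, 180].
#' @export
windExposure <- function(aspect) {
  if (any(aspect < 0 | aspect >= 360))
    stop("aspect must lie in [0, 360)")
  180 - abs(((aspect - 45 + 180) %% 360) - 180)
}

#' Per-variable environmental distance matrices
#'
#' One matrix per environmental variable, entries \eqn{|v_i - v_j|}
#' (Euclidean distance in one dimension).
#'
#' @param samples a \linkS4class{SampleTable}.
#' @param variables variable names (default: all of \code{envVars(samples)}).
#' @return a \linkS4class{PredictorSet} with one predictor per variable.
#' @export
perVariableDistances <- function(samples, variables = envVars(samples)) {
  d <- sampleData(samples)
  miss <- setdiff(variables, names(d))
  if (length(miss))
    stop(sprintf("variable(s) not in sample table: %s", paste(miss, collapse = ", ")))
  ps <- lapply(variables, function(v) {
    vals <- d[[v]]
    if (anyNA(vals))
      stop(sprintf("missing value of '%s' for individual '%s'",
                   v, d$id[which(is.na(vals))[1L]]))
    newPairwiseMatrix(abs(outer(vals, vals, "-")), d$id, "distance")
  })
  names(ps) <- variables
  PredictorSet(ps)
}

#' PCA-combined environmental distance
#'
#' Environmental variables are centred and scaled to unit variance, rotated
#' by principal component analysis (\code{stats::prcomp}), and individuals'
#' scores on the retained components are compared by Euclidean distance.
#' With all components retained (the default) the rotation is orthogonal and
#' the result equals the Euclidean distance on the standardized variables
#' directly.
#'
#' @param samples a \linkS4class{SampleTable}.
#' @param variables variable names (default all).
#' @param nComponents number of leading components to retain;
#'   \code{NULL} (default) retains all.
#' @return a \linkS4class{PairwiseMatrix} of kind \code{"distance"}.
#' @export
combinedEnvironmentDistance <- function(samples, variables = envVars(samples),
                                        nComponents = NULL) {
  d <- sampleData(samples)
  if (length(variables) < 2L) stop("at least 2 environmental variables required")
  X <- as.matrix(d[, variables, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance variable '%s' cannot be scaled",
                 variables[which(sds == 0)[1L]]))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- nComponents %||% ncol(pc$x)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  m <- as.matrix(stats::dist(scores))
  newPairwiseMatrix(m, d$id, "distance")
}

#' Jaccard community dissimilarity between individuals
#'
#' Each individual inherits the species set of its vegetation association;
#' the pairwise entry is \eqn{1 - |S_i \cap S_j| / |S_i \cup S_j|}.
#'
#' @param samples a \linkS4class{SampleTable}.
#' @param lookup named list mapping association label to species vector (see
#'   \code{\link{readAssociationLookup}}).
#' @return a \linkS4class{PairwiseMatrix} of kind \code{"dissimilarity"}.
#' @export
communityDistance <- function(samples, lookup) {
  d <- sampleData(samples)
  assoc <- as.character(d$association)
  miss <- setdiff(unique(assoc), names(lookup))
  if (length(miss))
    stop(sprintf("association(s) without lookup entry: %s",
                 paste(miss, collapse = ", ")))
  labs <- names(lookup)
  A <- length(labs)
  jac <- matrix(0, A, A, dimnames = list(labs, labs))
  for (a in seq_len(A)) for (b in seq_len(A)) {
    Sa <- unique(lookup[[a]]); Sb <- unique(lookup[[b]])
    jac[a, b] <- 1 - length(intersect(Sa, Sb)) / length(union(Sa, Sb))
  }
  m <- jac[assoc, assoc, drop = FALSE]
  newPairwiseMatrix(unname(m), d$id, "dissimilarity")
}

#' Standardize predictor and response vectors
#'
#' All matrices are unfolded to their lower-triangle pair vectors and each
#' vector (every predictor and the response) is transformed to mean 0, sd 1.
#' Standardizing the kinship response alongside the predictors makes effect
#' sizes dimensionless and comparable across runs/species; the scaling
#' parameters are retained for reporting on original scales.
#'
#' @param predictors a \linkS4class{PredictorSet}.
#' @param response a \linkS4class{PairwiseMatrix} (kinship) over the same
#'   individuals.
#' @return list with \code{predictors} (the standardized
#'   \linkS4class{PredictorSet}, scaling recorded), \code{response} (the
#'   standardized unfolded response vector) and \code{vectors} (named matrix
#'   of standardized predictor vectors, pairs x predictors).
#' @export
standardizePredictors <- function(predictors, response) {
  ids <- individualIds(predictors)
  if (!identical(ids, response@ids))
    stop("response ids do not match predictor ids")
  vecs <- vapply(names(predictors),
                 function(nm) unfold(predictors[[nm]]),
                 numeric(length(ids) * (length(ids) - 1L) / 2L))
  y <- unfold(response)
  std1 <- function(v, nm) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop(sprintf("zero-variance vector '%s' cannot be standardized", nm))
    (v - mean(v)) / s
  }
  Z <- vapply(colnames(vecs), function(nm) std1(vecs[, nm], nm),
              numeric(nrow(vecs)))
  ys <- std1(y, "response")
  scaling <- data.frame(
    name = c(colnames(vecs), "response"),
    mean = c(colMeans(vecs), mean(y)),
    sd = c(apply(vecs, 2L, stats::sd), stats::sd(y)),
    row.names = NULL)
  ps <- PredictorSet(predictors@predictors, standardized = TRUE,
                     scaling = scaling, vifLog = predictors@vifLog)
  list(predictors = ps, response = ys, vectors = Z)
}

#' Iterative collinearity screening by variance inflation factors
#'
#' The VIF of predictor j is \eqn{1/(1-R^2_j)} from the OLS regression of its
#' unfolded pair vector on all other retained predictors' vectors. While any
#' VIF exceeds the threshold, the predictor with the largest VIF is dropped
#' (ties broken toward the later predictor in declared order) and VIFs are
#' recomputed. VIFs are computed on the unfolded distance vectors -- the
#' objects that actually enter the regression; set \code{on = "raw"} to
#' screen raw per-individual variables instead (only meaningful for
#' per-variable environmental predictors).
#'
#' @param predictors a \linkS4class{PredictorSet} (>= 2 predictors for any
#'   screening to happen; a single predictor is returned unchanged).
#' @param threshold removal threshold (default 5).
#' @param samples optional \linkS4class{SampleTable}, required for
#'   \code{on = "raw"}.
#' @param on screen unfolded pair vectors (default) or raw variables.
#' @param quiet suppress removal messages.
#' @return the screened \linkS4class{PredictorSet}; \code{vifLog(x)} records
#'   every predictor's final VIF and any removals (with the VIF at removal).
#' @export
vifScreen <- function(predictors, threshold = 5, samples = NULL,
                      on = c("pairs", "raw"), quiet = FALSE) {
  on <- match.arg(on)
  nms <- names(predictors)
  if (on == "pairs") {
    X <- vapply(nms, function(nm) unfold(predictors[[nm]]),
                numeric(length(individualIds(predictors)) *
                        (length(individualIds(predictors)) - 1L) / 2L))
  } else {
    if (is.null(samples)) stop("samples required for on = 'raw'")
    d <- sampleData(samples)
    if (!all(nms %in% names(d)))
      stop("raw-variable screening requires per-variable predictors named after sample-table columns")
    X <- as.matrix(d[, nms, drop = FALSE])
  }
  vif1 <- function(keep, j) {
    y <- X[, keep[j]]
    fit <- stats::lm.fit(cbind(1, X[, keep[-j], drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  keep <- nms
  log <- data.frame(name = character(), vif = numeric(), dropped = logical())
  repeat {
    if (length(keep) < 2L) break
    vifs <- vapply(seq_along(keep), function(j) vif1(keep, j), numeric(1))
    names(vifs) <- keep
    if (all(vifs <= threshold)) break
    worst <- max(vifs)
    j <- max(which(vifs == worst)) # tie -> later predictor in declared order
    if (!quiet)
      message(sprintf("vifScreen: dropping '%s' (VIF = %.3g)", keep[j], vifs[j]))
    log <- rbind(log, data.frame(name = keep[j], vif = vifs[j], dropped = TRUE))
    keep <- keep[-j]
    if (!length(keep)) stop("all predictors removed by VIF screening")
  }
  finalVifs <- if (length(keep) >= 2L)
    vapply(seq_along(keep), function(j) vif1(keep, j), numeric(1))
  else rep(NA_real_, length(keep))
  log <- rbind(log, data.frame(name = keep, vif = finalVifs, dropped = FALSE))
  PredictorSet(predictors@predictors[keep],
               standardized = predictors@standardized,
               scaling = predictors@scaling, vifLog = log)
}
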