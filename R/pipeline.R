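#' Run the full three- or twelve-matrix analysis
#'
#' End-to-end individual-based test for isolation by distance (IBD),
#' environment (IBE) and community (IBC): genotype QC, kinship estimation,
#' predictor construction, standardization, collinearity screening (twelve
#' mode), all-subsets AICc model averaging, Mantel-style permutation
#' inference and FDR control.
#'
#' Modes mirror the two designs of the study this implements:
#' \describe{
#'   \item{\code{"three"}}{predictors are exactly geography, the PCA-combined
#'     environmental distance, and community dissimilarity.}
#'   \item{\code{"twelve"}}{geography, one distance matrix per environmental
#'     variable, and community; the environmental predictors are screened by
#'     variance inflation factor (> \code{vifThreshold} removed) before
#'     fitting, so with 10 variables at most 12 predictors enter.}
#' }
#' A term's final significance (\code{significant_final}) demands BOTH the
#' 95\% CI excluding zero AND an FDR-passed permutation p; the reported
#' \code{direction} is \code{"isolation"} (negative, significant final),
#' \code{"counter-gradient"} (positive, significant final) or \code{"none"}.
#'
#' @param genotypes a \linkS4class{DominantGenotypes} (replicate-filtered if
#'   replicate data exist; see \code{\link{filterLociByReplicates}}).
#' @param samples a \linkS4class{SampleTable} over the same individuals.
#' @param lookup association -> species list (for the community predictor).
#' @param mode \code{"three"} or \code{"twelve"}.
#' @param variables environmental variables to use (default all).
#' @param B permutations (default 1000).
#' @param vifThreshold VIF removal threshold (default 5; twelve mode only,
#'   applied to the environmental predictors as in the source design).
#' @param fdrLevel FDR level (default 0.05).
#' @param ciMultiplier CI half-width in SE units (default 1.96).
#' @param correction kinship correction variant (see
#'   \code{\link{kinshipMatrix}}).
#' @param averaging \code{"conditional"} or \code{"full"}.
#' @param geoMethod \code{"auto"} (default: haversine when coordinates look
#'   like decimal degrees, planar Euclidean otherwise), \code{"haversine"} or
#'   \code{"euclidean"}.
#' @param pSource use the empirical permutation p (default) or the
#'   normal-theory z p-value for FDR.
#' @param seed RNG seed for the permutation stream.
#' @param runId label written into the effects table.
#' @param outputDir if given, writes \code{effects.tsv}, \code{kinship.tsv}
#'   and \code{report.txt} there (byte-identical under identical config +
#'   seed).
#' @param quiet suppress progress messages.
#' @return list of class \code{"mmrrRun"}: \code{effects} (the effects
#'   table), \code{fits}, \code{perm}, \code{kinship}, \code{predictors},
#'   \code{report}.
#' @export
runAnalysis <- function(genotypes, samples, lookup, mode = c("three", "twelve"),
                        variables = envVars(samples), B = 1000,
                        vifThreshold = 5, fdrLevel = 0.05, ciMultiplier = 1.96,
                        correction = "dosage", averaging = "conditional",
                        geoMethod = c("auto", "haversine", "euclidean"),
                        pSource = c("empirical", "z"),
                        seed = 1, runId = "run1", outputDir = NULL,
                        quiet = TRUE) {
  mode <- match.arg(mode)
  geoMethod <- match.arg(geoMethod)
  pSource <- match.arg(pSource)
  gIds <- individualIds(genotypes)
  sIds <- individualIds(samples)
  if (!setequal(gIds, sIds)) {
    bad <- c(setdiff(gIds, sIds), setdiff(sIds, gIds))
    stop(sprintf("genotype/sample id mismatch: %s", paste(bad, collapse = ", ")))
  }
  sd0 <- sampleData(samples)
  samples <- SampleTable(sd0[match(gIds, sd0$id), , drop = FALSE],
                         envVars = envVars(samples))
  genotypes <- dropMonomorphic(genotypes, quiet = quiet)
  droppedLoci <- attr(genotypes, "dropped")
  kin <- kinshipMatrix(genotypes, correction = correction)

  if (geoMethod == "auto") {
    d <- sampleData(samples)
    geoMethod <- if (max(abs(d$lat)) <= 90 && max(abs(d$lon)) <= 180)
      "haversine" else "euclidean"
  }
  geo <- geographicDistances(samples, method = geoMethod)
  com <- communityDistance(samples, lookup)
  vifRecord <- data.frame(name = character(), vif = numeric(),
                          dropped = logical())
  if (mode == "three") {
    env <- combinedEnvironmentDistance(samples, variables)
    preds <- PredictorSet(list(geography = geo, environment_combined = env,
                               community = com))
  } else {
    envPs <- perVariableDistances(samples, variables)
    envPs <- vifScreen(envPs, threshold = vifThreshold, quiet = quiet)
    vifRecord <- vifLog(envPs)
    preds <- PredictorSet(c(list(geography = geo), envPs@predictors,
                            list(community = com)))
  }
  sp <- standardizePredictors(preds, kin)
  fits <- fitAllSubsets(sp$response, sp$vectors)
  eff <- averageEffects(fits, method = averaging, ciMultiplier = ciMultiplier)
  perm <- permutationTest(sp$response, sp$vectors, B = B, seed = seed,
                          method = averaging)
  stopifnot(identical(eff$term, perm$effects$term))
  pUse <- if (pSource == "empirical") perm$effects$p else perm$effects$p_z
  fdr <- fdrAdjust(pUse, level = fdrLevel)
  effects <- data.frame(run_id = runId, predictor = eff$term,
                        estimate = eff$estimate, se = eff$se,
                        ci_lo = eff$ci_lo, ci_hi = eff$ci_hi,
                        significant_ci = eff$significant_ci,
                        z = perm$effects$z, p = pUse, q = fdr$q,
                        significant_final = eff$significant_ci & fdr$discovery)
  effects$direction <- ifelse(!effects$significant_final, "none",
                              ifelse(effects$estimate < 0, "isolation",
                                     "counter-gradient"))
  report <- list(run_id = runId, mode = mode, seed = seed, B = B,
                 n_individuals = length(gIds),
                 n_loci = length(locusIds(genotypes)),
                 dropped_monomorphic = droppedLoci,
                 geo_method = geoMethod, correction = correction,
                 averaging = averaging, vif_threshold = vifThreshold,
                 vif_log = vifRecord, fdr_level = fdrLevel,
                 p_source = pSource,
                 scaling = scalingParams(sp$predictors))
  out <- structure(list(effects = effects, fits = fits, perm = perm,
                        kinship = kin, predictors = sp$predictors,
                        report = report), class = "mmrrRun")
  if (!is.null(outputDir)) writeRunOutputs(out, outputDir)
  out
}

writeRunOutputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$effects, file.path(dir, "effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  writePairwiseMatrix(run$kinship, file.path(dir, "kinship.tsv"))
  r <- run$report
  lines <- c(sprintf("run_id: %s", r$run_id),
             sprintf("mode: %s", r$mode),
             sprintf("seed: %d", r$seed),
             sprintf("permutations: %d", r$B),
             sprintf("individuals: %d", r$n_individuals),
             sprintf("loci_retained: %d", r$n_loci),
             sprintf("loci_dropped_monomorphic: %d", length(r$dropped_monomorphic)),
             sprintf("geo_method: %s", r$geo_method),
             sprintf("kinship_correction: %s", r$correction),
             sprintf("averaging: %s", r$averaging),
             sprintf("vif_threshold: %g", r$vif_threshold),
             sprintf("vif_removed: %s",
                     if (any(r$vif_log$dropped))
                       paste(sprintf("%s (%.3g)",
                                     r$vif_log$name[r$vif_log$dropped],
                                     r$vif_log$vif[r$vif_log$dropped]),
                             collapse = ", ")
                     else "none"),
             sprintf("fdr_level: %g", r$fdr_level),
             sprintf("p_source: %s", r$p_source))
  writeLines(lines, file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.mmrrRun <- function(x, ...) {
  r <- x$report
  cat(sprintf("mmrrRun '%s' (%s-matrix mode): %d individuals, %d loci, B = %d\n",
              r$run_id, r$mode, r$n_individuals, r$n_loci, r$B))
  print(x$effects[, c("predictor", "estimate", "se", "ci_lo", "ci_hi",
                      "p", "q", "significant_final", "direction")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

# Map a run's effects rows onto the three isolation classes:
# D = geography, C = community, E = everything environmental.
classSummary <- function(effects) {
  cls <- ifelse(effects$predictor == "geography", "D",
                ifelse(effects$predictor == "community", "C", "E"))
  vapply(c("D", "E", "C"), function(k) {
    dirs <- unique(effects$direction[cls == k])
    dirs <- dirs[dirs != "none"]
    if (!length(dirs)) "none"
    else if (length(dirs) == 1L) dirs
    else "both"
  }, character(1))
}

#' Compare three- and twelve-matrix classifications
#'
#' Per shared run id, tabulates which isolation classes (D = geographic,
#' E = environmental, C = community) the two designs agree on. Amalgamating
#' the environmental variables into one combined distance can attenuate or
#' flip individual-variable signals, so discordance here is itself a finding.
#'
#' @param effectsThree,effectsTwelve effects tables (or \code{"mmrrRun"}
#'   objects) from \code{\link{runAnalysis}} in the two modes, on the same
#'   dataset(s).
#' @return data.frame: run_id, class, direction_three, direction_twelve,
#'   agree.
#' @export
compareModes <- function(effectsThree, effectsTwelve) {
  if (inherits(effectsThree, "mmrrRun")) effectsThree <- effectsThree$effects
  if (inherits(effectsTwelve, "mmrrRun")) effectsTwelve <- effectsTwelve$effects
  shared <- intersect(unique(effectsThree$run_id), unique(effectsTwelve$run_id))
  if (!length(shared))
    stop("no shared run ids between the two effects tables")
  out <- lapply(shared, function(rid) {
    s3 <- classSummary(effectsThree[effectsThree$run_id == rid, ])
    s12 <- classSummary(effectsTwelve[effectsTwelve$run_id == rid, ])
    data.frame(run_id = rid, class = names(s3),
               direction_three = unname(s3), direction_twelve = unname(s12),
               agree = unname(s3 == s12))
  })
  do.call(rbind, out)
}
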