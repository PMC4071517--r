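#' Build a simulation configuration
#'
#' Defaults describe a neutral (all effect sds zero) population of 60
#' individuals scored at 200 dominant loci on a 1 km square landscape with 10
#' environmental variables realized as smooth Gaussian random fields (range
#' 50 m, the scale of fine terrain attributes mapped on a 10 m grid) and four
#' vegetation associations obtained by quantile-thresholding one field
#' variable. Isolation signals are switched on through the effect sds:
#' \code{gammaG} (spatially autocorrelated allele-frequency field, range
#' \code{rhoG}), \code{gammaE} (per-locus slope on one standardized
#' environmental variable), \code{gammaC} (association-level
#' allele-frequency effect), \code{gammaCG} (counter-gradient anisotropic
#' field along a gradient-form variable, see
#' \linkS4class{SimulationConfig}). Deterministic coordinate gradients
#' (\code{envForm = "gradient"}: x for odd variable indices, y for even) are
#' available for altitude-like variables; note that a gradient inside the
#' combined environmental metric couples it with geographic distance, which
#' is exactly the amalgamation artifact \code{\link{compareModes}} exposes.
#'
#' @param n,loci,side,nEnv,envForm,rhoEnv,nAssociations,assocVar,envEffectVar
#'   see \linkS4class{SimulationConfig}.
#' @param gammaG,rhoG,gammaE,gammaC,gammaCG,cgVar effect settings, see
#'   \linkS4class{SimulationConfig}.
#' @param baseFreqRange,speciesPool,speciesPerAssociation,seed see
#'   \linkS4class{SimulationConfig}.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(n = 60, loci = 200, side = 1000, nEnv = 10,
                             envForm = "field", rhoEnv = 50,
                             nAssociations = 4, assocVar = min(2, nEnv),
                             envEffectVar = min(3, nEnv),
                             gammaG = 0, rhoG = 250, gammaE = 0, gammaC = 0,
                             gammaCG = 0, cgVar = 1,
                             baseFreqRange = c(0.1, 0.9),
                             speciesPool = 30, speciesPerAssociation = 12,
                             seed = 1) {
  new("SimulationConfig", n = as.integer(n), loci = as.integer(loci),
      side = side, nEnv = as.integer(nEnv),
      envForm = rep_len(envForm, nEnv), rhoEnv = rhoEnv,
      nAssociations = as.integer(nAssociations),
      assocVar = as.integer(assocVar), envEffectVar = as.integer(envEffectVar),
      gammaG = gammaG, rhoG = rhoG, gammaE = gammaE, gammaC = gammaC,
      gammaCG = gammaCG, cgVar = as.integer(cgVar),
      baseFreqRange = baseFreqRange,
      speciesPool = as.integer(speciesPool),
      speciesPerAssociation = as.integer(speciesPerAssociation),
      seed = as.integer(seed))
}

envVarNames <- function(nEnv) {
  base <- c("altitude", "dist_creek", "dist_coast", "light", "soil_water",
            "soil_ph", "wind_exposure", "slope", "ruggedness", "microtopo")
  if (nEnv <= length(base)) base[seq_len(nEnv)]
  else c(base, paste0("env", seq_len(nEnv - length(base)) + length(base)))
}

# Lower-triangular factor L with L %*% t(L) = squared-exponential covariance
# of the point set; a small nugget keeps the Cholesky stable.
sqExpCholFactor <- function(x, y, rho, nugget = 1e-8) {
  D2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  C <- exp(-D2 / (2 * rho^2))
  diag(C) <- diag(C) + nugget
  t(chol(C))
}

#' Simulate a landscape, sample locations and community structure
#'
#' Individuals are placed uniformly at random on the square; each
#' environmental variable is a deterministic coordinate gradient or a
#' zero-mean unit-sd Gaussian random field (squared-exponential covariance,
#' range \code{rhoEnv}) realized at the sampled points; vegetation
#' associations are the quantile classes of variable \code{assocVar}; the
#' association -> species lookup draws each association a contiguous window
#' from a global species pool, positioned by association rank, so Jaccard
#' overlap decays with the associations' environmental separation.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param makeRasters also realize each environmental variable (and the
#'   association tessellation) on a \code{rasterCells} x \code{rasterCells}
#'   ESRI-style grid; individuals then take their containing cell's value, so
#'   \code{\link{extractAtPoints}} reproduces the sample table exactly.
#' @param rasterCells grid resolution per side when \code{makeRasters}.
#' @return list with \code{samples} (\linkS4class{SampleTable}; coordinates
#'   in metres stored as lon/lat for pipeline convenience -- use
#'   \code{method = "euclidean"} for geographic distances), \code{lookup}
#'   (association -> species list) and \code{rasters} (named list of
#'   \linkS4class{RasterGrid}, empty unless \code{makeRasters}).
#' @export
simulateLandscape <- function(config, makeRasters = FALSE, rasterCells = 25) {
  withSeed(config@seed, {
    n <- config@n
    side <- config@side
    x <- stats::runif(n, 0, side)
    y <- stats::runif(n, 0, side)
    vnames <- envVarNames(config@nEnv)
    rasters <- list()
    env <- matrix(0, n, config@nEnv, dimnames = list(NULL, vnames))
    if (makeRasters) {
      cs <- side / rasterCells
      centers <- (seq_len(rasterCells) - 0.5) * cs
      gx <- rep(centers, times = rasterCells)        # by row (north first)
      gy <- rep(rev(centers), each = rasterCells)
      Lg <- sqExpCholFactor(gx, gy, config@rhoEnv)
      for (v in seq_len(config@nEnv)) {
        vals <- if (config@envForm[v] == "gradient") {
          if (v %% 2L == 1L) gx else gy
        } else as.numeric(Lg %*% stats::rnorm(length(gx)))
        rast <- RasterGrid(matrix(vals, rasterCells, rasterCells, byrow = TRUE),
                           xllcorner = 0, yllcorner = 0, cellsize = cs)
        rasters[[vnames[v]]] <- rast
        env[, v] <- extractAtPoints(rast, x, y)
      }
    } else {
      Lp <- if (any(config@envForm == "field"))
        sqExpCholFactor(x, y, config@rhoEnv) else NULL
      for (v in seq_len(config@nEnv)) {
        env[, v] <- if (config@envForm[v] == "gradient") {
          if (v %% 2L == 1L) x else y
        } else as.numeric(Lp %*% stats::rnorm(n))
      }
    }
    A <- config@nAssociations
    av <- env[, config@assocVar]
    breaks <- stats::quantile(av, probs = seq(0, 1, length.out = A + 1L))
    breaks <- unique(breaks)
    breaks[1L] <- -Inf
    breaks[length(breaks)] <- Inf
    cls <- cut(av, breaks = breaks, labels = FALSE)
    A <- length(breaks) - 1L # degenerate quantiles can merge classes
    assoc <- paste0("A", cls)
    if (makeRasters) {
      rv <- rasters[[vnames[config@assocVar]]]@values
      rcls <- matrix(as.numeric(cut(as.numeric(t(rv)), breaks = breaks,
                                    labels = FALSE)),
                     nrow(rv), ncol(rv), byrow = TRUE)
      rasters[["association"]] <- RasterGrid(rcls, 0, 0, side / rasterCells)
    }
    pool <- sprintf("sp%02d", seq_len(config@speciesPool))
    per <- config@speciesPerAssociation
    lookup <- lapply(seq_len(A), function(r) {
      start <- if (A == 1L) 1L else
        1L + round((r - 1L) / (A - 1L) * (config@speciesPool - per))
      pool[start:(start + per - 1L)]
    })
    names(lookup) <- paste0("A", seq_len(A))
    d <- data.frame(id = sprintf("ind%03d", seq_len(n)), lon = x, lat = y,
                    association = assoc, env, check.names = FALSE)
    list(samples = SampleTable(d, envVars = vnames), lookup = lookup,
         rasters = rasters)
  })
}

#' Simulate dominant genotypes over a landscape
#'
#' Locus \eqn{l} gets a base allele frequency \eqn{p_{0l}} uniform on the
#' configured range; individual allele frequencies are perturbed on the logit
#' scale,
#' \deqn{logit(p_{il}) = logit(p_{0l}) + u_l(x_i, y_i) + b_l e_i + c_l(a_i),}
#' with \eqn{u_l} an independent zero-mean Gaussian random field per locus
#' (sd \code{gammaG}, range \code{rhoG}), \eqn{b_l \sim N(0, \gamma_E)}
#' multiplying the standardized environmental variable \code{envEffectVar},
#' and \eqn{c_l(a) \sim N(0, \gamma_C)} an association-level effect. The
#' dominant phenotype is \eqn{y_{il} \sim Bernoulli(1 - (1 - p_{il})^2)}
#' (band present unless homozygous band-absent, Hardy-Weinberg). Loci are
#' independent given the latent surfaces (unlinked markers).
#'
#' A positive \code{gammaCG} adds an anisotropic genetic field whose
#' correlation is long-ranged along the \code{cgVar} gradient axis and
#' short-ranged (\code{rhoG}) across it: dispersal effectively follows the
#' gradient, so at a given geographic distance individuals in MORE dissimilar
#' environments are MORE related -- the counter-gradient construction (a
#' wind-borne-dispersal caricature). It can be combined with an isolating
#' \code{gammaE} effect on another variable to build worlds with opposing
#' environmental signals.
#'
#' @param samples a \linkS4class{SampleTable} from
#'   \code{\link{simulateLandscape}}.
#' @param config the same \linkS4class{SimulationConfig}.
#' @param details also return the latent frequencies.
#' @return a \linkS4class{DominantGenotypes}; with \code{details = TRUE} a
#'   list \code{(genotypes, p0, pMat)} where \code{pMat} holds the realized
#'   per-individual allele frequencies.
#' @export
simulateGenotypes <- function(samples, config, details = FALSE) {
  withSeed(config@seed + 1L, {
    d <- sampleData(samples)
    n <- nrow(d)
    L <- config@loci
    p0 <- stats::runif(L, config@baseFreqRange[1L], config@baseFreqRange[2L])
    eta <- matrix(stats::qlogis(p0), n, L, byrow = TRUE)
    if (config@gammaG > 0) {
      Lch <- sqExpCholFactor(d$lon, d$lat, config@rhoG)
      eta <- eta + config@gammaG * (Lch %*% matrix(stats::rnorm(n * L), n, L))
    }
    vnames <- envVars(samples)
    if (config@gammaE > 0) {
      e <- d[[vnames[config@envEffectVar]]]
      e <- (e - mean(e)) / stats::sd(e)
      b <- stats::rnorm(L, 0, config@gammaE)
      eta <- eta + outer(e, b)
    }
    if (config@gammaCG > 0) {
      # anisotropic: flat along the cgVar gradient axis, range rhoG across it
      ortho <- if (config@cgVar %% 2L == 1L) d$lat else d$lon
      Lan <- sqExpCholFactor(ortho, rep(0, n), config@rhoG)
      eta <- eta + config@gammaCG * (Lan %*% matrix(stats::rnorm(n * L), n, L))
    }
    if (config@gammaC > 0) {
      a <- factor(d$association)
      cmat <- matrix(stats::rnorm(nlevels(a) * L, 0, config@gammaC),
                     nlevels(a), L)
      eta <- eta + cmat[as.integer(a), , drop = FALSE]
    }
    pMat <- stats::plogis(eta)
    fBand <- 1 - (1 - pMat)^2
    g <- matrix(stats::rbinom(n * L, 1L, fBand), n, L,
                dimnames = list(d$id, sprintf("L%04d", seq_len(L))))
    out <- DominantGenotypes(g)
    if (details) list(genotypes = out, p0 = p0, pMat = pMat) else out
  })
}

#' Simulate a complete ready-to-run dataset
#'
#' Landscape plus genotypes under one configuration; optionally written out
#' in exactly the formats the readers consume (genotypes.tsv, samples.tsv,
#' associations.tsv, one .asc per raster).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir optional output directory (created if needed).
#' @param makeRasters,rasterCells passed to \code{\link{simulateLandscape}}.
#' @return list with \code{genotypes}, \code{samples}, \code{lookup},
#'   \code{rasters}, and \code{paths} when \code{dir} is given.
#' @export
simulateDataset <- function(config, dir = NULL, makeRasters = FALSE,
                            rasterCells = 25) {
  land <- simulateLandscape(config, makeRasters = makeRasters,
                            rasterCells = rasterCells)
  geno <- simulateGenotypes(land$samples, config)
  out <- list(genotypes = geno, samples = land$samples, lookup = land$lookup,
              rasters = land$rasters)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genotypes = file.path(dir, "genotypes.tsv"),
                  samples = file.path(dir, "samples.tsv"),
                  lookup = file.path(dir, "associations.tsv"))
    writeGenotypes(geno, paths$genotypes)
    writeSampleTable(land$samples, paths$samples)
    writeAssociationLookup(land$lookup, paths$lookup)
    for (nm in names(land$rasters)) {
      p <- file.path(dir, paste0(nm, ".asc"))
      writeAsciiRaster(land$rasters[[nm]], p)
      paths[[paste0("raster_", nm)]] <- p
    }
    out$paths <- paths
  }
  out
}
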