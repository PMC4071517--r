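test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulationConfig(n = 15, loci = 60, seed = 9)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(genotypeValues(d1$genotypes), genotypeValues(d2$genotypes))
  expect_identical(sampleData(d1$samples), sampleData(d2$samples))
  expect_identical(d1$lookup, d2$lookup)
  # and the written files byte for byte
  dirA <- withr::local_tempdir(); dirB <- withr::local_tempdir()
  simulateDataset(cfg, dir = dirA)
  simulateDataset(cfg, dir = dirB)
  for (f in list.files(dirA))
    expect_identical(readLines(file.path(dirA, f)),
                     readLines(file.path(dirB, f)), label = f)
  # a different seed gives different data
  d3 <- simulateDataset(simulationConfig(n = 15, loci = 60, seed = 10))
  expect_false(identical(genotypeValues(d1$genotypes),
                         genotypeValues(d3$genotypes)))
})

test_that("the landscape realizes gradients, associations and species overlap", {
  cfg <- simulationConfig(n = 30, loci = 60, nEnv = 3,
                          envForm = c("gradient", "field", "field"),
                          nAssociations = 2, seed = 21)
  land <- simulateLandscape(cfg)
  d <- sampleData(land$samples)
  # pure x-gradient: per-variable distance perfectly rank-correlated with |dx|
  gd <- unfold(perVariableDistances(land$samples, "altitude")[["altitude"]])
  dx <- unfold(abs(outer(d$lon, d$lon, "-")))
  expect_equal(cor(unname(gd), dx, method = "spearman"), 1)
  expect_equal(unname(cor(d$altitude, d$lon)), 1)
  # two associations split at the median: every individual labelled
  expect_setequal(unique(d$association), c("A1", "A2"))
  expect_equal(sum(d$association == "A1"), 15)
  # species windows overlap less for more distant associations
  cfg4 <- simulationConfig(n = 40, loci = 60, nAssociations = 4, seed = 3)
  lk <- simulateLandscape(cfg4)$lookup
  jac <- function(a, b) 1 - length(intersect(a, b)) / length(union(a, b))
  expect_lt(jac(lk$A1, lk$A2), jac(lk$A1, lk$A3))
  expect_lte(jac(lk$A1, lk$A3), jac(lk$A1, lk$A4)) # saturates at disjoint
  expect_true(all(lengths(lk) == cfg4@speciesPerAssociation))
})

test_that("raster-backed landscapes agree with point extraction", {
  cfg <- simulationConfig(n = 25, loci = 60, nEnv = 2, seed = 13)
  land <- simulateLandscape(cfg, makeRasters = TRUE, rasterCells = 20)
  d <- sampleData(land$samples)
  expect_named(land$rasters, c("altitude", "dist_creek", "association"))
  for (v in c("altitude", "dist_creek"))
    expect_equal(extractAtPoints(land$rasters[[v]], d$lon, d$lat), d[[v]])
  acls <- extractAtPoints(land$rasters[["association"]], d$lon, d$lat)
  expect_equal(paste0("A", acls), d$association)
  # ascii round-trip preserves the grid
  f <- withr::local_tempfile(fileext = ".asc")
  writeAsciiRaster(land$rasters[["altitude"]], f)
  expect_equal(readAsciiRaster(f)@values, land$rasters[["altitude"]]@values,
               tolerance = 1e-12)
})

test_that("null genotypes follow the dominant Hardy-Weinberg expectation", {
  cfg <- simulationConfig(n = 200, loci = 400, seed = 31)
  land <- simulateLandscape(cfg)
  sim <- simulateGenotypes(land$samples, cfg, details = TRUE)
  fObs <- colMeans(genotypeValues(sim$genotypes))
  fExp <- 1 - (1 - sim$p0)^2
  # per-locus binomial tolerance: all z-scores within 4 sd
  z <- (fObs - fExp) / sqrt(fExp * (1 - fExp) / cfg@n)
  expect_lt(max(abs(z)), 4.5)
  expect_lt(abs(mean(fObs - fExp)), 0.005)
  # with all effects zero the latent frequencies are constant per locus
  expect_equal(max(apply(sim$pMat, 2, sd)), 0)
})

test_that("a spatial genetic field produces isolation by distance", {
  cfg <- simulationConfig(n = 50, loci = 150, gammaG = 0.8, seed = 41)
  ds <- simulateDataset(cfg)
  g <- dropMonomorphic(ds$genotypes, quiet = TRUE)
  k <- unfold(kinshipMatrix(g))
  gd <- unfold(geographicDistances(ds$samples, method = "euclidean"))
  ct <- cor.test(k, gd, method = "spearman", exact = FALSE)
  expect_lt(ct$estimate, -0.2)
  expect_lt(ct$p.value, 1e-10)
})

test_that("an environmental effect produces isolation by environment", {
  cfg <- simulationConfig(n = 50, loci = 150, gammaE = 0.8, seed = 43)
  ds <- simulateDataset(cfg)
  g <- dropMonomorphic(ds$genotypes, quiet = TRUE)
  k <- unfold(kinshipMatrix(g))
  ed <- unfold(perVariableDistances(ds$samples, "dist_coast")[["dist_coast"]])
  ct <- cor.test(k, ed, method = "spearman", exact = FALSE)
  expect_lt(ct$estimate, -0.2)
  # and geography stays close to uninformative in this world
  gd <- unfold(geographicDistances(ds$samples, method = "euclidean"))
  expect_lt(abs(cor(k, gd, method = "spearman")), 0.15)
})

test_that("configuration validity catches impossible worlds", {
  expect_error(simulationConfig(n = 5), "n must be >= 10")
  expect_error(simulationConfig(loci = 10), "loci must be >= 50")
  expect_error(simulationConfig(gammaG = -1), "effect sds")
  expect_error(simulationConfig(baseFreqRange = c(0, 0.9)), "baseFreqRange")
  expect_error(simulationConfig(assocVar = 99), "assocVar")
  expect_error(simulationConfig(gammaCG = 0.5), "gradient-form")
  expect_error(simulationConfig(speciesPerAssociation = 40), "speciesPool")
})
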