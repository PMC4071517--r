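test_that("great-circle distances match the closed form and symmetry", {
  s <- SampleTable(data.frame(id = c("a", "b", "c"),
                              lon = c(0, 0, 10), lat = c(0, 1, -5),
                              association = "x", altitude = 1:3))
  d <- geographicDistances(s)
  expect_s4_class(d, "PairwiseMatrix")
  # one degree of latitude on a 6371 km sphere: R * pi / 180
  expect_equal(pairValues(d)["a", "b"], 6371000 * pi / 180, tolerance = 1e-9)
  expect_equal(pairValues(d)["a", "b"], 111194.93, tolerance = 1e-7)
  expect_identical(pairValues(d)["c", "a"], pairValues(d)["a", "c"])
  expect_equal(diag(pairValues(d)), c(a = 0, b = 0, c = 0))

  bad <- SampleTable(data.frame(id = "a", lon = 500, lat = 0,
                                association = "x", altitude = 1))
  expect_error(geographicDistances(bad), "out of range")
  # projected metric coordinates use the planar option
  expect_equal(pairValues(geographicDistances(bad, method = "euclidean"))[1, 1], 0)
})

test_that("wind exposure rescales angular closeness to northeast", {
  expect_equal(windExposure(225), 0)   # sheltered southwest aspect
  expect_equal(windExposure(45), 180)  # fully exposed northeast aspect
  expect_equal(windExposure(135), 90)  # 90 degrees off the wind axis
  expect_equal(windExposure(315), 90)
  expect_equal(windExposure(0), 135)
  expect_error(windExposure(360), "\\[0, 360\\)")
  expect_error(windExposure(-1), "\\[0, 360\\)")
  a <- seq(0, 359.5, by = 0.5)
  expect_true(all(windExposure(a) >= 0 & windExposure(a) <= 180))
})

test_that("per-variable distances are absolute differences", {
  s <- SampleTable(data.frame(id = c("a", "b"), lon = 0:1, lat = 0:1,
                              association = "x",
                              altitude = c(100, 350), soil_ph = c(5, 5)))
  ps <- perVariableDistances(s)
  expect_equal(names(ps), c("altitude", "soil_ph"))
  expect_equal(pairValues(ps[["altitude"]])["a", "b"], 250)
  expect_equal(pairValues(ps[["soil_ph"]])["a", "b"], 0)

  s2 <- SampleTable(data.frame(id = c("a", "b"), lon = 0:1, lat = 0:1,
                               association = "x", altitude = c(1, NA)))
  expect_error(perVariableDistances(s2), "'altitude'.*'b'")
})

test_that("PCA-combined distance equals Euclidean on standardized variables", {
  # 3 individuals x 2 variables: distances {5, 0, 5} up to variance scaling
  s <- SampleTable(data.frame(id = c("a", "b", "c"), lon = 0, lat = 0,
                              association = "x",
                              v1 = c(0, 3, 0), v2 = c(0, 4, 0)))
  d <- combinedEnvironmentDistance(s, c("v1", "v2"))
  direct <- as.matrix(dist(scale(cbind(c(0, 3, 0), c(0, 4, 0)))))
  expect_equal(unname(pairValues(d)), unname(direct), tolerance = 1e-12)
  expect_equal(pairValues(d)["a", "c"], 0)
  expect_equal(pairValues(d)["a", "b"], pairValues(d)["b", "c"])

  expect_error(combinedEnvironmentDistance(s, "v1"), "at least 2")
  s0 <- SampleTable(data.frame(id = c("a", "b"), lon = 0, lat = 0,
                               association = "x", v1 = c(1, 1), v2 = c(1, 2)))
  expect_error(combinedEnvironmentDistance(s0, c("v1", "v2")),
               "zero-variance.*v1")
})

test_that("community distance is Jaccard on association species sets", {
  s <- SampleTable(data.frame(id = c("a", "b", "c"), lon = 0, lat = 0,
                              association = c("A1", "A2", "A1"),
                              altitude = 1:3))
  lk <- list(A1 = c("A", "B", "C"), A2 = c("B", "C", "D"))
  cm <- communityDistance(s, lk)
  expect_equal(matrixKind(cm), "dissimilarity")
  expect_equal(pairValues(cm)["a", "c"], 0)    # same association
  expect_equal(pairValues(cm)["a", "b"], 0.5)  # 1 - 2/4
  lkDisjoint <- list(A1 = c("A", "B"), A2 = c("C", "D"))
  expect_equal(pairValues(communityDistance(s, lkDisjoint))["a", "b"], 1)
  expect_error(communityDistance(s, list(A1 = "A")), "A2")
})

test_that("Jaccard dissimilarities agree with vegan and satisfy the triangle inequality", {
  skip_if_not_installed("vegan")
  withr::with_seed(31, {
    pool <- paste0("sp", 1:12)
    lk <- lapply(1:5, function(i) sample(pool, sample(3:8, 1)))
    names(lk) <- paste0("A", 1:5)
    s <- SampleTable(data.frame(id = paste0("i", 1:5), lon = 0, lat = 0,
                                association = paste0("A", 1:5), altitude = 1))
    cm <- pairValues(communityDistance(s, lk))
    pa <- t(vapply(lk, function(sp) pool %in% sp, logical(12)))
    veg <- as.matrix(vegan::vegdist(pa, method = "jaccard"))
    expect_equal(unname(cm), unname(veg), tolerance = 1e-12)
    for (i in 1:5) for (j in 1:5) for (k in 1:5)
      expect_lte(cm[i, j], cm[i, k] + cm[k, j] + 1e-12)
  })
})

test_that("standardization yields exact zero mean and unit sd, idempotently", {
  ids <- paste0("i", 1:6)
  withr::with_seed(8, {
    ps <- PredictorSet(list(p1 = distFromVector(rnorm(15), ids),
                            p2 = distFromVector(rnorm(15), ids)))
    resp <- kinMMRR:::newPairwiseMatrix(refold(rnorm(15), ids,
                                               diagValue = NA), ids, "kinship")
  })
  sp <- standardizePredictors(ps, resp)
  for (v in list(sp$vectors[, 1], sp$vectors[, 2], sp$response)) {
    expect_lt(abs(mean(v)), 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  # standardizing an already standardized vector changes nothing
  expect_equal((sp$response - mean(sp$response)) / sd(sp$response),
               sp$response, tolerance = 1e-12)
  # scaling parameters allow exact reconstruction
  sc <- scalingParams(sp$predictors)
  v1 <- unfold(ps[["p1"]])
  expect_equal(sp$vectors[, "p1"] * sc$sd[sc$name == "p1"] +
                 sc$mean[sc$name == "p1"], v1, tolerance = 1e-12,
               ignore_attr = TRUE)

  const <- PredictorSet(list(p1 = distFromVector(rep(1, 15), ids)))
  expect_error(standardizePredictors(const, resp), "zero-variance.*p1")
})

test_that("VIF screening removes collinear predictors iteratively", {
  ids <- paste0("i", 1:10)
  m <- 45
  withr::with_seed(21, {
    z1 <- rnorm(m); z2 <- rnorm(m); z3 <- rnorm(m)
  })
  orth <- function(a, b) residuals(lm(a ~ b))
  # mutually near-orthogonal: VIF ~ 1, nothing removed
  ps <- PredictorSet(list(a = distFromVector(z1, ids),
                          b = distFromVector(orth(z2, z1), ids)))
  expect_equal(names(vifScreen(ps, quiet = TRUE)), c("a", "b"))
  expect_false(any(vifLog(vifScreen(ps, quiet = TRUE))$dropped))

  # duplicated predictor: unbounded VIF, exactly one copy removed (the later)
  dup <- PredictorSet(list(a = distFromVector(z1, ids),
                           a_copy = distFromVector(z1, ids),
                           b = distFromVector(orth(z2, z1), ids)))
  scr <- vifScreen(dup, quiet = TRUE)
  expect_equal(names(scr), c("a", "b"))
  expect_equal(vifLog(scr)$name[vifLog(scr)$dropped], "a_copy")

  # correlation 0.9 -> VIF = 1/(1 - 0.81) ~ 5.26 > 5: one goes
  u <- scale(z1)[, 1]
  v <- 0.9 * u + sqrt(1 - 0.81) * scale(orth(z2, z1))[, 1]
  stopifnot(abs(cor(u, v) - 0.9) < 1e-10)
  cps <- PredictorSet(list(x = distFromVector(u, ids),
                           y = distFromVector(v, ids)))
  scr2 <- vifScreen(cps, threshold = 5, quiet = TRUE)
  expect_equal(length(scr2), 1L)
  expect_equal(vifLog(scr2)$vif[vifLog(scr2)$dropped], 1 / (1 - 0.81),
               tolerance = 1e-9)
  # ... but survives a threshold above 1/(1 - r^2)
  expect_equal(length(vifScreen(cps, threshold = 6, quiet = TRUE)), 2L)

  # single predictor: nothing to screen
  expect_equal(names(vifScreen(PredictorSet(list(a = distFromVector(z1, ids))),
                               quiet = TRUE)), "a")
})
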