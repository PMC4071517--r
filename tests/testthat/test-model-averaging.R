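test_that("unfold produces the row-major lower triangle and refold inverts it", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m[lower.tri(m)] <- c(12, 13, 23) # (2,1), (3,1), (3,2) column-major
  m <- m + t(m)
  v <- unfold(m)
  expect_length(v, 3)
  expect_equal(unname(v), c(12, 13, 23)) # row-major pair order (2,1),(3,1),(3,2)
  expect_equal(names(v), c("b|a", "c|a", "c|b"))
  expect_equal(refold(v, letters[1:3]), m)

  withr::with_seed(4, {
    n <- 7
    ids <- paste0("i", 1:n)
    a <- refold(rnorm(21), ids)
    b <- refold(rnorm(21), ids)
    # same ids unfold in the same pair order
    expect_equal(names(unfold(a)), names(unfold(b)))
  })
  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(unfold(asym), "asymmetric")
})

test_that("all-subsets fitting enumerates 2^p submodels with coherent weights", {
  withr::with_seed(10, {
    m <- 40
    X <- cbind(g = rnorm(m), e = rnorm(m), c = rnorm(m))
    y <- -0.4 * X[, "g"] + rnorm(m)
  })
  fits <- fitAllSubsets(y, X)
  expect_equal(nrow(fits$table), 8L) # three predictors -> 2^3 combinations
  expect_equal(fits$table$model[1], "(intercept)")
  expect_equal(sum(fits$table$weight), 1, tolerance = 1e-10)
  expect_true(all(is.finite(fits$table$aicc)))
  # parameter count: slopes + intercept + residual variance
  expect_equal(fits$table$k, lengths(fits$subsets) + 2L)

  # equal-AICc models split the weight evenly
  expect_equal(kinMMRR:::akaikeWeights(c(10, 10)), c(0.5, 0.5))

  expect_error(fitAllSubsets(y[1:4], X[1:4, ]), "p \\+ 3")
  expect_error(fitAllSubsets(y, cbind(X, g2 = X[, "g"])), "collinear")
})

test_that("model-averaged estimates match the lm-based brute-force oracle", {
  for (s in 1:6) {
    withr::with_seed(200 + s, {
      m <- sample(30:120, 1)
      p <- sample(2:4, 1)
      X <- matrix(rnorm(m * p), m, p,
                  dimnames = list(NULL, paste0("v", 1:p)))
      y <- drop(X %*% runif(p, -0.5, 0.5)) + rnorm(m)
    })
    fits <- fitAllSubsets(y, X)
    eff <- averageEffects(fits)
    orc <- oracleModelAverage(y, X)
    idx <- match(fits$table$model, orc$labels)
    expect_false(anyNA(idx))
    expect_equal(fits$table$aicc, orc$aicc[idx], tolerance = 1e-10)
    expect_equal(fits$table$weight, orc$weights[idx], tolerance = 1e-10)
    expect_equal(eff$estimate, orc$effects$estimate, tolerance = 1e-10)
    expect_equal(eff$se, orc$effects$se, tolerance = 1e-10)
  }
})

test_that("single-predictor averaging reduces to the OLS slope", {
  withr::with_seed(3, {
    x <- rnorm(25)
    y <- 0.7 * x + rnorm(25)
  })
  fits <- fitAllSubsets(y, cbind(x = x))
  eff <- averageEffects(fits)
  expect_equal(eff$estimate, unname(coef(lm(y ~ x))["x"]), tolerance = 1e-12)
})

test_that("a dominant submodel recovers its conventional OLS estimate and SE", {
  withr::with_seed(14, {
    m <- 500
    X <- cbind(a = rnorm(m), b = rnorm(m))
    # both terms indispensable: every submodel missing one is crushed
    y <- -2 * X[, "a"] + 2 * X[, "b"] + 0.3 * rnorm(m)
  })
  fits <- fitAllSubsets(y, X)
  best <- which.max(fits$table$weight)
  expect_equal(fits$table$model[best], "a+b")
  expect_gt(fits$table$weight[best], 0.9999)
  eff <- averageEffects(fits)
  ref <- summary(lm(y ~ X))
  for (tm in c("a", "b")) {
    expect_equal(eff$estimate[eff$term == tm], coef(ref)[paste0("X", tm), 1],
                 tolerance = 1e-3)
    expect_equal(eff$se[eff$term == tm], coef(ref)[paste0("X", tm), 2],
                 tolerance = 1e-3)
  }
})

test_that("signs map onto isolation vs counter-gradient classes", {
  withr::with_seed(9, {
    m <- 200
    X <- cbind(neg = rnorm(m), pos = rnorm(m), null = rnorm(m))
    y <- -1 * X[, "neg"] + 1 * X[, "pos"] + rnorm(m, sd = 0.4)
  })
  eff <- averageEffects(fitAllSubsets(y, X))
  expect_equal(eff$direction[eff$term == "neg"], "isolation")
  expect_equal(eff$direction[eff$term == "pos"], "counter-gradient")
  expect_equal(eff$direction[eff$term == "null"], "none")
  expect_true(all(eff$ci_lo <= eff$estimate & eff$estimate <= eff$ci_hi))
})

test_that("an added pure-noise predictor barely moves the other estimates", {
  withr::with_seed(17, {
    m <- 300
    X <- cbind(a = rnorm(m), b = rnorm(m))
    y <- -0.5 * X[, "a"] + 0.3 * X[, "b"] + rnorm(m)
    noise <- rnorm(m)
  })
  e2 <- averageEffects(fitAllSubsets(y, X))
  e3 <- averageEffects(fitAllSubsets(y, cbind(X, z = noise)))
  for (tm in c("a", "b"))
    expect_lt(abs(e3$estimate[e3$term == tm] - e2$estimate[e2$term == tm]),
              2 * e2$se[e2$term == tm])
})

test_that("full-model averaging shrinks terms absent from good submodels", {
  withr::with_seed(23, {
    m <- 60
    X <- cbind(a = rnorm(m), b = rnorm(m))
    y <- -0.6 * X[, "a"] + rnorm(m)
  })
  fits <- fitAllSubsets(y, X)
  cond <- averageEffects(fits, method = "conditional")
  full <- averageEffects(fits, method = "full")
  expect_lt(abs(full$estimate[full$term == "b"]),
            abs(cond$estimate[cond$term == "b"]) + 1e-12)
  # revised SE variant is available and close for a dominant model set
  rev <- averageEffects(fits, seForm = "revised")
  expect_true(all(rev$se > 0))
})

test_that("the vectorized many-response engine matches the reference path", {
  withr::with_seed(31, {
    m <- 45
    X <- cbind(a = rnorm(m), b = rnorm(m), c = rnorm(m))
    Y <- cbind(-0.4 * X[, "a"] + rnorm(m), rnorm(m), rnorm(m))
  })
  fast <- kinMMRR:::averageManyResponses(Y, X)
  for (col in 1:3) {
    ref <- averageEffects(fitAllSubsets(Y[, col], X))
    expect_equal(unname(fast[ref$term, col]), ref$estimate, tolerance = 1e-10)
  }
})
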