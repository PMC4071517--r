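test_that("allele frequencies and dosages follow the HWE back-calculation", {
  # band frequency 0.75 -> presence-allele frequency 0.5
  g <- DominantGenotypes(matrix(c(1, 1, 1, 0), 4, 1,
                                dimnames = list(paste0("i", 1:4), "L1")))
  fr <- estimateFrequencies(g)
  expect_equal(unname(fr$fBand), 0.75)
  expect_equal(unname(fr$p), 0.5)
  # band absent -> homozygous recessive -> dosage 0
  expect_equal(unname(fr$dosage[4, 1]), 0)
  # band present at p = 0.5 -> posterior mean dosage 1/(2 - 0.5) = 2/3,
  # i.e. (p^2 + pq)/(p^2 + 2pq) computed by hand
  expect_equal(unname(fr$dosage[1, 1]), 2 / 3)

  mono <- DominantGenotypes(matrix(c(1, 1), 2, 1,
                                   dimnames = list(c("a", "b"), "L1")))
  expect_error(estimateFrequencies(mono), "monomorphic")
})

test_that("kinship matches the double-loop oracle, with and without missing data", {
  g <- toyGenotypes()
  k <- kinshipMatrix(g)
  gv <- genotypeValues(g)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(pairValues(k)[i, j], oracleKinshipPair(gv, i, j),
                 tolerance = 1e-12)

  # allelic correction variant agrees with its own oracle
  ka <- kinshipMatrix(g, correction = "allelic")
  expect_equal(pairValues(ka)[1, 2], oracleKinshipPair(gv, 1, 2, "allelic"),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pairValues(ka)[1, 2], pairValues(k)[1, 2])))

  # pairwise-complete handling of missing genotypes
  gm <- genotypeValues(randomPolymorphicGenotypes(8, 12, seed = 5))
  withr::with_seed(6, gm[sample(length(gm), 15)] <- NA)
  gm <- genotypeValues(dropMonomorphic(DominantGenotypes(gm), quiet = TRUE))
  km <- kinshipMatrix(DominantGenotypes(gm))
  for (pr in list(c(1, 2), c(3, 7), c(4, 8)))
    expect_equal(pairValues(km)[pr[1], pr[2]],
                 oracleKinshipPair(gm, pr[1], pr[2]), tolerance = 1e-12)
})

test_that("kinship is exactly symmetric and invariant to locus order", {
  g <- randomPolymorphicGenotypes(10, 30, seed = 11)
  k <- pairValues(kinshipMatrix(g))
  expect_identical(k[lower.tri(k)], t(k)[lower.tri(k)])
  shuf <- withr::with_seed(2, sample(ncol(genotypeValues(g))))
  g2 <- DominantGenotypes(genotypeValues(g)[, shuf])
  expect_equal(pairValues(kinshipMatrix(g2)), k, tolerance = 1e-12)
})

test_that("a duplicated genotype row attains the maximal kinship", {
  for (s in 1:20) {
    g <- randomPolymorphicGenotypes(6, 15, seed = 100 + s)
    gv <- genotypeValues(g)
    gv <- rbind(gv, dup = gv[1, ])
    rownames(gv) <- c(rownames(gv)[-7], "dup")
    gv <- genotypeValues(dropMonomorphic(DominantGenotypes(gv), quiet = TRUE))
    k <- pairValues(kinshipMatrix(DominantGenotypes(gv)))
    pairF <- k["dup", "i1"]
    others <- c(k["dup", setdiff(rownames(gv), c("dup", "i1"))],
                k["i1", setdiff(rownames(gv), c("dup", "i1"))])
    expect_true(all(pairF >= others))
  }
})

test_that("the estimator is centred on panmictic data and errors sensibly", {
  g <- randomPolymorphicGenotypes(30, 80, seed = 77)
  k <- kinshipMatrix(g)
  expect_equal(mean(unfold(k)), 0, tolerance = 1e-12) # exact with no missing

  # disjoint observation patterns -> no shared loci (each locus still
  # polymorphic among its observers)
  gv <- matrix(NA_real_, 3, 4,
               dimnames = list(c("a", "b", "c"), paste0("L", 1:4)))
  gv["a", 1:2] <- c(1, 0); gv["b", 3:4] <- c(0, 1); gv["c", ] <- c(0, 1, 1, 0)
  expect_error(kinshipMatrix(DominantGenotypes(gv)), "share no non-missing locus")
})
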