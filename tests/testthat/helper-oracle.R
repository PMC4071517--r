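# Independent brute-force oracle for all-subsets AICc model averaging,
# built on stats::lm / stats::logLik / stats::AIC rather than the package's
# cross-product engine.
oracleModelAverage <- function(y, X) {
  nm <- colnames(X)
  p <- ncol(X)
  m <- length(y)
  d <- data.frame(y = y, X, check.names = FALSE)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    S <- nm[unlist(grid[i, ])]
    f <- if (length(S)) stats::reformulate(sprintf("`%s`", S), "y")
         else y ~ 1
    fit <- stats::lm(f, data = d)
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    list(S = S, fit = fit,
         aicc = stats::AIC(fit) + 2 * k * (k + 1) / (m - k - 1))
  })
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  labels <- vapply(fits, function(f)
    if (length(f$S)) paste(f$S, collapse = "+") else "(intercept)",
    character(1))
  w <- exp(-(aicc - min(aicc)) / 2)
  w <- w / sum(w)
  eff <- lapply(nm, function(tm) {
    has <- vapply(fits, function(f) tm %in% f$S, logical(1))
    wp <- w[has] / sum(w[has])
    th <- vapply(fits[has], function(f) stats::coef(f$fit)[[tm]], numeric(1))
    vv <- vapply(fits[has], function(f) diag(stats::vcov(f$fit))[[tm]],
                 numeric(1))
    est <- sum(wp * th)
    se <- sum(wp * sqrt(vv + (th - est)^2))
    data.frame(term = tm, estimate = est, se = se)
  })
  list(aicc = aicc, weights = w, labels = labels,
       effects = do.call(rbind, eff))
}

# Brute-force raster lookup: scan every cell and test containment by the
# half-open convention.
oracleExtract <- function(raster, px, py) {
  cs <- raster@cellsize
  vapply(seq_along(px), function(k) {
    hit <- NA_real_
    for (i in seq_len(raster@nrows)) for (j in seq_len(raster@ncols)) {
      x0 <- raster@xllcorner + (j - 1) * cs
      y0 <- raster@yllcorner + (raster@nrows - i) * cs # row 1 = north
      if (px[k] >= x0 && px[k] < x0 + cs && py[k] >= y0 && py[k] < y0 + cs) {
        hit <- raster@values[i, j]
      }
    }
    hit
  }, numeric(1))
}

# Direct double-loop evaluation of the dominant-marker kinship formula with
# pairwise-complete loci, independent of the package's matrix algebra.
oracleKinshipPair <- function(geno, i, j, correction = "dosage") {
  fb <- colMeans(geno, na.rm = TRUE)
  p <- 1 - sqrt(1 - fb)
  x <- sweep(geno, 2, 1 / (2 - p), "*")
  num <- 0
  den <- 0
  for (l in seq_len(ncol(geno))) {
    if (is.na(geno[i, l]) || is.na(geno[j, l])) next
    nl <- sum(!is.na(geno[, l]))
    cl <- if (correction == "dosage")
      sum((x[, l] - p[l])^2, na.rm = TRUE) / nl / (nl - 1)
    else p[l] * (1 - p[l]) / (nl - 1)
    num <- num + (x[i, l] - p[l]) * (x[j, l] - p[l]) + cl
    den <- den + p[l] * (1 - p[l])
  }
  unname(num / den)
}
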