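# All 2^p subsets of term indices, intercept-only first, ordered by size then
# lexicographically -- a fixed enumeration so runs are reproducible.
enumerateSubsets <- function(p) {
  out <- list(integer(0))
  if (p >= 1L) for (sz in 1:p)
    out <- c(out, utils::combn(p, sz, simplify = FALSE))
  out
}

# Gaussian profile log-likelihood of an OLS fit and its small-sample AICc.
# k counts intercept + slopes + residual variance.
aiccFromRss <- function(rss, m, k) {
  ll <- -m / 2 * (log(2 * pi * rss / m) + 1)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (m - k - 1)
}

akaikeWeights <- function(aicc) {
  w <- exp(-(aicc - min(aicc)) / 2)
  w / sum(w)
}

#' Fit every submodel of the multiple matrix regression
#'
#' Ordinary least squares is applied to the unfolded response for every
#' subset of the predictors (all \eqn{2^p} combinations, including the
#' intercept-only model). For each submodel the Gaussian log-likelihood
#' \eqn{-m/2(\ln(2\pi RSS/m) + 1)}, the parameter count
#' \eqn{k = \#slopes + 2} (intercept and residual variance included), the
#' small-sample criterion
#' \eqn{AICc = -2\ell + 2k + 2k(k+1)/(m-k-1)} and the Akaike weight
#' \eqn{w_g = e^{-\Delta_g/2} / \sum_h e^{-\Delta_h/2}} are recorded.
#'
#' @param response numeric vector of length m (unfolded, typically
#'   standardized kinship).
#' @param predictors named numeric matrix (m x p) or named list of length-m
#'   vectors; p <= 12 after collinearity screening.
#' @return an object of class \code{"SubmodelFits"}: a list with
#'   \code{terms} (predictor names), \code{subsets} (term-name subsets),
#'   \code{table} (data.frame: model, k, rss, logLik, aicc, weight),
#'   \code{coefs} and \code{vars} (per-submodel slope estimates and their
#'   sampling variances), \code{m}.
#' @export
fitAllSubsets <- function(response, predictors) {
  X <- if (is.list(predictors) && !is.matrix(predictors))
    do.call(cbind, predictors) else as.matrix(predictors)
  if (is.null(colnames(X))) stop("predictors must be named")
  m <- length(response)
  p <- ncol(X)
  if (nrow(X) != m) stop("response and predictors must have equal length")
  if (m < p + 3L) stop("need at least p + 3 observations")
  kmax <- p + 2L
  if (m - kmax - 1L <= 0L)
    stop("largest model leaves no residual degrees of freedom for AICc")
  subsets <- enumerateSubsets(p)
  nm <- colnames(X)
  coefs <- vars <- vector("list", length(subsets))
  tab <- data.frame(model = character(length(subsets)),
                    k = integer(length(subsets)),
                    rss = numeric(length(subsets)),
                    logLik = numeric(length(subsets)),
                    aicc = numeric(length(subsets)))
  for (g in seq_along(subsets)) {
    S <- subsets[[g]]
    Xg <- cbind(`(Intercept)` = 1, X[, S, drop = FALSE])
    qrX <- qr(Xg)
    if (qrX$rank < ncol(Xg))
      stop(sprintf("collinear design in submodel {%s}; screen predictors first",
                   paste(nm[S], collapse = ", ")))
    b <- qr.coef(qrX, response)
    res <- response - Xg %*% b
    rss <- sum(res^2)
    dfres <- m - ncol(Xg)
    sigma2 <- rss / dfres
    XtXinv <- chol2inv(qr.R(qrX))
    v <- sigma2 * diag(XtXinv)
    k <- length(S) + 2L
    tab$model[g] <- if (length(S)) paste(nm[S], collapse = "+") else "(intercept)"
    tab$k[g] <- k
    tab$rss[g] <- rss
    tab$logLik[g] <- -m / 2 * (log(2 * pi * rss / m) + 1)
    tab$aicc[g] <- aiccFromRss(rss, m, k)
    coefs[[g]] <- stats::setNames(b[-1L], nm[S])
    vars[[g]] <- stats::setNames(v[-1L], nm[S])
  }
  tab$weight <- akaikeWeights(tab$aicc)
  structure(list(terms = nm, subsets = lapply(subsets, function(S) nm[S]),
                 table = tab, coefs = coefs, vars = vars, m = m),
            class = "SubmodelFits")
}

#' @export
print.SubmodelFits <- function(x, ...) {
  cat(sprintf("SubmodelFits: %d submodels of %d terms, m = %d pairs\n",
              nrow(x$table), length(x$terms), x$m))
  top <- x$table[order(-x$table$weight), ][1:min(5L, nrow(x$table)), ]
  print(top[, c("model", "k", "aicc", "weight")], row.names = FALSE, ...)
  invisible(x)
}

#' AICc model-averaged coefficients with unconditional standard errors
#'
#' Conditional ("natural") averaging: each term is averaged over the
#' submodels that contain it, with Akaike weights renormalized over that set:
#' \eqn{\bar\theta_j = \sum_g w'_g \hat\theta_{j,g}}. The unconditional
#' standard error follows Burnham & Anderson's weighted-sum-of-roots form
#' \eqn{SE_j = \sum_g w'_g \sqrt{var(\hat\theta_{j,g}) +
#' (\hat\theta_{j,g}-\bar\theta_j)^2}}, which folds model-selection
#' uncertainty into the sampling variance; the revised
#' square-root-of-weighted-sum variant is available via \code{seForm}.
#' Full-model (shrinkage) averaging -- absent terms contribute 0 with their
#' model's full weight -- is available via \code{method = "full"}.
#'
#' A term is flagged significant when its confidence interval
#' \eqn{\bar\theta_j \pm z \cdot SE_j} excludes zero; a significant negative
#' coefficient is classified \code{"isolation"} (relatedness declines with
#' the predictor distance) and a significant positive one
#' \code{"counter-gradient"}.
#'
#' @param fits a \code{"SubmodelFits"} object.
#' @param method conditional (default) or full averaging.
#' @param seForm unconditional-SE variant, see Details.
#' @param ciMultiplier CI half-width in SE units (default 1.96, the normal
#'   95\% quantile; pair counts are large enough that the t correction is
#'   negligible).
#' @return data.frame with one row per term: \code{term}, \code{estimate},
#'   \code{se}, \code{ci_lo}, \code{ci_hi}, \code{significant_ci},
#'   \code{direction}.
#' @export
averageEffects <- function(fits, method = c("conditional", "full"),
                           seForm = c("weighted_roots", "revised"),
                           ciMultiplier = 1.96) {
  method <- match.arg(method)
  seForm <- match.arg(seForm)
  w <- fits$table$weight
  out <- lapply(fits$terms, function(tm) {
    has <- vapply(fits$subsets, function(S) tm %in% S, logical(1))
    if (!any(has)) stop(sprintf("term '%s' appears in no submodel", tm))
    th <- vapply(which(has), function(g) fits$coefs[[g]][[tm]], numeric(1))
    vv <- vapply(which(has), function(g) fits$vars[[g]][[tm]], numeric(1))
    if (method == "conditional") {
      wp <- w[has] / sum(w[has])
      est <- sum(wp * th)
      dev2 <- (th - est)^2
      se <- if (seForm == "weighted_roots") sum(wp * sqrt(vv + dev2))
            else sqrt(sum(wp * (vv + dev2)))
    } else {
      est <- sum(w[has] * th) # absent models contribute 0
      dev2 <- (th - est)^2
      seIn <- if (seForm == "weighted_roots") sum(w[has] * sqrt(vv + dev2))
              else NA
      # absent models: estimate 0, variance 0, deviation est^2
      se <- if (seForm == "weighted_roots")
        seIn + sum(w[!has]) * sqrt(est^2)
      else sqrt(sum(w[has] * (vv + dev2)) + sum(w[!has]) * est^2)
    }
    data.frame(term = tm, estimate = est, se = se,
               ci_lo = est - ciMultiplier * se,
               ci_hi = est + ciMultiplier * se)
  })
  out <- do.call(rbind, out)
  out$significant_ci <- out$ci_lo > 0 | out$ci_hi < 0
  out$direction <- ifelse(!out$significant_ci, "none",
                          ifelse(out$estimate < 0, "isolation", "counter-gradient"))
  out
}

# Vectorized model-averaged estimates for MANY response columns at once
# (the permutation engine): Y is m x C, X is m x p named. Returns a p x C
# matrix of conditionally averaged estimates. Point estimates and RSS come
# from precomputed QR factorizations; per-column weights are recomputed.
averageManyResponses <- function(Y, X, method = c("conditional", "full")) {
  method <- match.arg(method)
  m <- nrow(Y)
  p <- ncol(X)
  C <- ncol(Y)
  nm <- colnames(X)
  subsets <- enumerateSubsets(p)
  G <- length(subsets)
  yy <- colSums(Y^2)
  rssM <- matrix(0, G, C)
  # flat stack of every (submodel, slope) row for vectorized aggregation
  nRows <- sum(lengths(subsets))
  THall <- matrix(0, nRows, C)
  termIdx <- integer(nRows)
  subIdx <- integer(nRows)
  pos <- 0L
  # normal equations from precomputed cross-products: per-subset cost is
  # independent of the pair count m (predictors are standardized and
  # VIF-screened, so the tiny Gram matrices are well conditioned)
  Xa <- cbind(`(Intercept)` = 1, X)
  XtX <- crossprod(Xa)
  XtY <- crossprod(Xa, Y)
  for (g in seq_len(G)) {
    S <- subsets[[g]]
    ind <- c(1L, S + 1L)
    B <- solve(XtX[ind, ind, drop = FALSE], XtY[ind, , drop = FALSE])
    dim(B) <- c(length(ind), C)
    rssM[g, ] <- pmax(yy - colSums(B * XtY[ind, , drop = FALSE]),
                      .Machine$double.eps)
    if (length(S)) {
      rows <- pos + seq_along(S)
      THall[rows, ] <- B[-1L, , drop = FALSE]
      termIdx[rows] <- S
      subIdx[rows] <- g
      pos <- pos + length(S)
    }
  }
  k <- lengths(subsets) + 2L
  aicc <- aiccFromRss(rssM, m, k)      # recycles k down columns: G x C
  aicc <- sweep(aicc, 2L, apply(aicc, 2L, min))
  W <- exp(-aicc / 2)
  W <- sweep(W, 2L, colSums(W), "/")
  Wrows <- W[subIdx, , drop = FALSE]
  num <- rowsum(Wrows * THall, termIdx)
  out <- if (method == "conditional") num / rowsum(Wrows, termIdx) else num
  rownames(out) <- nm[as.integer(rownames(out))]
  out[nm, , drop = FALSE]
}
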