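## Annotation-GLM fitting, ISC screening, circular-shift permutation nulls,
## and component selection.

#' Fit an annotation model to a time course
#'
#' Ordinary least squares with intercept.  \code{r} is the Pearson
#' correlation of the fitted and observed series (the multiple correlation
#' of the model), \code{rSquared} its square.  Weights are normalised so the
#' main explanatory variable — the feature with the largest |beta| — receives
#' weight 1 with its sign preserved (a negative-dominant model yields weight
#' -1 rather than a global sign flip).
#'
#' @param X a \linkS4class{DesignMatrix} (or plain time x features matrix).
#' @param y observed time course, same length as \code{nrow(X)}.
#' @return a \linkS4class{ModelFit}.
#' @export
fitAnnotationModel <- function(X, y) {
  modelId <- if (is(X, "DesignMatrix")) X@modelId else "custom"
  M <- if (is(X, "DesignMatrix")) designMatrix(X) else as.matrix(X)
  if (nrow(M) != length(y)) stop("rows(X) must equal length(y)")
  Xi <- cbind(`(Intercept)` = 1, M)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    dep <- colnames(Xi)[qrX$pivot[(qrX$rank + 1):ncol(Xi)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- as.numeric(Xi %*% beta)
  b <- beta[-1]
  r <- if (stats::sd(fitted) == 0) 0 else stats::cor(fitted, y)
  nw <- if (max(abs(b)) > 0) b / max(abs(b)) else b
  new("ModelFit", betas = b, intercept = unname(beta[1]),
      normalizedWeights = nw, fitted = fitted,
      r = r, rSquared = r^2, modelId = modelId)
}

#' Per-subject single-feature GLM slopes
#'
#' Fits one feature (plus intercept) in isolation to each subject's
#' component time course, returning the per-subject slope estimates used in
#' the weight tests.
#'
#' @param x single regressor (numeric vector).
#' @param Y subjects x time matrix (or list of time courses).
#' @return numeric vector of per-subject betas.
#' @export
singleFeatureFits <- function(x, Y) {
  if (is.list(Y)) Y <- do.call(rbind, Y)
  apply(Y, 1, function(y) {
    fitAnnotationModel(matrix(x, ncol = 1,
                              dimnames = list(NULL, "feature")), y)@betas
  })
}

#' Tests on single-feature weights
#'
#' For each feature: a one-sample t-test of the per-subject weights against
#' zero for each of two components, and a paired t-test of the difference
#' between the components.  All tests are two-sided.
#'
#' @param betas1,betas2 subjects x features matrices of single-feature
#'   weights for the two components.
#' @return data.frame with one row per feature: one-sample t and p per
#'   component, paired t and p.  Zero-variance differences give NA p with a
#'   flag.
#' @export
weightTests <- function(betas1, betas2) {
  if (!all(dim(betas1) == dim(betas2)))
    stop("weight matrices must have equal dimensions")
  if (nrow(betas1) < 3) stop("need at least 3 subjects")
  feats <- colnames(betas1)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(betas1)))
  one <- function(v) {
    if (stats::sd(v) == 0) return(c(NA_real_, NA_real_))
    tt <- stats::t.test(v)
    c(tt$statistic, tt$p.value)
  }
  res <- lapply(seq_len(ncol(betas1)), function(j) {
    a <- one(betas1[, j]); b <- one(betas2[, j])
    d <- betas1[, j] - betas2[, j]
    p <- if (stats::sd(d) == 0) {
      if (all(d == 0)) c(0, 1) else c(NA_real_, NA_real_)
    } else {
      tt <- stats::t.test(betas1[, j], betas2[, j], paired = TRUE)
      c(tt$statistic, tt$p.value)
    }
    data.frame(feature = feats[j], t1 = a[1], p1 = a[2], t2 = b[1],
               p2 = b[2], tPaired = p[1], pPaired = p[2],
               degenerate = stats::sd(d) == 0 && !all(d == 0))
  })
  do.call(rbind, res)
}

#' Inter-subject correlation of component time courses
#'
#' Computes all pairwise Pearson correlations of the subjects' time courses
#' for one component, clips them just inside (-1, 1), and averages in
#' Fisher-z space.  The permutation p-value circularly shifts one member of
#' each pair (destroying stimulus alignment while preserving
#' autocorrelation) and compares the resulting mean ISC to the observed one.
#'
#' @param Y subjects x time matrix (or list of per-subject time courses) for
#'   one component.
#' @param nPerm number of permutations for the p-value (0 skips it).
#' @param seed RNG seed for the permutation shifts.
#' @return an \linkS4class{IscResult}.
#' @examples
#' isc <- iscMean(matrix(rnorm(40), 4, 10), nPerm = 0)
#' @export
iscMean <- function(Y, nPerm = 1000L, seed = 1L) {
  if (is.list(Y)) Y <- do.call(rbind, Y)
  n <- nrow(Y)
  if (n < 2) stop("need at least 2 subjects")
  clip <- function(r) pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  C <- stats::cor(t(Y))
  pr <- clip(C[upper.tri(C)])
  meanR <- fisherZinv(mean(fisherZ(pr)))
  p <- NA_real_
  if (nPerm > 0) {
    Tt <- ncol(Y)
    obs <- mean(fisherZ(pr))
    perm <- withSeed(seed, {
      vapply(seq_len(nPerm), function(b) {
        shifts <- sample(Tt - 1L, n, replace = TRUE)
        Ys <- t(vapply(seq_len(n), function(i) rotateVec(Y[i, ], shifts[i]),
                       numeric(Tt)))
        Cp <- stats::cor(t(Ys))
        mean(fisherZ(clip(Cp[upper.tri(Cp)])))
      }, numeric(1))
    })
    p <- (sum(perm >= obs) + 1) / (nPerm + 1)
  }
  new("IscResult", pairwiseR = pr, meanR = meanR,
      dispersion = stats::var(pr),
      dispersionSd = stats::sd(pr), pValue = p)
}

## Multiple correlation of a fixed model with every circular rotation of a
## series: returns the vector of r over shifts s = 0..T-1 (identity first).
## Q is the orthonormal basis of the centered design.
rotationR <- function(Q, y) {
  yc <- y - mean(y)
  denom <- sqrt(sum(yc^2))
  if (denom == 0) return(rep(0, length(y)))
  D <- circularCrossprod(Q, yc)       # shifts x k
  sqrt(pmax(rowSums(D^2), 0)) / denom
}

#' Circular-shift permutation null for an annotation model
#'
#' For every distinct circular rotation of every supplied time course the
#' model is refitted and the correlation of the fitted and rotated series
#' recorded.  With series of length T this gives T realizations per series
#' (the identity rotation is included, so the observed r is part of the
#' null).  The pooled realizations are summarised into a 100-bin lookup
#' table; \code{\link{thresholdAt}} interpolates linearly between bin
#' centers.
#'
#' Rotation preserves the mean, variance and autocorrelation of the series
#' while destroying its alignment with the stimulus, which makes this an
#' appropriate null for autocorrelated BOLD time courses.
#'
#' @param X a \linkS4class{DesignMatrix} (or plain matrix).
#' @param Y one time course (vector) or several (time x series matrix).
#' @param shiftStep rotation increment; 1 uses all T rotations.
#' @return a \linkS4class{PermutationNull}; the observed per-series r values
#'   are attached as attribute \code{"observedR"}.
#' @export
circularNull <- function(X, Y, shiftStep = 1L) {
  modelId <- if (is(X, "DesignMatrix")) X@modelId else "custom"
  M <- if (is(X, "DesignMatrix")) designMatrix(X) else as.matrix(X)
  Y <- if (is.matrix(Y)) Y else matrix(Y, ncol = 1)
  Tt <- nrow(Y)
  if (nrow(M) != Tt) stop("X and Y must share the time dimension")
  if (Tt < 50) warning("series shorter than 50: threshold estimate unstable")
  Q <- qr.Q(qr(scale(M, center = TRUE, scale = FALSE)))
  keep <- seq(1L, Tt, by = shiftStep)
  samples <- numeric(0)
  observed <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    r <- rotationR(Q, Y[, j])
    observed[j] <- r[1]
    samples <- c(samples, r[keep])
  }
  bt <- binTable(samples)
  out <- new("PermutationNull", modelId = modelId, rSamples = sort(samples),
             binCenters = bt$centers, binProb = bt$prob,
             nSeries = ncol(Y), nTime = Tt,
             shiftStep = as.integer(shiftStep))
  attr(out, "observedR") <- observed
  out
}

#' Circular-shift null for a single annotation
#'
#' As \code{\link{circularNull}} but with plain (signed) Pearson correlation
#' of the single regressor against each rotation, and rotations taken in
#' two-step increments so only half of the distribution is sampled
#' (ceiling(T/2) realizations per series).
#'
#' @param x single regressor (numeric vector).
#' @param Y one or several time courses.
#' @return a \linkS4class{PermutationNull}.
#' @export
singleAnnotationNull <- function(x, Y) {
  Y <- if (is.matrix(Y)) Y else matrix(Y, ncol = 1)
  Tt <- nrow(Y)
  if (length(x) != Tt) stop("x and Y must share the time dimension")
  if (Tt < 50) warning("series shorter than 50: threshold estimate unstable")
  xc <- x - mean(x)
  xn <- xc / sqrt(sum(xc^2))
  keep <- seq(1L, Tt, by = 2L)
  samples <- numeric(0)
  observed <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    yc <- Y[, j] - mean(Y[, j])
    denom <- sqrt(sum(yc^2))
    r <- if (denom == 0) rep(0, Tt) else
      as.numeric(circularCrossprod(matrix(xn, ncol = 1), yc)) / denom
    observed[j] <- r[1]
    samples <- c(samples, r[keep])
  }
  bt <- binTable(samples)
  out <- new("PermutationNull", modelId = "single", rSamples = sort(samples),
             binCenters = bt$centers, binProb = bt$prob,
             nSeries = ncol(Y), nTime = Tt, shiftStep = 2L)
  attr(out, "observedR") <- observed
  out
}

#' Per-modality visualization threshold
#'
#' The single-annotation thresholds of one modality are combined into one
#' visualization threshold as their arithmetic mean.
#'
#' @param nulls list of \linkS4class{PermutationNull} objects (one per
#'   annotation).
#' @param p upper-tail probability.
#' @return mean of the individual thresholds.
#' @export
modalityThreshold <- function(nulls, p = 0.001) {
  mean(vapply(nulls, thresholdAt, numeric(1), p = p))
}

#' @rdname thresholdAt
#' @export
setMethod("thresholdAt", "PermutationNull", function(x, p) {
  binThreshold(x@binCenters, x@binProb, p)
})

#' Pairwise correlation matrix of annotation tracks
#'
#' @param set an \linkS4class{AnnotationSet} (or samples x features matrix).
#' @param convolve optional \code{\link{hrfSpec}}: convolve tracks before
#'   correlating (both scales are of interest; the raw tracks are the
#'   default).
#' @return list with \code{r} (symmetric correlation matrix, unit diagonal;
#'   rows/cols of constant tracks are NA and listed in \code{undefined}),
#'   \code{histogram} (off-diagonal value histogram, from
#'   \code{\link[graphics]{hist}}), and \code{undefined}.
#' @export
annotationCorrelationMatrix <- function(set, convolve = NULL) {
  m <- if (is(set, "AnnotationSet")) trackMatrix(set) else as.matrix(set)
  if (!is.null(convolve)) {
    k <- hrfKernel(convolve)$values
    m <- apply(m, 2, causalConvolve, kernel = k)
  }
  sds <- apply(m, 2, stats::sd)
  undef <- colnames(m)[sds == 0]
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  off <- r[upper.tri(r)]
  off <- off[is.finite(off)]
  h <- if (length(off))
    graphics::hist(off, breaks = 20, plot = FALSE) else NULL
  list(r = r, histogram = h, undefined = undef)
}

#' Select components by ISC, model fit and stability
#'
#' Keeps the components that (a) show significant inter-subject correlation,
#' (b) have a model fit exceeding the circular-shift threshold of the
#' auditory or the visual model, and (c) passed the stability criteria.
#'
#' @param components a \linkS4class{ComponentSet} (with stability filled).
#' @param iscResults list of \linkS4class{IscResult}, one per component.
#' @param fitsAud,fitsVis lists of \linkS4class{ModelFit} per component for
#'   the auditory and visual models (either may be \code{NULL}).
#' @param nullAud,nullVis the matching \linkS4class{PermutationNull}s.
#' @param config an \code{\link{icaConfig}} providing the stability rule.
#' @param alpha significance level for both the ISC p-value and the model
#'   threshold.
#' @return integer vector of kept component indices.
#' @export
selectComponents <- function(components, iscResults, fitsAud = NULL,
                             fitsVis = NULL, nullAud = NULL, nullVis = NULL,
                             config = icaConfig(), alpha = 0.001) {
  k <- nComponents(components)
  stable <- components@stabilityIndex > config$stabilityMin
  if (config$requireAllRuns)
    stable <- stable & components@runCount == components@nRuns
  iscOk <- vapply(iscResults, function(z) z@pValue < alpha, logical(1))
  modelOk <- rep(FALSE, k)
  if (!is.null(fitsAud)) {
    thr <- thresholdAt(nullAud, alpha)
    modelOk <- modelOk |
      vapply(fitsAud, function(f) f@r > thr, logical(1))
  }
  if (!is.null(fitsVis)) {
    thr <- thresholdAt(nullVis, alpha)
    modelOk <- modelOk |
      vapply(fitsVis, function(f) f@r > thr, logical(1))
  }
  which(stable & iscOk & modelOk)
}
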