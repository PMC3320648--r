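## Temporal-concatenation group spatial ICA with repeated randomised /
## bootstrapped estimation, stability clustering, and subject-level
## back-reconstruction.

#' Group ICA configuration
#'
#' @param nComponents model order (number of components; the full study used
#'   40, desk-scale synthetic runs use the planted component count).
#' @param nRuns number of randomised ICA repetitions pooled for stability
#'   clustering.
#' @param bootstrap resample the concatenated time dimension with
#'   replacement before each run.
#' @param subjectPcaDim optional per-subject PCA dimension before temporal
#'   concatenation (\code{NULL} skips the subject-level reduction).
#' @param randomSeed seed for run initialisation and bootstrap draws.
#' @param stabilityMin components are retained when their mean intra-cluster
#'   |spatial r| exceeds this value.
#' @param requireAllRuns additionally require the component's cluster to
#'   contain a member from every run.
#' @param maxIter,tol fixed-point iteration controls.
#' @return list of class \code{"IcaConfig"}.
#' @export
icaConfig <- function(nComponents = 4L, nRuns = 100L, bootstrap = TRUE,
                      subjectPcaDim = NULL, randomSeed = 1L,
                      stabilityMin = 0.9, requireAllRuns = TRUE,
                      maxIter = 200L, tol = 1e-6) {
  if (stabilityMin <= 0 || stabilityMin > 1)
    stop("stabilityMin must lie in (0, 1]")
  structure(list(nComponents = as.integer(nComponents),
                 nRuns = as.integer(nRuns), bootstrap = isTRUE(bootstrap),
                 subjectPcaDim = subjectPcaDim,
                 randomSeed = as.integer(randomSeed),
                 stabilityMin = stabilityMin,
                 requireAllRuns = isTRUE(requireAllRuns),
                 maxIter = as.integer(maxIter), tol = tol),
            class = "IcaConfig")
}

#' Concatenate subjects and reduce with PCA
#'
#' Optionally reduces each subject's time dimension to
#' \code{config$subjectPcaDim} principal components, concatenates subjects
#' along time, and reduces the concatenated matrix to
#' \code{config$nComponents} dimensions by group PCA.  The eigenvectors and
#' singular values are retained so the reduced space can be reconstructed
#' and bootstrap re-reductions computed cheaply.
#'
#' @param datasets list of \linkS4class{BoldDataset}, detrended and
#'   standardised, sharing a mask.
#' @param config an \code{\link{icaConfig}}.
#' @return list with \code{reduced} (nComponents x voxels), \code{concat}
#'   (concatenated time x voxels matrix), \code{eigVectors} (time x
#'   nComponents), \code{eigValues}, \code{gram} (concatenated-time Gram
#'   matrix, reused for bootstrap), \code{explained} (fraction of variance
#'   retained), and \code{rowsPerSubject}.
#' @export
concatAndReduce <- function(datasets, config) {
  vox <- vapply(datasets, nVoxels, integer(1))
  if (length(unique(vox)) != 1L) stop("datasets must share a voxel count")
  mats <- lapply(datasets, boldMatrix)
  if (!is.null(config$subjectPcaDim)) {
    d <- config$subjectPcaDim
    mats <- lapply(mats, function(m) {
      g <- tcrossprod(m)
      e <- eigen(g, symmetric = TRUE)
      t(e$vectors[, seq_len(d), drop = FALSE]) %*% m
    })
  }
  Y <- do.call(rbind, mats)
  k <- config$nComponents
  if (k > min(dim(Y))) stop("nComponents exceeds the available rank")
  G <- tcrossprod(Y)
  e <- eigen(G, symmetric = TRUE)
  if (e$values[k] <= max(e$values) * 1e-12)
    stop("nComponents exceeds the available rank")
  E <- e$vectors[, seq_len(k), drop = FALSE]
  list(reduced = crossprod(E, Y), concat = Y, eigVectors = E,
       eigValues = e$values, gram = G,
       explained = sum(e$values[seq_len(k)]) / sum(pmax(e$values, 0)),
       rowsPerSubject = vapply(mats, nrow, integer(1)))
}

#' One randomised (optionally bootstrapped) spatial ICA decomposition
#'
#' Estimates maximally non-Gaussian spatial sources from a reduced
#' components x voxels matrix by a symmetric fixed-point iteration with the
#' tanh contrast (maximising negentropy, equivalently minimising the mutual
#' information of the source estimates).  Rows of the returned source matrix
#' are spatial maps; the mixing matrix columns map sources to the reduced
#' coordinates (time courses after composition with the PCA operators).
#'
#' When \code{bootstrapIdx} is supplied it holds resampled time indices: the
#' reduction is recomputed on the bootstrap sample (using the precomputed
#' Gram matrix) before estimation.
#'
#' @param reduction result of \code{\link{concatAndReduce}}.
#' @param seed RNG seed for the random orthogonal initialisation.
#' @param bootstrapIdx optional integer vector of resampled time rows.
#' @param maxIter,tol iteration controls.
#' @return list with \code{maps} (k x voxels), \code{mixing} (k x k, reduced
#'   space), \code{converged} flag and \code{iterations} used.  A
#'   non-converged run is returned flagged, not an error.
#' @export
runIcaOnce <- function(reduction, seed = 1L, bootstrapIdx = NULL,
                       maxIter = 200L, tol = 1e-6) {
  X <- if (is.null(bootstrapIdx)) {
    reduction$reduced
  } else {
    Gb <- reduction$gram[bootstrapIdx, bootstrapIdx]
    eb <- eigen(Gb, symmetric = TRUE)
    k <- nrow(reduction$reduced)
    Eb <- eb$vectors[, seq_len(k), drop = FALSE]
    crossprod(Eb, reduction$concat[bootstrapIdx, , drop = FALSE])
  }
  if (!all(is.finite(X))) stop("reduced matrix must be finite")
  k <- nrow(X); V <- ncol(X)
  ## whiten across the component dimension (voxels are the samples)
  Xc <- X - rowMeans(X)
  covX <- tcrossprod(Xc) / (V - 1)
  ew <- eigen(covX, symmetric = TRUE)
  Kw <- diag(1 / sqrt(pmax(ew$values, 1e-12)), k) %*% t(ew$vectors)
  Z <- Kw %*% Xc
  W <- withSeed(seed, symOrth(matrix(stats::rnorm(k * k), k, k)))
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    WX <- W %*% Z
    G <- tanh(WX)
    W1 <- G %*% t(Z) / V - diag(rowMeans(1 - G^2), k) %*% W
    W1 <- symOrth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- W %*% Z                       # spatial maps in whitened coordinates
  A <- solve(W %*% Kw)               # mixing: reduced = A %*% S (up to means)
  list(maps = S, mixing = A, converged = converged, iterations = iter)
}

## Symmetric orthogonalisation W <- (W W')^{-1/2} W.
symOrth <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nrow(W)) %*%
    t(e$vectors) %*% W
}

#' Cluster pooled ICA runs by spatial similarity
#'
#' Pools the spatial maps of all runs, computes pairwise similarity as the
#' absolute spatial Pearson correlation, and applies average-linkage
#' agglomerative clustering on 1 - |r| into \code{config$nComponents}
#' clusters.  Per cluster the stability index is the mean pairwise
#' intra-cluster |r|, the run count is the number of distinct runs
#' represented, and the representative map is the sign-aligned cluster mean
#' anchored at the centrotype (the member with maximal summed similarity).
#' Maps are z-scored for reporting.
#'
#' @param decompositions list of \code{\link{runIcaOnce}} results.
#' @param config an \code{\link{icaConfig}}.
#' @param maskDim optional mask dimensions stored in the result.
#' @return a \linkS4class{ComponentSet} (no time courses yet; see
#'   \code{\link{backReconstruct}}).
#' @export
icassoCluster <- function(decompositions, config, maskDim = integer(0)) {
  if (length(decompositions) < 2) stop("need at least 2 decompositions")
  pool <- do.call(rbind, lapply(decompositions, `[[`, "maps"))
  runId <- rep(seq_along(decompositions),
               vapply(decompositions, function(d) nrow(d$maps), integer(1)))
  C <- abs(stats::cor(t(pool)))
  k <- config$nComponents
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  cl <- stats::cutree(hc, k = k)
  if (length(unique(cl)) < k)
    stop("empty cluster produced; nComponents is likely mis-set")
  maps <- matrix(0, k, ncol(pool))
  stab <- numeric(k)
  runs <- integer(k)
  for (j in seq_len(k)) {
    members <- which(cl == j)
    runs[j] <- length(unique(runId[members]))
    sub <- C[members, members, drop = FALSE]
    stab[j] <- if (length(members) > 1)
      mean(sub[upper.tri(sub)]) else 1
    centro <- members[which.max(rowSums(sub))]
    sgn <- sign(stats::cor(t(pool[members, , drop = FALSE]),
                           pool[centro, ]))
    sgn[sgn == 0] <- 1
    maps[j, ] <- colMeans(pool[members, , drop = FALSE] * as.numeric(sgn))
  }
  ord <- order(stab, decreasing = TRUE)
  new("ComponentSet", spatialMaps = zscoreRows(maps[ord, , drop = FALSE]),
      rawMaps = maps[ord, , drop = FALSE],
      stabilityIndex = pmin(stab[ord], 1), runCount = runs[ord],
      nRuns = length(decompositions), maskDim = as.integer(maskDim))
}

#' Keep only stable components
#'
#' Retains components whose stability index exceeds
#' \code{config$stabilityMin} and (when \code{config$requireAllRuns}) whose
#' cluster contains a member from every run.  An empty result is allowed.
#'
#' @param components a \linkS4class{ComponentSet}.
#' @param config an \code{\link{icaConfig}}.
#' @return the filtered \linkS4class{ComponentSet}.
#' @export
selectStable <- function(components, config) {
  keep <- components@stabilityIndex > config$stabilityMin
  if (config$requireAllRuns)
    keep <- keep & components@runCount == components@nRuns
  components[which(keep)]
}

#' Back-reconstruct subject component time courses
#'
#' In spatial ICA the component time course is the spatial-map weighted
#' average of the voxel time courses; subject data are projected onto the
#' pseudo-inverse of the spatial map matrix.  For orthonormal maps this
#' reduces to a plain weighted average.  Group time courses are the mean of
#' the subject time courses.
#'
#' @param components a \linkS4class{ComponentSet}.
#' @param datasets list of \linkS4class{BoldDataset} (standardised, same
#'   voxel order as the maps).
#' @return the \linkS4class{ComponentSet} with \code{subjectTimecourses} and
#'   \code{groupTimecourses} filled.
#' @export
backReconstruct <- function(components, datasets) {
  S <- if (nrow(components@rawMaps)) components@rawMaps
    else components@spatialMaps
  SS <- tcrossprod(S)
  pinvS <- tryCatch(t(S) %*% solve(SS), error = function(e) {
    warning("rank-deficient spatial map matrix; using least-squares pseudo-inverse")
    t(MASS::ginv(S))
  })
  tcs <- lapply(datasets, function(d) t(boldMatrix(d) %*% pinvS))
  out <- components
  out@subjectTimecourses <- tcs
  out@groupTimecourses <- Reduce(`+`, tcs) / length(tcs)
  out
}

#' Run the full group ICA with stability clustering
#'
#' Convenience driver: concatenates and reduces the datasets, runs
#' \code{config$nRuns} randomised (optionally bootstrapped) decompositions,
#' clusters the pooled maps, and back-reconstructs subject time courses.
#'
#' @param datasets list of detrended, standardised
#'   \linkS4class{BoldDataset}.
#' @param config an \code{\link{icaConfig}}.
#' @return a \linkS4class{ComponentSet} with time courses, plus attributes
#'   \code{"reduction"} (the PCA operators) and \code{"runLog"} (per-run
#'   seed and convergence).
#' @export
groupICA <- function(datasets, config = icaConfig()) {
  red <- concatAndReduce(datasets, config)
  Tt <- nrow(red$concat)
  decomps <- vector("list", config$nRuns)
  log <- data.frame(run = seq_len(config$nRuns),
                    seed = config$randomSeed + seq_len(config$nRuns) - 1L,
                    converged = NA)
  for (r in seq_len(config$nRuns)) {
    seed <- log$seed[r]
    idx <- if (config$bootstrap && r > 1)
      withSeed(seed + 500000L, sample.int(Tt, Tt, replace = TRUE)) else NULL
    dec <- runIcaOnce(red, seed = seed, bootstrapIdx = idx,
                      maxIter = config$maxIter, tol = config$tol)
    log$converged[r] <- dec$converged
    decomps[[r]] <- dec
  }
  comp <- icassoCluster(decomps, config, maskDim = dim(datasets[[1]]@mask))
  comp <- backReconstruct(comp, datasets)
  attr(comp, "reduction") <- red
  attr(comp, "runLog") <- log
  comp
}

#' Stability-vs-dimensionality sweep
#'
#' Exploratory utility re-running the stability clustering at several model
#' orders and reporting the mean and minimum stability index at each, as a
#' guide for choosing the dimensionality when it is not fixed a priori.
#'
#' @param datasets list of \linkS4class{BoldDataset}.
#' @param dims integer vector of candidate model orders.
#' @param config base \code{\link{icaConfig}} (its \code{nComponents} is
#'   overridden per candidate).
#' @return data.frame with columns \code{dim}, \code{meanStability},
#'   \code{minStability}.
#' @export
stabilitySweep <- function(datasets, dims, config = icaConfig(nRuns = 10L)) {
  res <- lapply(dims, function(d) {
    cfg <- config
    cfg$nComponents <- as.integer(d)
    comp <- groupICA(datasets, cfg)
    data.frame(dim = d, meanStability = mean(stabilityIndex(comp)),
               minStability = min(stabilityIndex(comp)))
  })
  do.call(rbind, res)
}
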