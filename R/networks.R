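## Spatial thresholding, 18-connectivity cluster labeling, ICA-vs-voxelwise
## overlap classification, ROI connectivity permutation testing, and
## time-point snapshot maps.

#' Threshold a statistic volume into a binary mask
#'
#' Default rule for IC maps is |z| >= 3 (the map scaling is z-scored; note
#' the binarisation rule for IC maps is a package convention, configurable
#' here, not a field standard).  For voxel-wise correlation maps pass the
#' model's permutation threshold with \code{absolute = FALSE}.
#'
#' @param volume numeric 3-D array (or vector) of statistic values.
#' @param threshold cutoff value.
#' @param absolute threshold |value| (TRUE, sign-invariant, for IC maps) or
#'   the signed value (FALSE, for correlation maps).
#' @return logical mask of the same shape.
#' @export
thresholdMap <- function(volume, threshold = 3, absolute = TRUE) {
  if (!all(is.finite(volume))) stop("statistic values must be finite")
  m <- if (absolute) abs(volume) > threshold else volume > threshold
  if (!any(m)) warning("empty mask after thresholding")
  m
}

## Relative offsets of the 18-neighborhood: face- (6) and edge- (12)
## adjacent voxels; vertex-adjacent ones (|dx|+|dy|+|dz| = 3) are excluded.
neighborOffsets18 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[rowSums(abs(g)) %in% c(1, 2), ]
  as.matrix(g)
}

#' Label connected clusters under 18-connectivity
#'
#' Connected-component labeling of a binary 3-D mask where voxels are
#' neighbors when they share a face or an edge (18-connectivity).
#' Components whose size does not strictly exceed \code{minClusterSize}
#' voxels are discarded; retained clusters are relabeled contiguously from 1
#' in decreasing size order.
#'
#' @param mask logical 3-D array.
#' @param connectivity only 18 is implemented (the criterion used for the
#'   overlap analysis).
#' @param minClusterSize keep only clusters strictly larger than this many
#'   voxels (default 125, so a 5x5x5 solid cube is discarded).
#' @param data optional time x voxels matrix in mask-linear order (over
#'   \code{which(maskArray)}) from which per-cluster mean time courses are
#'   computed; \code{maskArray} gives the linearisation mask (defaults to
#'   \code{mask} itself... see Details).
#' @param maskArray logical array defining the column order of \code{data};
#'   defaults to \code{mask}.
#' @return a \linkS4class{ClusterSet}.
#' @examples
#' m <- array(FALSE, c(10, 10, 10)); m[2:6, 2:6, 2:6] <- TRUE  # 125 voxels
#' length(labelClusters(m)@sizes)  # 0: not strictly larger than 125
#' @export
labelClusters <- function(mask, connectivity = 18L, minClusterSize = 125L,
                          data = NULL, maskArray = NULL) {
  if (connectivity != 18L) stop("only 18-connectivity is implemented")
  dims <- dim(mask)
  lab <- array(0L, dims)
  off <- neighborOffsets18()
  active <- which(mask)
  inMask <- array(FALSE, dims); inMask[active] <- TRUE
  visited <- array(FALSE, dims)
  comps <- list()
  for (seed in active) {
    if (visited[seed]) next
    ## vectorised BFS from seed
    comp <- integer(0)
    frontier <- seed
    visited[seed] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      fc <- arrayInd(frontier, dims)
      ## all neighbors of the frontier
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(o)
        sweep(fc, 2, off[o, ], "+")))
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * dims[1] +
                      (nb[, 3] - 1L) * dims[1] * dims[2])
      lin <- lin[inMask[lin] & !visited[lin]]
      visited[lin] <- TRUE
      frontier <- lin
    }
    comps[[length(comps) + 1L]] <- comp
  }
  sizes <- vapply(comps, length, integer(1))
  keep <- which(sizes > minClusterSize)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  tcs <- matrix(0, 0, 0)
  if (!is.null(data)) {
    if (is.null(maskArray)) maskArray <- mask
    colOf <- array(NA_integer_, dims)
    colOf[which(maskArray)] <- seq_len(sum(maskArray))
    tcs <- matrix(0, length(keep), nrow(data))
  }
  for (j in seq_along(keep)) {
    lab[comps[[keep[j]]]] <- j
    if (!is.null(data)) {
      cols <- colOf[comps[[keep[j]]]]
      cols <- cols[!is.na(cols)]
      tcs[j, ] <- rowMeans(data[, cols, drop = FALSE])
    }
  }
  new("ClusterSet", labels = lab, sizes = as.integer(sizes[keep]),
      meanTimecourses = tcs,
      provenance = rep("unknown", length(keep)),
      connectivity = 18L, minClusterSize = as.integer(minClusterSize))
}

#' Classify voxel-wise vs IC mask overlap
#'
#' Labels every voxel of co-registered binary masks into one of eight
#' categories, mirroring the overlay convention of showing voxel-only areas
#' in green, the two ICs in red and blue, and pairwise/triple overlaps in
#' yellow, cyan and white.
#'
#' @param voxelMask voxel-wise GLM suprathreshold mask.
#' @param icMask1,icMask2 thresholded IC masks, same shape.
#' @return list with \code{categories} (integer array: 0 none, 1
#'   voxel_only, 2 ic1_only, 3 ic2_only, 4 voxel+ic1, 5 voxel+ic2, 6
#'   ic1+ic2, 7 all three) and \code{counts} (named vector of category
#'   sizes).
#' @export
classifyOverlap <- function(voxelMask, icMask1, icMask2) {
  if (!all(dim(voxelMask) == dim(icMask1)) ||
      !all(dim(voxelMask) == dim(icMask2)))
    stop("masks must have identical shapes")
  code <- voxelMask + 2L * icMask1 + 4L * icMask2
  ## remap binary code (v + 2*i1 + 4*i2) to the documented category order
  remap <- c(`0` = 0L, `1` = 1L, `2` = 2L, `4` = 3L, `3` = 4L, `5` = 5L,
             `6` = 6L, `7` = 7L)
  cat <- array(remap[as.character(code)], dim(voxelMask))
  nm <- c("none", "voxel_only", "ic1_only", "ic2_only", "voxel_ic1",
          "voxel_ic2", "ic1_ic2", "all")
  counts <- vapply(0:7, function(k) sum(cat == k), integer(1))
  names(counts) <- nm
  list(categories = cat, counts = counts)
}

#' ROI functional-connectivity permutation threshold
#'
#' Permutation null for the maximum correlation between cluster mean time
#' courses: each permutation selects a seed ROI uniformly at random,
#' circularly shifts its time course by at least \code{minShift} samples,
#' correlates it with the time courses of all other ROIs, and saves the
#' maximum value (signed by default; \code{absolute = TRUE} uses |r|).  The
#' observed pairwise correlations exceeding the threshold are flagged
#' significant.
#'
#' All shift/seed combinations are precomputed via FFT cross-correlation, so
#' very large permutation counts (the full-scale run used 1e7; the desk
#' default is 1e5) cost only the random draws.
#'
#' @param timecourses ROIs x time matrix (e.g.
#'   \code{clusterSet@meanTimecourses}).
#' @param nPermutations number of permutations.
#' @param minShift minimum circular shift in samples.
#' @param p significance level for the reported threshold.
#' @param seed RNG seed.
#' @param absolute use the maximum of |r| instead of the signed maximum.
#' @return list with \code{null} (a \linkS4class{ConnectivityNull}),
#'   \code{threshold}, \code{observed} (ROI x ROI correlation matrix) and
#'   \code{significantPairs} (data.frame i, j, r).
#' @export
roiConnectivityThreshold <- function(timecourses, nPermutations = 1e5,
                                     minShift = 5L, p = 0.001, seed = 1L,
                                     absolute = FALSE) {
  R <- nrow(timecourses)
  Tt <- ncol(timecourses)
  if (R < 2) stop("need at least 2 ROIs")
  if (Tt <= 2 * minShift) stop("time courses too short for the shift range")
  Z <- t(apply(timecourses, 1, function(x) {
    xc <- x - mean(x); xc / sqrt(sum(xc^2))
  }))
  ## cc[s+1, j, l] = cor(rotate(ROI j, s), ROI l) via FFT cross-correlation
  maxR <- matrix(-Inf, Tt, R)          # max over other ROIs, per (shift, seed)
  for (j in seq_len(R)) {
    Qj <- matrix(Z[j, ], ncol = 1)
    for (l in seq_len(R)) {
      if (l == j) next
      cc <- as.numeric(circularCrossprod(Qj, Z[l, ]))
      ## circularCrossprod rotates its second argument; rotating l by -s is
      ## equivalent to rotating the seed j by s, which is what the scheme does
      if (absolute) cc <- abs(cc)
      maxR[, j] <- pmax(maxR[, j], cc)
    }
  }
  shiftRange <- minShift:(Tt - minShift)
  log <- withSeed(seed, {
    sj <- sample.int(R, nPermutations, replace = TRUE)
    ss <- shiftRange[sample.int(length(shiftRange), nPermutations,
                                replace = TRUE)]
    list(seedRoi = sj, shift = ss)
  })
  draws <- maxR[cbind(log$shift + 1L, log$seedRoi)]
  bt <- binTable(draws)
  thr <- binThreshold(bt$centers, bt$prob, p)
  tailP <- mean(draws >= thr)
  null <- new("ConnectivityNull",
              maxR = if (length(draws) <= 1e6) draws else
                draws[seq_len(1e6)],
              binCenters = bt$centers, binProb = bt$prob,
              nPermutations = as.integer(nPermutations),
              minShift = as.integer(minShift),
              mcSe = sqrt(tailP * (1 - tailP) / nPermutations))
  obs <- stats::cor(t(timecourses))
  sig <- which(upper.tri(obs) & obs > thr, arr.ind = TRUE)
  list(null = null, threshold = thr, observed = obs,
       significantPairs = data.frame(i = sig[, 1], j = sig[, 2],
                                     r = obs[sig]),
       permutationLog = if (nPermutations <= 1e6)
         data.frame(seedRoi = log$seedRoi, shift = log$shift) else NULL)
}

#' @rdname thresholdAt
#' @export
setMethod("thresholdAt", "ConnectivityNull", function(x, p) {
  binThreshold(x@binCenters, x@binProb, p)
})

#' Snapshot activity map at a single time point
#'
#' Across-subject mean of standardised voxel signals at one time point,
#' thresholded under the assumption that the mean of n standard-normal
#' samples is null: the one-sided threshold is \code{qnorm(1 - p) / sqrt(n)}
#' (a two-sided option halves p and applies |mean|).
#'
#' @param datasets list of standardised \linkS4class{BoldDataset}.
#' @param t time index (TR units).
#' @param p significance level.
#' @param twoSided use a two-sided threshold on |mean|.
#' @return list with \code{values} (mean volume as a 3-D array, 0 outside
#'   the mask), \code{suprathreshold} (logical array) and \code{threshold}.
#' @export
snapshotMap <- function(datasets, t, p = 0.05, twoSided = FALSE) {
  n <- length(datasets)
  if (n < 2) stop("need at least 2 subjects")
  rows <- vapply(datasets, function(d) d@data[t, ], numeric(nVoxels(datasets[[1]])))
  mu <- rowMeans(rows)
  thr <- stats::qnorm(1 - (if (twoSided) p / 2 else p)) / sqrt(n)
  mask <- datasets[[1]]@mask
  vol <- array(0, dim(mask)); vol[which(mask)] <- mu
  supra <- array(FALSE, dim(mask))
  supra[which(mask)] <- if (twoSided) abs(mu) > thr else mu > thr
  list(values = vol, suprathreshold = supra, threshold = thr)
}
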