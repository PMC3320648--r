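## Central S4 containers for the annotated-film fMRI pipeline.

#' AnnotationTrack: one named stimulus feature sampled at 1 Hz
#'
#' A single stimulus annotation time course.  Boxcar tracks are binary
#' presence indicators (e.g. speech on/off), ordinal tracks are manual motion
#' scores in 0--4, continuous tracks are real-valued descriptors (e.g. RMS
#' energy).  The sampling rate is fixed at 1 Hz throughout the pipeline.
#'
#' @slot name feature name.
#' @slot modality \code{"auditory"} or \code{"visual"}.
#' @slot kind \code{"boxcar"}, \code{"continuous"} or \code{"ordinal"}.
#' @slot rate sampling rate in Hz (always 1).
#' @slot values numeric vector of samples.
#' @export
setClass("AnnotationTrack",
  representation(name = "character", modality = "character",
                 kind = "character", rate = "numeric", values = "numeric"),
  prototype(rate = 1))

setValidity("AnnotationTrack", function(object) {
  msg <- NULL
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!object@modality %in% c("auditory", "visual"))
    msg <- c(msg, "'modality' must be 'auditory' or 'visual'")
  if (!object@kind %in% c("boxcar", "continuous", "ordinal"))
    msg <- c(msg, "'kind' must be 'boxcar', 'continuous' or 'ordinal'")
  if (!identical(object@rate, 1))
    msg <- c(msg, "'rate' is fixed at 1 Hz")
  if (anyNA(object@values))
    msg <- c(msg, "'values' must not contain NA (apply silence substitution first)")
  if (object@kind == "boxcar" && !all(object@values %in% c(0, 1)))
    msg <- c(msg, "boxcar values must be 0/1")
  if (object@kind == "ordinal" && !all(object@values %in% 0:4))
    msg <- c(msg, "ordinal values must be integers in 0..4")
  if (is.null(msg)) TRUE else msg
})

#' AnnotationSet: a named collection of AnnotationTracks
#'
#' @slot tracks list of \linkS4class{AnnotationTrack}, all the same length.
#' @export
setClass("AnnotationSet", representation(tracks = "list"))

setValidity("AnnotationSet", function(object) {
  if (!length(object@tracks)) return(TRUE)
  ok <- vapply(object@tracks, is, logical(1), "AnnotationTrack")
  if (!all(ok)) return("all elements must be AnnotationTrack objects")
  lens <- vapply(object@tracks, function(t) length(t@values), integer(1))
  if (length(unique(lens)) > 1L) return("all tracks must have equal length")
  nm <- vapply(object@tracks, function(t) t@name, character(1))
  if (anyDuplicated(nm)) return("track names must be unique")
  TRUE
})

#' DesignMatrix: HRF-convolved, TR-sampled regressor collection
#'
#' One GLM model (auditory, visual, or custom): each column is an annotation
#' track convolved with the canonical HRF and resampled on the TR grid.
#'
#' @slot modelId model label, e.g. \code{"auditory"}.
#' @slot features regressor (column) names.
#' @slot matrix time(TR) x features numeric matrix.
#' @slot tr repetition time in seconds.
#' @export
setClass("DesignMatrix",
  representation(modelId = "character", features = "character",
                 matrix = "matrix", tr = "numeric"))

setValidity("DesignMatrix", function(object) {
  msg <- NULL
  if (!all(is.finite(object@matrix)))
    msg <- c(msg, "design matrix entries must be finite")
  if (ncol(object@matrix) != length(object@features))
    msg <- c(msg, "'features' length must match column count")
  if (ncol(object@matrix) > 0 && any(apply(object@matrix, 2, function(z) all(z == 0))))
    msg <- c(msg, "design matrix must not contain an all-zero column")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "'tr' must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' BoldDataset: one subject's masked BOLD matrix
#'
#' Voxel time series inside a brain mask, stored time x voxels.  Voxel order
#' follows the linear order of \code{TRUE} entries in the mask array (first
#' array index fastest), so datasets sharing a mask are column-aligned.
#'
#' @slot data time x voxels numeric matrix.
#' @slot mask logical 3-D array; \code{sum(mask)} equals \code{ncol(data)}.
#' @slot tr repetition time in seconds.
#' @slot subjectId subject label.
#' @slot flaggedVoxels integer indices of voxels flagged during processing
#'   (e.g. zero-variance voxels zeroed by standardisation).
#' @export
setClass("BoldDataset",
  representation(data = "matrix", mask = "array", tr = "numeric",
                 subjectId = "character", flaggedVoxels = "integer"),
  prototype(flaggedVoxels = integer(0), subjectId = "subject"))

setValidity("BoldDataset", function(object) {
  msg <- NULL
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    msg <- c(msg, "'mask' must be a logical 3-D array")
  else if (sum(object@mask) != ncol(object@data))
    msg <- c(msg, "mask voxel count must equal ncol(data)")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "BOLD data must be finite")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "'tr' must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' ComponentSet: group spatial ICA result
#'
#' Spatial maps, stability indices from bootstrapped re-estimation, and
#' (after back-reconstruction) group and subject-level component time
#' courses.  In spatial ICA a component time course is the spatial-map
#' weighted average of the voxel time courses.
#'
#' @slot spatialMaps components x voxels matrix, z-scored per component (the
#'   reporting/thresholding scale).
#' @slot rawMaps the same maps on their estimation scale (no centering);
#'   used for back-reconstruction so the projection is not distorted by the
#'   per-map offset that z-scoring introduces.
#' @slot groupTimecourses components x time matrix (may be 0-row before
#'   back-reconstruction).
#' @slot subjectTimecourses list of components x time matrices, one per
#'   subject (empty before back-reconstruction).
#' @slot stabilityIndex per-component mean pairwise intra-cluster |spatial r|.
#' @slot runCount number of distinct ICA runs contributing to each cluster.
#' @slot nRuns total number of ICA runs pooled.
#' @slot maskDim integer dimensions of the originating mask array.
#' @export
setClass("ComponentSet",
  representation(spatialMaps = "matrix", rawMaps = "matrix",
                 groupTimecourses = "matrix",
                 subjectTimecourses = "list", stabilityIndex = "numeric",
                 runCount = "integer", nRuns = "integer", maskDim = "integer"),
  prototype(rawMaps = matrix(0, 0, 0), groupTimecourses = matrix(0, 0, 0),
            subjectTimecourses = list(), nRuns = 1L, maskDim = integer(0)))

setValidity("ComponentSet", function(object) {
  msg <- NULL
  k <- nrow(object@spatialMaps)
  if (length(object@stabilityIndex) != k)
    msg <- c(msg, "one stability index per component required")
  if (any(object@stabilityIndex < 0 | object@stabilityIndex > 1 + 1e-12))
    msg <- c(msg, "stability index must lie in [0, 1]")
  if (length(object@runCount) != k)
    msg <- c(msg, "one run count per component required")
  if (nrow(object@groupTimecourses) > 0 && nrow(object@groupTimecourses) != k)
    msg <- c(msg, "groupTimecourses rows must match component count")
  if (is.null(msg)) TRUE else msg
})

#' ModelFit: annotation-GLM fit to one time course
#'
#' Ordinary least squares fit of a regressor collection (plus intercept) to an
#' observed component or voxel time course.  \code{r} is the Pearson
#' correlation of fitted and observed series (the multiple correlation), and
#' normalized weights scale the betas so the main explanatory variable (the
#' largest |beta|) receives weight 1 (sign preserved).
#'
#' @slot betas named per-feature coefficients (intercept excluded).
#' @slot intercept fitted intercept.
#' @slot normalizedWeights betas / max|beta|.
#' @slot fitted fitted time series.
#' @slot r Pearson correlation of fitted vs observed.
#' @slot rSquared coefficient of determination (= r^2).
#' @slot modelId model label.
#' @export
setClass("ModelFit",
  representation(betas = "numeric", intercept = "numeric",
                 normalizedWeights = "numeric", fitted = "numeric",
                 r = "numeric", rSquared = "numeric", modelId = "character"),
  prototype(modelId = "custom"))

setValidity("ModelFit", function(object) {
  msg <- NULL
  if (abs(object@rSquared - object@r^2) > 1e-12)
    msg <- c(msg, "rSquared must equal r^2")
  if (length(object@normalizedWeights) &&
      max(abs(object@normalizedWeights)) > 1 + 1e-9)
    msg <- c(msg, "|normalized weights| must not exceed 1")
  if (is.null(msg)) TRUE else msg
})

#' IscResult: inter-subject correlation of one component
#'
#' Pairwise Pearson correlations of subject time courses; the mean is taken
#' in Fisher-z space and back-transformed.  Dispersion across pairs is
#' reported both as variance and as SD.
#'
#' @slot pairwiseR per-pair correlations (clipped away from +-1).
#' @slot meanR Fisher-z mean, back-transformed.
#' @slot dispersion variance of the pairwise correlations.
#' @slot dispersionSd standard deviation of the pairwise correlations.
#' @slot pValue circular-shift permutation p-value (NA if not computed).
#' @export
setClass("IscResult",
  representation(pairwiseR = "numeric", meanR = "numeric",
                 dispersion = "numeric", dispersionSd = "numeric",
                 pValue = "numeric"),
  prototype(pValue = NA_real_))

setValidity("IscResult", function(object) {
  msg <- NULL
  if (any(abs(object@pairwiseR) >= 1))
    msg <- c(msg, "pairwise correlations must be clipped inside (-1, 1)")
  if (abs(object@meanR) >= 1)
    msg <- c(msg, "meanR must lie inside (-1, 1)")
  if (is.null(msg)) TRUE else msg
})

#' PermutationNull: circular-shift null distribution of model correlations
#'
#' Empirical null of correlation coefficients obtained by refitting a model
#' to every circular rotation of the observed time courses.  The distribution
#' is summarised as a 100-bin lookup table (probability mass at bin centers);
#' \code{\link{thresholdAt}} interpolates linearly between bins.
#'
#' @slot modelId model label.
#' @slot rSamples sorted correlation realizations.
#' @slot binCenters centers of the 100 bins.
#' @slot binProb probability mass per bin (sums to 1).
#' @slot nSeries number of time series contributing rotations.
#' @slot nTime series length (number of distinct rotations per series when
#'   the step is 1).
#' @slot shiftStep rotation increment (1 for model nulls, 2 for
#'   single-annotation nulls).
#' @export
setClass("PermutationNull",
  representation(modelId = "character", rSamples = "numeric",
                 binCenters = "numeric", binProb = "numeric",
                 nSeries = "integer", nTime = "integer", shiftStep = "integer"),
  prototype(shiftStep = 1L))

setValidity("PermutationNull", function(object) {
  msg <- NULL
  if (abs(sum(object@binProb) - 1) > 1e-9)
    msg <- c(msg, "bin probabilities must sum to 1")
  if (is.unsorted(object@rSamples))
    msg <- c(msg, "rSamples must be sorted")
  if (is.null(msg)) TRUE else msg
})

#' ClusterSet: labeled suprathreshold clusters
#'
#' Connected components of a binary 3-D mask under 18-connectivity (voxels
#' sharing a face or an edge, not only a vertex), with components at or below
#' the minimum size discarded.
#'
#' @slot labels integer 3-D array; 0 = background, clusters numbered from 1.
#' @slot sizes voxel count per retained cluster.
#' @slot meanTimecourses clusters x time matrix of mean time courses (0-row
#'   when no data were attached).
#' @slot provenance per-cluster origin: \code{"ic_only"}, \code{"voxel_only"}
#'   or \code{"overlap"} (or \code{"unknown"}).
#' @slot connectivity connectivity criterion used (18).
#' @slot minClusterSize size threshold; only clusters strictly larger are kept.
#' @export
setClass("ClusterSet",
  representation(labels = "array", sizes = "integer",
                 meanTimecourses = "matrix", provenance = "character",
                 connectivity = "integer", minClusterSize = "integer"),
  prototype(meanTimecourses = matrix(0, 0, 0), provenance = character(0),
            connectivity = 18L, minClusterSize = 125L))

setValidity("ClusterSet", function(object) {
  msg <- NULL
  n <- length(object@sizes)
  lab <- object@labels
  if (n > 0 && !setequal(setdiff(unique(as.integer(lab)), 0L), seq_len(n)))
    msg <- c(msg, "labels must be contiguous from 1")
  if (n > 0 && any(object@sizes <= object@minClusterSize))
    msg <- c(msg, "every retained cluster must exceed minClusterSize")
  if (is.null(msg)) TRUE else msg
})

#' ConnectivityNull: max-correlation permutation null for ROI connectivity
#'
#' Null distribution of the maximum correlation between a randomly chosen
#' seed ROI, circularly shifted by at least \code{minShift} samples, and all
#' other ROI mean time courses.
#'
#' @slot maxR permutation samples of the maximum correlation (possibly
#'   subsampled for storage; the bin table is built from all draws).
#' @slot binCenters,binProb 100-bin lookup table of the full distribution.
#' @slot nPermutations number of permutations drawn.
#' @slot minShift minimum circular shift in samples.
#' @slot mcSe Monte-Carlo standard error of the tail probability at the
#'   reported threshold.
#' @export
setClass("ConnectivityNull",
  representation(maxR = "numeric", binCenters = "numeric", binProb = "numeric",
                 nPermutations = "integer", minShift = "integer",
                 mcSe = "numeric"),
  prototype(mcSe = NA_real_))

setValidity("ConnectivityNull", function(object) {
  msg <- NULL
  if (any(abs(object@maxR) > 1 + 1e-12))
    msg <- c(msg, "correlation samples must lie in [-1, 1]")
  if (abs(sum(object@binProb) - 1) > 1e-9)
    msg <- c(msg, "bin probabilities must sum to 1")
  if (is.null(msg)) TRUE else msg
})

## ------------------------------------------------------------------ show

setMethod("show", "AnnotationTrack", function(object) {
  cat(sprintf("AnnotationTrack '%s' (%s, %s): %d samples @ %g Hz\n",
              object@name, object@modality, object@kind,
              length(object@values), object@rate))
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet with %d tracks x %d samples\n",
              length(object@tracks),
              if (length(object@tracks)) length(object@tracks[[1]]@values) else 0L))
  for (t in object@tracks)
    cat(sprintf("  %-20s %-8s %s\n", t@name, t@modality, t@kind))
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix '%s': %d timepoints (TR %g s) x %d regressors\n",
              object@modelId, nrow(object@matrix), object@tr,
              ncol(object@matrix)))
  cat("  features:", paste(object@features, collapse = ", "), "\n")
})

setMethod("show", "BoldDataset", function(object) {
  cat(sprintf("BoldDataset '%s': %d timepoints x %d voxels (TR %g s), mask %s\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@tr, paste(dim(object@mask), collapse = "x")))
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: %d components x %d voxels (%d runs pooled)\n",
              nrow(object@spatialMaps), ncol(object@spatialMaps), object@nRuns))
  cat(sprintf("  stability: %s\n",
              paste(sprintf("%.3f", object@stabilityIndex), collapse = " ")))
  if (nrow(object@groupTimecourses))
    cat(sprintf("  time courses: %d timepoints, %d subjects\n",
                ncol(object@groupTimecourses), length(object@subjectTimecourses)))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit '%s': r = %.4f, R^2 = %.4f\n",
              object@modelId, object@r, object@rSquared))
  w <- round(object@normalizedWeights, 3)
  cat("  normalized weights:",
      paste(sprintf("%s=%g", names(object@betas), w), collapse = ", "), "\n")
})

setMethod("show", "IscResult", function(object) {
  cat(sprintf("IscResult: mean r = %.3f (var %.4f, sd %.4f across %d pairs), p = %s\n",
              object@meanR, object@dispersion, object@dispersionSd,
              length(object@pairwiseR), format(object@pValue)))
})

setMethod("show", "PermutationNull", function(object) {
  cat(sprintf("PermutationNull '%s': %d realizations (%d series x length %d, step %d)\n",
              object@modelId, length(object@rSamples), object@nSeries,
              object@nTime, object@shiftStep))
  cat(sprintf("  threshold at p=0.001: r > %.4f\n", thresholdAt(object, 0.001)))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d clusters (> %d voxels, %d-connectivity); sizes: %s\n",
              length(object@sizes), object@minClusterSize, object@connectivity,
              paste(object@sizes, collapse = " ")))
})

setMethod("show", "ConnectivityNull", function(object) {
  cat(sprintf("ConnectivityNull: %d permutations, min shift %d samples\n",
              object@nPermutations, object@minShift))
  cat(sprintf("  threshold at p=0.001: r = %.4f\n", thresholdAt(object, 0.001)))
})

## ------------------------------------------------------------------ accessors

#' @rdname trackValues
#' @export
setMethod("trackValues", "AnnotationTrack", function(x) x@values)

#' @rdname designMatrix
#' @export
setMethod("designMatrix", "DesignMatrix", function(x) {
  m <- x@matrix
  colnames(m) <- x@features
  m
})

#' @rdname boldMatrix
#' @export
setMethod("boldMatrix", "BoldDataset", function(x) x@data)

#' @rdname nTimepoints
#' @export
setMethod("nTimepoints", "BoldDataset", function(x) nrow(x@data))

#' @rdname nTimepoints
#' @export
setMethod("nTimepoints", "DesignMatrix", function(x) nrow(x@matrix))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "BoldDataset", function(x) ncol(x@data))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "ComponentSet", function(x) ncol(x@spatialMaps))

#' @rdname nComponents
#' @export
setMethod("nComponents", "ComponentSet", function(x) nrow(x@spatialMaps))

#' @rdname spatialMaps
#' @export
setMethod("spatialMaps", "ComponentSet", function(x) x@spatialMaps)

#' @rdname stabilityIndex
#' @export
setMethod("stabilityIndex", "ComponentSet", function(x) x@stabilityIndex)

#' @rdname runCount
#' @export
setMethod("runCount", "ComponentSet", function(x) x@runCount)

#' @rdname groupTimecourses
#' @export
setMethod("groupTimecourses", "ComponentSet", function(x) x@groupTimecourses)

#' @rdname subjectTimecourses
#' @export
setMethod("subjectTimecourses", "ComponentSet", function(x) x@subjectTimecourses)

#' Subset a ComponentSet
#'
#' @param x a \linkS4class{ComponentSet}.
#' @param i component indices (integer or logical).
#' @param j,drop,... ignored.
#' @return the subsetted \linkS4class{ComponentSet}.
#' @export
setMethod("[", "ComponentSet", function(x, i, j, ..., drop = FALSE) {
  new("ComponentSet",
      spatialMaps = x@spatialMaps[i, , drop = FALSE],
      rawMaps = if (nrow(x@rawMaps)) x@rawMaps[i, , drop = FALSE]
        else x@rawMaps,
      groupTimecourses = if (nrow(x@groupTimecourses))
        x@groupTimecourses[i, , drop = FALSE] else x@groupTimecourses,
      subjectTimecourses = lapply(x@subjectTimecourses,
                                  function(tc) tc[i, , drop = FALSE]),
      stabilityIndex = x@stabilityIndex[i],
      runCount = x@runCount[i],
      nRuns = x@nRuns,
      maskDim = x@maskDim)
})
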