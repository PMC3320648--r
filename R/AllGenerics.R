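#' @import methods
NULL

#' Interpolated permutation threshold
#'
#' Return the statistic value whose estimated upper-tail probability under a
#' permutation null distribution equals \code{p}.  The null is summarised as a
#' 100-bin lookup table of tail probabilities at bin centers; values between
#' centers are obtained by linear interpolation.
#'
#' @param x a \linkS4class{PermutationNull} or \linkS4class{ConnectivityNull}.
#' @param p numeric vector of upper-tail probabilities in (0, 1).
#' @return numeric vector of thresholds, monotone decreasing in \code{p}.
#' @export
setGeneric("thresholdAt", function(x, p) standardGeneric("thresholdAt"))

#' Number of timepoints
#' @param x an object with a time dimension.
#' @return integer count of timepoints (TR units).
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' Number of voxels inside the analysis mask
#' @param x an object carrying masked voxel data.
#' @return integer voxel count.
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' Number of components
#' @param x a \linkS4class{ComponentSet}.
#' @return integer component count.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Spatial maps accessor
#' @param x a \linkS4class{ComponentSet}.
#' @return components x voxels matrix of z-scored spatial maps.
#' @export
setGeneric("spatialMaps", function(x) standardGeneric("spatialMaps"))

#' Stability index accessor
#' @param x a \linkS4class{ComponentSet}.
#' @return per-component mean intra-cluster |spatial correlation|.
#' @export
setGeneric("stabilityIndex", function(x) standardGeneric("stabilityIndex"))

#' Run count accessor
#' @param x a \linkS4class{ComponentSet}.
#' @return number of distinct ICA runs represented in each component cluster.
#' @export
setGeneric("runCount", function(x) standardGeneric("runCount"))

#' Group component time courses
#' @param x a \linkS4class{ComponentSet}.
#' @return components x time matrix (mean of subject back-reconstructions).
#' @export
setGeneric("groupTimecourses", function(x) standardGeneric("groupTimecourses"))

#' Subject-level back-reconstructed component time courses
#' @param x a \linkS4class{ComponentSet}.
#' @return list (one per subject) of components x time matrices.
#' @export
setGeneric("subjectTimecourses", function(x) standardGeneric("subjectTimecourses"))

#' BOLD data matrix accessor
#' @param x a \linkS4class{BoldDataset}.
#' @return time x voxels numeric matrix.
#' @export
setGeneric("boldMatrix", function(x) standardGeneric("boldMatrix"))

#' Track values accessor
#' @param x an \linkS4class{AnnotationTrack}.
#' @return numeric vector of 1-Hz samples.
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' Design matrix accessor
#' @param x a \linkS4class{DesignMatrix}.
#' @return time(TR) x features numeric matrix.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))
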