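#' Create an annotation track
#'
#' @param name feature name.
#' @param values numeric vector of 1-Hz samples.
#' @param modality \code{"auditory"} or \code{"visual"}.
#' @param kind \code{"boxcar"}, \code{"continuous"} or \code{"ordinal"}.
#' @return an \linkS4class{AnnotationTrack}.
#' @examples
#' annotationTrack("speech", c(0, 1, 1, 0), "auditory", "boxcar")
#' @export
annotationTrack <- function(name, values,
                            modality = c("auditory", "visual"),
                            kind = c("continuous", "boxcar", "ordinal")) {
  new("AnnotationTrack", name = name, values = as.numeric(values),
      modality = match.arg(modality), kind = match.arg(kind), rate = 1)
}

#' Create an annotation set
#'
#' @param tracks list of \linkS4class{AnnotationTrack} objects of equal length.
#' @return an \linkS4class{AnnotationSet}.
#' @export
annotationSet <- function(tracks) {
  names(tracks) <- vapply(tracks, function(t) t@name, character(1))
  new("AnnotationSet", tracks = tracks)
}

#' Names of the tracks in an annotation set
#' @param set an \linkS4class{AnnotationSet}.
#' @return character vector of track names.
#' @export
trackNames <- function(set) {
  vapply(set@tracks, function(t) t@name, character(1))
}

#' Extract one track by name
#' @param set an \linkS4class{AnnotationSet}.
#' @param name track name.
#' @return the \linkS4class{AnnotationTrack}.
#' @export
getTrack <- function(set, name) {
  i <- match(name, trackNames(set))
  if (is.na(i)) stop("no track named '", name, "'")
  set@tracks[[i]]
}

#' Subset an annotation set by modality or name
#' @param set an \linkS4class{AnnotationSet}.
#' @param modality optional modality filter.
#' @param names optional name filter.
#' @return an \linkS4class{AnnotationSet}.
#' @export
subsetTracks <- function(set, modality = NULL, names = NULL) {
  keep <- rep(TRUE, length(set@tracks))
  if (!is.null(modality))
    keep <- keep & vapply(set@tracks, function(t) t@modality, character(1)) %in% modality
  if (!is.null(names))
    keep <- keep & trackNames(set) %in% names
  annotationSet(set@tracks[keep])
}

#' Annotation set as a value matrix
#' @param set an \linkS4class{AnnotationSet}.
#' @return samples x tracks numeric matrix with track names as columns.
#' @export
trackMatrix <- function(set) {
  m <- vapply(set@tracks, function(t) t@values,
              numeric(length(set@tracks[[1]]@values)))
  colnames(m) <- trackNames(set)
  m
}
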