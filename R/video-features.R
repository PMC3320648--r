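## Visual annotation: DCT high-pass contrast-edge density and motion scoring
## from object tracks.

#' Edge filter specification
#'
#' The contrast-edge detector high-pass filters each frame in the 2-D
#' discrete cosine transform domain.  A coefficient at index (kx, ky) of an
#' Nx x Ny frame has radial frequency \code{sqrt((pi*kx/Nx)^2 +
#' (pi*ky/Ny)^2)} rad/pixel; coefficients below the cutoff are zeroed.  The
#' default cutoff of 2*pi/16 rad/pixel retains only sharp contrast edges.
#'
#' @param cutoff cutoff in rad/pixel, in (0, pi).
#' @param maskGeometry \code{"radial"} (isotropic threshold on the radial
#'   frequency; the default, since the cutoff is a scalar) or
#'   \code{"separable"} (threshold each axis independently).
#' @return list of class \code{"EdgeFilterSpec"}.
#' @export
edgeFilterSpec <- function(cutoff = 2 * pi / 16,
                           maskGeometry = c("radial", "separable")) {
  if (cutoff <= 0 || cutoff >= pi) stop("cutoff must lie in (0, pi)")
  structure(list(cutoff = cutoff, maskGeometry = match.arg(maskGeometry)),
            class = "EdgeFilterSpec")
}

#' Motion scoring specification
#'
#' Thresholds mapping object area and speed to 0--2 scores.  Area is the
#' bounding-box fraction of the frame: below the first break scores 0,
#' between the breaks (inclusive) 1, above the second break 2.  Speed is the
#' sum of instantaneous centroid displacements within a 1-s window
#' (pixels/second): below 15 scores 0, 15--50 scores 1, above 50 scores 2.
#'
#' @param areaBreaks two increasing fractions of frame area.
#' @param speedBreaks two increasing speeds in px/s.
#' @param window scoring window in seconds.
#' @return list of class \code{"MotionScoringSpec"}.
#' @export
motionScoringSpec <- function(areaBreaks = c(1 / 10, 1 / 6),
                              speedBreaks = c(15, 50), window = 1) {
  if (any(diff(areaBreaks) <= 0) || any(diff(speedBreaks) <= 0))
    stop("breaks must be strictly increasing")
  structure(list(areaBreaks = areaBreaks, speedBreaks = speedBreaks,
                 window = window),
            class = "MotionScoringSpec")
}

## Orthonormal DCT-II matrix of order n (rows = frequency index 0..n-1).
dctMatrix <- function(n) {
  k <- seq_len(n) - 1
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

#' Contrast-edge density of a frame sequence
#'
#' Per frame: 2-D DCT, zero all coefficients whose radial frequency falls
#' below the cutoff, inverse DCT, absolute value, mean over pixels.  Frame
#' values are then averaged within non-overlapping 1-s windows to give a
#' 1-Hz visual annotation track.  The measure is invariant to adding a
#' constant to all pixels (the DC coefficient is always removed) and scales
#' linearly with contrast.
#'
#' @param frames list of equal-size grayscale matrices with intensities in
#'   [0, 1].
#' @param fps frames per second (for 1-s windowing); use \code{fps = 1} with
#'   one frame per second.
#' @param spec an \code{\link{edgeFilterSpec}}.
#' @return an \linkS4class{AnnotationTrack} named \code{"edge_density"} with
#'   \code{floor(nframes / fps)} samples.
#' @export
edgeDensity <- function(frames, fps = 25L, spec = edgeFilterSpec()) {
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same size")
  ny <- dims[1, 1]; nx <- dims[2, 1]
  Cy <- dctMatrix(ny); Cx <- dctMatrix(nx)
  wy <- pi * (seq_len(ny) - 1) / ny
  wx <- pi * (seq_len(nx) - 1) / nx
  keep <- if (spec$maskGeometry == "radial") {
    outer(wy, wx, function(a, b) sqrt(a^2 + b^2)) >= spec$cutoff
  } else {
    outer(wy >= spec$cutoff, wx >= spec$cutoff, "|")
  }
  perFrame <- vapply(frames, function(img) {
    D <- Cy %*% img %*% t(Cx)
    D[!keep] <- 0
    mean(abs(t(Cy) %*% D %*% Cx))
  }, numeric(1))
  nWin <- floor(length(frames) / fps)
  vals <- vapply(seq_len(nWin), function(w)
    mean(perFrame[((w - 1) * fps + 1):(w * fps)]), numeric(1))
  annotationTrack("edge_density", vals, "visual", "continuous")
}

#' Manual motion score from size and strength sub-scores
#'
#' The overall motion score is the sum of the shot-size score (0--2) and the
#' motion-strength score (0--2) wherever motion is present; an object that is
#' not in motion scores 0 regardless of its size on screen.
#'
#' @param sizeScore integer 0--2 (long shot 0, medium 1, close-up 2);
#'   vectorised.
#' @param strengthScore integer 0--2 (none 0, intermediate 1, strong 2);
#'   vectorised.
#' @return integer motion score 0--4.
#' @examples
#' scoreMotionManual(2, 0)  # no motion: 0 regardless of size
#' scoreMotionManual(1, 2)  # 3
#' @export
scoreMotionManual <- function(sizeScore, strengthScore) {
  if (any(!sizeScore %in% 0:2) || any(!strengthScore %in% 0:2))
    stop("sub-scores must be integers in 0..2")
  ifelse(strengthScore == 0, 0L, as.integer(sizeScore + strengthScore))
}

#' Motion scores from object tracks
#'
#' Maps semi-automatic object tracks to 1-Hz per-category ordinal motion
#' tracks on the same 0--4 scale as the manual annotation.  Per object and
#' 1-s window, the bounding-box area fraction (mean over frames present) is
#' mapped to a 0--2 area score and the summed instantaneous centroid speed
#' to a 0--2 speed score using \code{spec}.  Per category the maxima of the
#' two measures across objects are taken independently and summed; when the
#' maximum speed score is 0 the window scores 0 regardless of area
#' (\code{zeroWhenStill = FALSE} disables that parity rule with the manual
#' scoring).
#'
#' @param tracks track data.frame as produced by \code{\link{genVideoTracks}}
#'   (columns frame, object_id, category, x0, y0, x1, y1, cx, cy).
#' @param frameArea full frame area in pixels^2.
#' @param fps frames per second of the track table.
#' @param nSeconds number of 1-s windows to emit; defaults to
#'   \code{floor(max(frame)/fps)}.
#' @param spec a \code{\link{motionScoringSpec}}.
#' @param zeroWhenStill force a window score of 0 when no object moved.
#' @return an \linkS4class{AnnotationSet} of ordinal visual tracks, one per
#'   category present.
#' @export
scoreMotionTracks <- function(tracks, frameArea, fps, nSeconds = NULL,
                              spec = motionScoringSpec(),
                              zeroWhenStill = TRUE) {
  known <- c("body", "head", "hand", "mechanical")
  if (!all(tracks$category %in% known))
    stop("unknown category: ",
         paste(setdiff(unique(tracks$category), known), collapse = ", "))
  if (is.null(nSeconds)) nSeconds <- floor(max(tracks$frame) / fps)
  ## instantaneous speed per frame over the whole track of each object
  ## (|centroid displacement| from the previous frame; 0 at track start)
  tracks <- tracks[order(tracks$object_id, tracks$frame), , drop = FALSE]
  oid <- factor(tracks$object_id, levels = unique(tracks$object_id))
  tracks$speed <- unlist(lapply(split(tracks, oid), function(ob) {
    c(0, sqrt(diff(ob$cx)^2 + diff(ob$cy)^2))
  }), use.names = FALSE)
  cats <- unique(tracks$category)
  out <- lapply(cats, function(cat) {
    sub <- tracks[tracks$category == cat, , drop = FALSE]
    score <- integer(nSeconds)
    for (w in seq_len(nSeconds)) {
      fr <- ((w - 1) * fps + 1):(w * fps)
      win <- sub[sub$frame %in% fr, , drop = FALSE]
      if (!nrow(win)) next
      areaSc <- speedSc <- integer(0)
      for (id in unique(win$object_id)) {
        ob <- win[win$object_id == id, , drop = FALSE]
        areaFrac <- mean((ob$x1 - ob$x0 + 1) * (ob$y1 - ob$y0 + 1)) / frameArea
        areaSc <- c(areaSc, breakScore(areaFrac, spec$areaBreaks))
        speedSc <- c(speedSc, breakScore(sum(ob$speed), spec$speedBreaks))
      }
      s <- max(areaSc) + max(speedSc)
      if (zeroWhenStill && max(speedSc) == 0) s <- 0L
      score[w] <- s
    }
    annotationTrack(cat, score, "visual", "ordinal")
  })
  annotationSet(out)
}

## 0 below the first break, 1 between the breaks inclusive, 2 above.
breakScore <- function(x, breaks) {
  if (x < breaks[1]) 0L else if (x <= breaks[2]) 1L else 2L
}
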