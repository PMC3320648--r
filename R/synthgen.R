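## Synthetic study generator: annotations, toy media, object tracks, and
## multi-subject BOLD-like data with planted spatial networks, so every
## downstream stage can be exercised against known ground truth.

#' Synthetic study configuration
#'
#' Defines the geometry and noise structure of a synthetic multi-subject
#' naturalistic-fMRI study.  The defaults give a desk-scale study (5 subjects,
#' 300 volumes of TR 2 s, 2000 mask voxels, 4 planted networks); the full
#' study geometry (10 subjects, 679 retained volumes after discarding the
#' first 10 of 689) is reachable through the arguments.
#'
#' Each planted network is a Gaussian blob in the mask whose time course is a
#' linear combination (rows of \code{weightMatrix}) of HRF-convolved
#' annotation regressors, plus shared AR(1) "network noise" common to all
#' subjects and an idiosyncratic AR(1) perturbation per subject.  Voxel-level
#' AR(1) noise is added on top.  The subject-noise SD controls the
#' inter-subject correlation of the planted component time courses.
#'
#' @param nSubjects number of subjects.
#' @param nTimepoints number of volumes (TR units); at least 20.
#' @param tr repetition time in seconds.
#' @param nVoxels number of in-mask voxels.
#' @param maskShape integer(3) array dimensions; \code{prod(maskShape)} must
#'   be at least \code{nVoxels}.
#' @param nComponents number of planted networks.
#' @param weightMatrix components x features matrix mapping design regressors
#'   to network time courses; \code{NULL} selects the built-in default
#'   (see \code{\link{defaultWeightMatrix}}).
#' @param sharedNoiseSd SD of the AR(1) noise shared by all subjects on each
#'   network time course.
#' @param subjectNoiseSd SD of the per-subject AR(1) perturbation of each
#'   network time course.
#' @param voxelNoiseSd SD of the per-voxel AR(1) measurement noise.
#' @param ar1Phi common AR(1) coefficient, in (-1, 1).
#' @param seed integer RNG seed; all outputs are reproducible from it.
#' @return a validated list of class \code{"SynthConfig"}.
#' @examples
#' cfg <- synthConfig(nSubjects = 2, nTimepoints = 40, nVoxels = 200,
#'                    maskShape = c(10, 5, 4), seed = 1)
#' @export
synthConfig <- function(nSubjects = 5L, nTimepoints = 300L, tr = 2,
                        nVoxels = 2000L, maskShape = c(20L, 10L, 10L),
                        nComponents = 4L, weightMatrix = NULL,
                        sharedNoiseSd = 0.25, subjectNoiseSd = 1,
                        voxelNoiseSd = 1, ar1Phi = 0.4, seed = 1L) {
  if (nTimepoints < 20) stop("nTimepoints must be at least 20")
  if (prod(maskShape) < nVoxels)
    stop("prod(maskShape) must be at least nVoxels")
  if (abs(ar1Phi) >= 1) stop("ar1Phi must lie in (-1, 1)")
  if (any(c(sharedNoiseSd, subjectNoiseSd, voxelNoiseSd) < 0))
    stop("noise SDs must be non-negative")
  if (is.null(weightMatrix)) weightMatrix <- defaultWeightMatrix(nComponents)
  if (nrow(weightMatrix) != nComponents)
    stop("weightMatrix must have nComponents rows")
  structure(list(nSubjects = as.integer(nSubjects),
                 nTimepoints = as.integer(nTimepoints), tr = tr,
                 nVoxels = as.integer(nVoxels),
                 maskShape = as.integer(maskShape),
                 nComponents = as.integer(nComponents),
                 weightMatrix = weightMatrix,
                 sharedNoiseSd = sharedNoiseSd,
                 subjectNoiseSd = subjectNoiseSd,
                 voxelNoiseSd = voxelNoiseSd,
                 ar1Phi = ar1Phi, seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Default network-to-feature weight matrix
#'
#' Rows are planted networks, columns the eight auditory features (four
#' boxcars: speech, music, lead and background singing; four continuous
#' descriptors: zero crossing rate, spectral spread, entropy, RMS energy).
#' The default networks emulate a low-level sound-energy network, a
#' speech-preferring network, a music network and a spectral-structure
#' network.
#'
#' @param nComponents number of networks (rows recycled/truncated from the
#'   four built-ins).
#' @return nComponents x 8 matrix with feature column names.
#' @export
defaultWeightMatrix <- function(nComponents = 4L) {
  feats <- c("speech", "music", "lead_singing", "background_singing",
             "zcr", "spectral_spread", "entropy", "rms")
  base <- rbind(
    c(0.0, 0.3, 0.0, 0.0, 0.3, 0.6, 0.0, 1.0),   # sound energy
    c(1.0, 0.4, 0.3, 0.0, 0.0, 0.0, 0.2, 0.0),   # speech network
    c(0.3, 1.0, 0.6, 0.4, 0.0, 0.0, 0.0, 0.2),   # music network
    c(-0.3, 0.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.0))  # spectral structure
  w <- base[rep_len(seq_len(nrow(base)), nComponents), , drop = FALSE]
  dimnames(w) <- list(NULL, feats)
  w
}

#' Generate synthetic stimulus annotations
#'
#' Produces the full annotation battery at 1 Hz: four auditory boxcars
#' (speech, music, lead and background singing), four continuous acoustic
#' descriptors (smoothed Gaussian noise clipped at zero), one continuous
#' edge-density track, and six ordinal motion-category tracks scored 0--4
#' (mechanical, hand, head, body, global, inferred).
#'
#' Boxcars are placed as random blocks until a target active fraction is
#' reached.  With \code{overlap = 0} the blocks of different boxcars are
#' drawn from disjoint free time, so no second of the stimulus has two
#' categories active; with \code{overlap > 0} each boxcar is placed
#' independently and natural overlap occurs.
#'
#' @param config a \code{\link{synthConfig}}; duration is
#'   \code{nTimepoints * tr} seconds.
#' @param density target active fraction of each boxcar.
#' @param overlap 0 forces disjoint boxcars; any positive value places them
#'   independently.
#' @param meanBlock mean boxcar block length in seconds.
#' @return an \linkS4class{AnnotationSet} with 15 tracks.
#' @examples
#' ann <- genAnnotations(synthConfig(nTimepoints = 60, nVoxels = 100,
#'                                   maskShape = c(5, 5, 4), seed = 2))
#' trackNames(ann)
#' @export
genAnnotations <- function(config, density = 0.3, overlap = 0.5,
                           meanBlock = 8) {
  dur <- as.integer(round(config$nTimepoints * config$tr))
  if (dur < 10) stop("invalid config: stimulus duration must be at least 10 s")
  withSeed(config$seed, {
    boxNames <- c("speech", "music", "lead_singing", "background_singing")
    occupied <- logical(dur)
    boxcars <- lapply(boxNames, function(nm) {
      v <- placeBlocks(dur, density, meanBlock,
                       free = if (overlap == 0) !occupied else NULL)
      if (overlap == 0) occupied <<- occupied | (v > 0)
      annotationTrack(nm, v, "auditory", "boxcar")
    })
    contNames <- c("zcr", "spectral_spread", "entropy", "rms")
    continuous <- lapply(contNames, function(nm) {
      v <- smoothedNoise(dur)
      annotationTrack(nm, pmax(v, 0), "auditory", "continuous")
    })
    edge <- annotationTrack("edge_density", pmax(smoothedNoise(dur), 0),
                            "visual", "continuous")
    motNames <- c("mechanical", "hand", "head", "body", "global", "inferred")
    motion <- lapply(motNames, function(nm) {
      act <- placeBlocks(dur, density, meanBlock)
      sc <- act
      on <- which(act > 0)
      if (length(on)) {
        ## constant score per block, 1..4
        blocks <- cumsum(c(TRUE, diff(on) > 1))
        sc[on] <- sample(1:4, max(blocks), replace = TRUE)[blocks]
      }
      annotationTrack(nm, sc, "visual", "ordinal")
    })
    annotationSet(c(boxcars, continuous, list(edge), motion))
  })
}

## Place ~density*n active seconds as geometric blocks; when `free` is given,
## blocks are only placed on free seconds (disjointness by construction).
placeBlocks <- function(n, density, meanBlock, free = NULL) {
  v <- numeric(n)
  target <- round(density * n)
  avail <- if (is.null(free)) rep(TRUE, n) else free
  placed <- 0L
  guard <- 0L
  while (placed < target && any(avail) && guard < 10000L) {
    guard <- guard + 1L
    len <- min(1L + stats::rgeom(1, 1 / meanBlock), target - placed)
    start <- sample(which(avail), 1L)
    idx <- start:min(n, start + len - 1L)
    idx <- idx[avail[idx]]
    ## keep the contiguous run beginning at start
    run <- cumsum(c(1L, diff(idx))) == seq_along(idx)
    idx <- idx[run]
    v[idx] <- 1
    avail[idx] <- FALSE
    placed <- placed + length(idx)
  }
  v
}

## Smoothed, positively shifted Gaussian noise (moving average, width w s).
smoothedNoise <- function(n, w = 5L, mean = 1, sd = 0.5) {
  x <- stats::rnorm(n + w)
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))[(w + 1):(n + w)]
  mean + sd * sm / stats::sd(sm)
}

#' Generate a synthetic audio fixture with analytic ground truth
#'
#' Concatenates 1-s segments of silence, pure tones, two-tone chords, and
#' white noise at a given sample rate.  The returned truth table carries the
#' analytic zero crossing rate, RMS and spectral spread per segment where a
#' closed form exists (NA otherwise), so audio feature extractors can be
#' checked against exact values.  Tones carry a small phase offset so that no
#' sample falls exactly on a zero of the waveform.
#'
#' @param segments data.frame with columns \code{type} (\code{"silence"},
#'   \code{"tone"}, \code{"chord"}, \code{"noise"}), \code{f1}, \code{f2}
#'   (Hz) and \code{amp}; one row per second.  \code{NULL} gives a default
#'   8-segment program.
#' @param sampleRate sampling rate in Hz (at least 2000).
#' @param phase phase offset of tonal segments in radians.
#' @param seed RNG seed for noise segments.
#' @return list with elements \code{wave} (numeric samples),
#'   \code{sampleRate}, and \code{truth} (per-segment data.frame with
#'   analytic \code{rms}, \code{zcr}, \code{spread}).
#' @export
genAudio <- function(segments = NULL, sampleRate = 8000L, phase = pi / 6,
                     seed = 1L) {
  if (sampleRate < 2000) stop("sample rate must be at least 2 kHz")
  if (is.null(segments))
    segments <- data.frame(
      type = c("silence", "tone", "chord", "noise",
               "tone", "silence", "chord", "noise"),
      f1 = c(NA, 440, 400, NA, 220, NA, 600, NA),
      f2 = c(NA, NA, 800, NA, NA, NA, 1000, NA),
      amp = c(0, 0.5, 0.4, 0.3, 0.8, 0, 0.25, 0.5))
  t <- (seq_len(sampleRate) - 1) / sampleRate
  withSeed(seed, {
    segs <- lapply(seq_len(nrow(segments)), function(i) {
      s <- segments[i, ]
      switch(as.character(s$type),
        silence = numeric(sampleRate),
        tone = s$amp * sin(2 * pi * s$f1 * t + phase),
        chord = s$amp * (sin(2 * pi * s$f1 * t + phase) +
                         sin(2 * pi * s$f2 * t + phase)) / 2,
        noise = stats::rnorm(sampleRate, sd = s$amp),
        stop("unknown segment type: ", s$type))
    })
    truth <- segments
    truth$rms <- NA_real_
    truth$zcr <- NA_real_
    truth$spread <- NA_real_
    for (i in seq_len(nrow(segments))) {
      s <- segments[i, ]
      if (s$type == "silence") {
        truth$rms[i] <- 0; truth$zcr[i] <- 0
      } else if (s$type == "tone") {
        truth$rms[i] <- s$amp / sqrt(2)
        truth$zcr[i] <- 2 * s$f1
        truth$spread[i] <- 0
      } else if (s$type == "chord") {
        ## two equal-amplitude lines (A/2 each) at f1 and f2:
        ## power = 2 * (A/2)^2 / 2, spread of a symmetric two-point spectrum
        truth$rms[i] <- s$amp / 2
        truth$spread[i] <- abs(s$f2 - s$f1) / 2
      }
    }
    list(wave = unlist(segs), sampleRate = as.integer(sampleRate),
         truth = truth)
  })
}

#' Generate a synthetic frame sequence with exact object tracks
#'
#' Renders moving rectangles on a uniform background and emits the exact
#' per-frame bounding box and centroid of every object, so that track-based
#' motion scoring can be verified against analytic speeds and areas.
#' Objects whose bounding box would leave the frame have their tracks
#' truncated at the last fully visible frame and are flagged.
#'
#' @param objects data.frame with one row per object: \code{category}
#'   (\code{"body"}, \code{"head"}, \code{"hand"}, \code{"mechanical"}),
#'   \code{x}, \code{y} (top-left start, pixels), \code{w}, \code{h} (size),
#'   \code{vx}, \code{vy} (pixels/frame), \code{value} (intensity).
#' @param frameSize integer(2): height, width in pixels.
#' @param fps frames per second.
#' @param duration duration in seconds.
#' @param background background intensity in [0, 1].
#' @return list with \code{frames} (list of height x width matrices in
#'   [0, 1]), \code{tracks} (data.frame: frame, object_id, category, x0, y0,
#'   x1, y1, cx, cy, clipped), \code{fps}, \code{frameSize}.
#' @export
genVideoTracks <- function(objects = NULL, frameSize = c(64L, 64L), fps = 25L,
                           duration = 4, background = 0.5) {
  if (is.null(objects))
    objects <- data.frame(
      category = c("body", "hand", "mechanical"),
      x = c(5, 40, 20), y = c(5, 30, 40), w = c(12, 6, 8), h = c(20, 6, 8),
      vx = c(2, 0, -1), vy = c(0, 0, 1), value = c(0.9, 0.1, 0.8))
  nFrames <- as.integer(round(duration * fps))
  H <- frameSize[1]; W <- frameSize[2]
  frames <- vector("list", nFrames)
  rows <- list()
  for (f in seq_len(nFrames)) {
    img <- matrix(background, H, W)
    for (i in seq_len(nrow(objects))) {
      o <- objects[i, ]
      x0 <- o$x + (f - 1) * o$vx
      y0 <- o$y + (f - 1) * o$vy
      x1 <- x0 + o$w - 1
      y1 <- y0 + o$h - 1
      clipped <- x0 < 1 || y0 < 1 || x1 > W || y1 > H
      if (clipped) next  # truncated: no further track rows for this object
      img[y0:y1, x0:x1] <- o$value
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, object_id = i, category = as.character(o$category),
        x0 = x0, y0 = y0, x1 = x1, y1 = y1,
        cx = (x0 + x1) / 2, cy = (y0 + y1) / 2, clipped = FALSE)
    }
    frames[[f]] <- img
  }
  tracks <- do.call(rbind, rows)
  ## flag truncated objects (those with fewer rows than frames)
  cnt <- table(factor(tracks$object_id, levels = seq_len(nrow(objects))))
  tracks$clipped <- cnt[as.character(tracks$object_id)] < nFrames
  list(frames = frames, tracks = tracks, fps = as.integer(fps),
       frameSize = as.integer(frameSize))
}

#' Generate multi-subject BOLD data with planted networks
#'
#' Subject data are built as \code{timecourses \%*\% spatialMaps + noise}:
#' each planted network's deterministic time course is a row of
#' \code{config$weightMatrix} applied to the design regressors (scaled to
#' unit SD), to which shared AR(1) network noise (common to all subjects)
#' and a per-subject AR(1) perturbation are added.  Per-voxel AR(1)
#' measurement noise is superimposed.  Spatial maps are Gaussian blobs on a
#' lattice with minimum separation, giving pairwise spatial |r| below 0.3 by
#' construction.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param design a \linkS4class{DesignMatrix} with \code{config$nTimepoints}
#'   rows and one column per weight-matrix column.
#' @return list with \code{datasets} (list of \linkS4class{BoldDataset}) and
#'   \code{truth}: a list with \code{spatialMaps} (components x voxels),
#'   \code{componentTimecourses} (list per subject of components x time, the
#'   shared + subject-specific part), \code{sharedTimecourses}
#'   (components x time), \code{generatingBetas} (the scaled weight matrix)
#'   and \code{mask}.
#' @examples
#' cfg <- synthConfig(nSubjects = 2, nTimepoints = 60, nVoxels = 200,
#'                    maskShape = c(10, 5, 4), seed = 3)
#' ann <- genAnnotations(cfg)
#' des <- buildDesignMatrix(subsetTracks(ann, "auditory"), tr = cfg$tr,
#'                          nTimepoints = cfg$nTimepoints, modelId = "auditory")
#' sim <- genBold(cfg, des)
#' @export
genBold <- function(config, design) {
  X <- designMatrix(design)
  if (nrow(X) != config$nTimepoints)
    stop("design matrix time length must equal config$nTimepoints")
  W <- config$weightMatrix
  if (ncol(W) != ncol(X))
    stop("weightMatrix columns must match design regressors")
  zeroRows <- rowSums(W != 0) == 0
  if (any(zeroRows))
    warning("weightMatrix has all-zero rows; those components are pure noise")
  Tt <- config$nTimepoints
  k <- config$nComponents
  withSeed(config$seed, {
    maps <- makeSpatialMaps(config)
    ## deterministic part, unit-SD per component (zero rows stay zero)
    base <- X %*% t(W)                               # T x k
    sc <- apply(base, 2, stats::sd)
    sc[sc == 0] <- 1
    base <- sweep(base, 2, sc, "/")
    betas <- W / sc                                  # generating betas after scaling
    shared <- base + arNoise(Tt, config$sharedNoiseSd, config$ar1Phi, k)
    datasets <- vector("list", config$nSubjects)
    subjTc <- vector("list", config$nSubjects)
    maskArr <- array(FALSE, config$maskShape)
    maskArr[seq_len(config$nVoxels)] <- TRUE
    for (s in seq_len(config$nSubjects)) {
      tc <- shared + arNoise(Tt, config$subjectNoiseSd, config$ar1Phi, k)
      y <- tc %*% maps +
        arNoise(Tt, config$voxelNoiseSd, config$ar1Phi, config$nVoxels)
      subjTc[[s]] <- t(tc)                           # components x time
      datasets[[s]] <- new("BoldDataset", data = y, mask = maskArr,
                           tr = config$tr,
                           subjectId = sprintf("sub-%02d", s))
    }
    list(datasets = datasets,
         truth = list(spatialMaps = maps,
                      componentTimecourses = subjTc,
                      sharedTimecourses = t(shared),
                      generatingBetas = betas,
                      mask = maskArr))
  })
}

## Gaussian blobs with centers spread on a lattice inside the mask box.
## Minimum separation keeps pairwise spatial correlation low.
makeSpatialMaps <- function(config) {
  k <- config$nComponents
  dims <- config$maskShape
  ## voxel coordinates of the first nVoxels linear indices
  idx <- seq_len(config$nVoxels)
  coords <- arrayInd(idx, dims)
  ## place centers on a coarse lattice of candidate positions
  cand <- as.matrix(expand.grid(
    x = seq(0.15, 0.85, length.out = max(2, ceiling(sqrt(k)))) * dims[1],
    y = seq(0.2, 0.8, length.out = max(2, ceiling(k / ceiling(sqrt(k))))) * dims[2],
    z = dims[3] / 2))
  centers <- cand[seq_len(k), , drop = FALSE]
  sigma <- max(1.5, min(dims) / 6)
  maps <- matrix(0, k, config$nVoxels)
  for (j in seq_len(k)) {
    d2 <- (coords[, 1] - centers[j, 1])^2 + (coords[, 2] - centers[j, 2])^2 +
      (coords[, 3] - centers[j, 3])^2
    m <- exp(-d2 / (2 * sigma^2))
    m[m < 0.01] <- 0                      # compact support: blobs do not smear
    maps[j, ] <- m
  }
  maps
}
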