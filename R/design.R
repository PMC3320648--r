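## HRF regressor construction and temporal preprocessing of voxel series.

#' Canonical double-gamma HRF specification
#'
#' Difference of two gamma densities: a response peaking at
#' \code{peakDelay} seconds minus \code{undershootRatio} times an undershoot
#' peaking at \code{undershootDelay} seconds.  Gammas are parameterised by
#' their mode, so the kernel's argmax falls at \code{peakDelay} exactly (the
#' canonical six-second lag).  The kernel is normalised to peak amplitude 1.
#'
#' @param peakDelay time-to-peak of the response, seconds.
#' @param undershootDelay time-to-peak of the undershoot, seconds.
#' @param peakDispersion,undershootDispersion gamma dispersions, seconds.
#' @param undershootRatio undershoot amplitude relative to the peak.
#' @param kernelLength kernel support, seconds.
#' @param dt sampling interval of the kernel, seconds.
#' @return list of class \code{"HrfSpec"}.
#' @export
hrfSpec <- function(peakDelay = 6, undershootDelay = 16, peakDispersion = 1,
                    undershootDispersion = 1, undershootRatio = 1 / 6,
                    kernelLength = 32, dt = 1) {
  vals <- c(peakDelay, undershootDelay, peakDispersion,
            undershootDispersion, kernelLength, dt)
  if (any(vals <= 0) || undershootRatio < 0)
    stop("all HRF parameters must be positive (undershootRatio >= 0)")
  if (dt > kernelLength) stop("dt must not exceed kernelLength")
  structure(list(peakDelay = peakDelay, undershootDelay = undershootDelay,
                 peakDispersion = peakDispersion,
                 undershootDispersion = undershootDispersion,
                 undershootRatio = undershootRatio,
                 kernelLength = kernelLength, dt = dt),
            class = "HrfSpec")
}

#' Sampled double-gamma HRF kernel
#'
#' @param spec an \code{\link{hrfSpec}}.
#' @return list with \code{time} (seconds, from 0) and \code{values}
#'   (kernel samples, peak-normalised to 1).
#' @examples
#' k <- hrfKernel()
#' k$time[which.max(k$values)]  # 6
#' @export
hrfKernel <- function(spec = hrfSpec()) {
  t <- seq(0, spec$kernelLength, by = spec$dt)
  ## gamma density with mode m, dispersion d: shape = 1 + m/d, rate = 1/d
  g <- function(m, d) stats::dgamma(t, shape = 1 + m / d, rate = 1 / d)
  h <- g(spec$peakDelay, spec$peakDispersion) -
    spec$undershootRatio * g(spec$undershootDelay, spec$undershootDispersion)
  list(time = t, values = h / max(h))
}

## Causal discrete convolution truncated to the input length.
causalConvolve <- function(x, kernel) {
  n <- length(x)
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_len(n)]
}

#' HRF-convolved, TR-sampled regressor from a 1-Hz track
#'
#' Convolves a 1-Hz annotation track with the canonical HRF at 1-s
#' resolution, truncates to the stimulus length, and resamples on the TR
#' grid (t = 0, TR, 2 TR, ...).  Resampling is by decimation at the grid
#' points by default (the boxcar-regressor convention);
#' \code{resample = "linear"} interpolates instead, which only differs for
#' non-integer TR.
#'
#' @param track an \linkS4class{AnnotationTrack} (rate 1 Hz) or numeric
#'   vector of 1-Hz samples.
#' @param spec an \code{\link{hrfSpec}}.
#' @param tr repetition time, seconds.
#' @param nTimepoints required regressor length in TR units.
#' @param resample \code{"decimate"} or \code{"linear"}.
#' @return numeric regressor of length \code{nTimepoints}.
#' @export
makeRegressor <- function(track, spec = hrfSpec(), tr = 2, nTimepoints,
                          resample = c("decimate", "linear")) {
  resample <- match.arg(resample)
  x <- if (is(track, "AnnotationTrack")) track@values else as.numeric(track)
  if (length(x) < nTimepoints * tr)
    stop("track too short: need at least nTimepoints * tr seconds")
  conv <- causalConvolve(x, hrfKernel(spec)$values)
  tGrid <- (seq_len(nTimepoints) - 1) * tr
  if (resample == "decimate" && all(tGrid == round(tGrid))) {
    conv[tGrid + 1]
  } else {
    stats::approx(x = seq_along(conv) - 1, y = conv, xout = tGrid)$y
  }
}

#' Build a design matrix from an annotation set
#'
#' Convolves every track with the HRF and assembles the TR-sampled
#' regressors into a \linkS4class{DesignMatrix}.
#'
#' @param set an \linkS4class{AnnotationSet}.
#' @param spec an \code{\link{hrfSpec}}.
#' @param tr repetition time, seconds.
#' @param nTimepoints regressor length in TR units.
#' @param modelId model label (\code{"auditory"}, \code{"visual"}, or
#'   custom).
#' @param resample passed to \code{\link{makeRegressor}}.
#' @return a \linkS4class{DesignMatrix}.
#' @export
buildDesignMatrix <- function(set, spec = hrfSpec(), tr = 2, nTimepoints,
                              modelId = "custom",
                              resample = c("decimate", "linear")) {
  resample <- match.arg(resample)
  m <- vapply(set@tracks, function(t)
    makeRegressor(t, spec, tr, nTimepoints, resample), numeric(nTimepoints))
  m <- matrix(m, nrow = nTimepoints)
  new("DesignMatrix", modelId = modelId, features = unname(trackNames(set)),
      matrix = m, tr = tr)
}

#' Gaussian-weighted running-line high-pass filter
#'
#' For each time point a straight line (intercept + slope) is fitted to the
#' whole series by least squares with Gaussian weights of SD \code{sigma}
#' seconds centred on that point; the fitted value is subtracted and the
#' global mean added back.  This removes drifts slower than roughly
#' \code{1/(2 sigma)} Hz while preserving the series mean.
#'
#' @param series numeric vector, or a time x voxels matrix (each column
#'   filtered), or a \linkS4class{BoldDataset}.
#' @param sigma Gaussian SD in seconds (default 100).
#' @param tr sampling interval in seconds (taken from the dataset when a
#'   \linkS4class{BoldDataset} is given).
#' @return object of the same shape/class, detrended.
#' @export
highpassDetrend <- function(series, sigma = 100, tr = 2) {
  if (sigma <= 0) stop("sigma must be positive")
  if (is(series, "BoldDataset")) {
    out <- series
    out@data <- highpassDetrend(series@data, sigma, series@tr)
    return(out)
  }
  m <- if (is.matrix(series)) series else matrix(series, ncol = 1)
  if (nrow(m) < 5) stop("series must have length at least 5")
  S <- runningLineSmoother(nrow(m), sigma / tr)
  out <- m - S %*% m + matrix(colMeans(m), nrow(m), ncol(m), byrow = TRUE)
  if (is.matrix(series)) out else as.numeric(out)
}

## T x T linear smoother: row t gives the Gaussian-weighted least-squares
## line prediction at t.  sigmaTr is the Gaussian SD in sample units.
runningLineSmoother <- function(n, sigmaTr) {
  x <- seq_len(n)
  S <- matrix(0, n, n)
  for (t in x) {
    w <- exp(-((x - t)^2) / (2 * sigmaTr^2))
    xc <- x - t
    sw <- sum(w); swx <- sum(w * xc); swx2 <- sum(w * xc^2)
    det <- sw * swx2 - swx^2
    ## prediction at xc = 0: [swx2 * sum(w y) - swx * sum(w x y)] / det
    S[t, ] <- (swx2 * w - swx * (w * xc)) / det
  }
  S
}

#' Standardize voxel time courses and average across subjects
#'
#' Each subject's voxel time courses are standardised to zero mean and unit
#' variance; the voxel-wise mean across subjects is then taken.  Voxels with
#' zero variance in any subject are set to 0 for that subject and flagged in
#' the result.
#'
#' @param datasets list of \linkS4class{BoldDataset} with identical masks and
#'   time lengths.
#' @return a \linkS4class{BoldDataset} holding the across-subject mean of the
#'   standardised series (\code{subjectId = "group-mean"}); flagged voxel
#'   indices are in \code{@flaggedVoxels}.
#' @export
standardizeAndAverage <- function(datasets) {
  dims <- vapply(datasets, function(d) dim(d@data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("datasets must share time length and mask")
  flagged <- integer(0)
  acc <- matrix(0, dims[1, 1], dims[2, 1])
  for (d in datasets) {
    z <- standardizeVoxels(d@data)
    flagged <- union(flagged, attr(z, "flagged"))
    acc <- acc + z
  }
  new("BoldDataset", data = acc / length(datasets),
      mask = datasets[[1]]@mask, tr = datasets[[1]]@tr,
      subjectId = "group-mean", flaggedVoxels = sort(as.integer(flagged)))
}

## z-score columns; zero-variance columns become 0 and are flagged.
standardizeVoxels <- function(m) {
  mu <- colMeans(m)
  s <- sqrt(colSums(sweep(m, 2, mu)^2) / (nrow(m) - 1))
  bad <- which(s == 0)
  s[bad] <- 1
  z <- sweep(sweep(m, 2, mu), 2, s, "/")
  z[, bad] <- 0
  attr(z, "flagged") <- bad
  z
}

#' Standardize the voxel time courses of each dataset
#'
#' Convenience wrapper applying per-voxel z-scoring to every subject without
#' averaging (the form expected by the group-ICA concatenation step).
#'
#' @param datasets list of \linkS4class{BoldDataset}.
#' @return list of standardised \linkS4class{BoldDataset} objects.
#' @export
standardizeDatasets <- function(datasets) {
  lapply(datasets, function(d) {
    z <- standardizeVoxels(d@data)
    flagged <- as.integer(attr(z, "flagged"))
    attr(z, "flagged") <- NULL
    new("BoldDataset", data = z, mask = d@mask, tr = d@tr,
        subjectId = d@subjectId, flaggedVoxels = flagged)
  })
}
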