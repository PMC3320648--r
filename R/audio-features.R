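## Automatic audio annotation: four acoustic descriptors computed in
## non-overlapping 1-s windows from a mono waveform.

#' Extract acoustic annotation tracks from a mono waveform
#'
#' Computes, per non-overlapping 1-s window:
#' \itemize{
#'   \item \code{zcr}: zero crossing rate, the number of sign changes per
#'     second (a simple noisiness measure);
#'   \item \code{rms}: root-mean-square amplitude (loudness proxy);
#'   \item \code{spectral_spread}: standard deviation in Hz of the
#'     magnitude-spectrum distribution (spectrum normalised to a probability
#'     mass over the non-negative frequency bins);
#'   \item \code{entropy}: Shannon entropy of the normalised magnitude
#'     spectrum divided by \code{log(number of bins)}, so a flat spectrum
#'     maps to 1.
#' }
#' Entropy is undefined in silent windows; those entries are filled by
#' \code{\link{substituteSilence}} with the entropy of the most silent
#' non-silent window.
#'
#' The spectrum is the magnitude of the real FFT over the full 1-s window
#' with no tapering by default; \code{window = "hann"} applies a Hann taper.
#'
#' @param wave numeric vector of mono samples (use \code{rowMeans} to downmix
#'   stereo before calling; a matrix input raises an error saying so).
#' @param sampleRate sampling rate in Hz.
#' @param window \code{"rect"} (default) or \code{"hann"}.
#' @param substitute apply the silence substitution rule to the entropy
#'   track (default TRUE).
#' @return an \linkS4class{AnnotationSet} with tracks \code{zcr},
#'   \code{spectral_spread}, \code{entropy}, \code{rms}, each with
#'   \code{floor(duration)} samples.
#' @examples
#' au <- genAudio()
#' feats <- extractAudioFeatures(au$wave, au$sampleRate)
#' @export
extractAudioFeatures <- function(wave, sampleRate,
                                 window = c("rect", "hann"),
                                 substitute = TRUE) {
  window <- match.arg(window)
  if (is.matrix(wave) && ncol(wave) > 1)
    stop("stereo input: downmix to mono first (e.g. rowMeans(wave))")
  wave <- as.numeric(wave)
  if (length(wave) == 0) stop("zero-length waveform")
  n <- sampleRate
  nWin <- floor(length(wave) / n)
  if (nWin < 1) stop("waveform must be at least 1 s long")
  taper <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)) else rep(1, n)
  zcr <- rms <- spread <- entropy <- numeric(nWin)
  for (w in seq_len(nWin)) {
    x <- wave[((w - 1) * n + 1):(w * n)]
    zcr[w] <- sum(x[-1] * x[-n] < 0)
    rms[w] <- sqrt(mean(x^2))
    sp <- spectrumStats(x * taper, sampleRate)
    spread[w] <- sp$spread
    entropy[w] <- sp$entropy
  }
  ent <- annotationTrack("entropy",
                         ifelse(is.na(entropy), 0, entropy),
                         "auditory", "continuous")
  out <- annotationSet(list(
    annotationTrack("zcr", zcr, "auditory", "continuous"),
    annotationTrack("spectral_spread", ifelse(is.na(spread), 0, spread),
                    "auditory", "continuous"),
    ent,
    annotationTrack("rms", rms, "auditory", "continuous")))
  if (substitute && any(is.na(entropy))) {
    fixed <- substituteSilence(entropy, rms)
    out@tracks$entropy <- annotationTrack("entropy", fixed, "auditory",
                                          "continuous")
  }
  out
}

## Magnitude-spectrum moments over the non-negative frequency bins.
## Returns NA spread/entropy for an all-zero window.
spectrumStats <- function(x, sampleRate) {
  n <- length(x)
  half <- floor(n / 2) + 1L
  mag <- Mod(stats::fft(x))[seq_len(half)]
  tot <- sum(mag)
  if (tot == 0) return(list(spread = NA_real_, entropy = NA_real_))
  p <- mag / tot
  f <- (seq_len(half) - 1) * sampleRate / n
  mu <- sum(p * f)
  spread <- sqrt(sum(p * (f - mu)^2))
  nz <- p[p > 0]
  list(spread = spread, entropy = -sum(nz * log(nz)) / log(length(p)))
}

#' Fill silent-window entropy values
#'
#' Windows whose RMS falls below a silence floor receive the entropy of the
#' window with the smallest RMS above the floor (the "most silent" part of
#' the sound that still carries signal).  Ties are broken by the earliest
#' window.
#'
#' @param entropy numeric entropy track (NA in silent windows is accepted).
#' @param rms aligned RMS track.
#' @param floorFrac silence floor as a fraction of the maximum RMS.
#' @return the entropy track with silent windows substituted.
#' @export
substituteSilence <- function(entropy, rms, floorFrac = 1e-6) {
  if (length(entropy) != length(rms)) stop("tracks must be aligned")
  floorVal <- floorFrac * max(rms)
  silent <- rms <= floorVal | is.na(entropy)
  if (all(silent)) stop("all-silent track: entropy undefined everywhere")
  if (!any(silent)) return(entropy)
  candidates <- which(!silent)
  donor <- candidates[which.min(rms[candidates])]  # which.min: earliest tie
  entropy[silent] <- entropy[donor]
  entropy
}

#' Pearson correlation between two annotation tracks
#'
#' Used to compare automatic against manual annotations of the same feature,
#' optionally after HRF convolution of both tracks (the comparison can be
#' made on either scale).
#'
#' @param a,b \linkS4class{AnnotationTrack} objects or numeric vectors of
#'   equal length (at least 3).
#' @param hrf optional \code{\link{hrfSpec}}; when supplied both tracks are
#'   HRF-convolved at 1 Hz before correlating.
#' @return Pearson r.
#' @export
compareAnnotationPair <- function(a, b, hrf = NULL) {
  va <- if (is(a, "AnnotationTrack")) a@values else as.numeric(a)
  vb <- if (is(b, "AnnotationTrack")) b@values else as.numeric(b)
  if (length(va) != length(vb) || length(va) < 3)
    stop("tracks must have equal length of at least 3")
  if (!is.null(hrf)) {
    k <- hrfKernel(hrf)
    va <- causalConvolve(va, k$values)
    vb <- causalConvolve(vb, k$values)
  }
  safeCor(va, vb)
}
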