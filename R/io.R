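## File formats: NIfTI volumes, TSV annotation/track/design tables, and a
## minimal RIFF/WAVE codec for the audio fixtures.

#' Load a masked BOLD dataset from NIfTI
#'
#' Reads a 4-D BOLD volume and a 3-D brain mask, discards the leading
#' volumes (the blank-screen period at scan start), and returns the masked
#' time x voxels matrix.  Voxel order is the linear order of the mask
#' (first array index fastest).
#'
#' @param path 4-D NIfTI file.
#' @param maskPath 3-D mask NIfTI on the same grid (non-zero = in mask).
#' @param discardVolumes number of initial volumes to drop (default 10).
#' @param tr repetition time in seconds; defaults to the NIfTI header
#'   pixdim.
#' @param subjectId subject label.
#' @return a \linkS4class{BoldDataset}.
#' @export
loadBold <- function(path, maskPath, discardVolumes = 10L, tr = NULL,
                     subjectId = basename(path)) {
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(maskPath)
  if (length(dim(img)) != 4) stop("expected a 4-D BOLD image")
  if (!all(dim(img)[1:3] == dim(msk)[1:3]))
    stop("grid mismatch between BOLD image and mask")
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2
  }
  maskArr <- array(as.array(msk) != 0, dim(msk)[1:3])
  nT <- dim(img)[4]
  if (discardVolumes >= nT) stop("cannot discard all volumes")
  keep <- (discardVolumes + 1):nT
  flat <- matrix(as.numeric(img), prod(dim(img)[1:3]), nT)
  data <- t(flat[which(maskArr), keep, drop = FALSE])
  if (!all(is.finite(data))) stop("non-finite values inside the mask")
  new("BoldDataset", data = data, mask = maskArr, tr = tr,
      subjectId = subjectId)
}

#' Write a BOLD dataset (and its mask) as NIfTI
#'
#' @param dataset a \linkS4class{BoldDataset}.
#' @param path output 4-D NIfTI path.
#' @param maskPath optional output path for the mask volume.
#' @return \code{path}, invisibly.
#' @export
writeBold <- function(dataset, path, maskPath = NULL) {
  dims <- dim(dataset@mask)
  nT <- nTimepoints(dataset)
  arr <- array(0, c(dims, nT))
  idx <- which(dataset@mask)
  flat <- matrix(0, prod(dims), nT)
  flat[idx, ] <- t(dataset@data)
  arr <- array(flat, c(dims, nT))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, dataset@tr)
  RNifti::writeNifti(img, path)
  if (!is.null(maskPath))
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(dataset@mask), dims)),
                       maskPath)
  invisible(path)
}

#' Write annotation tracks as TSV
#'
#' Long format with columns \code{time_s}, \code{name}, \code{value} plus
#' \code{modality} and \code{kind} so the set round-trips exactly.
#'
#' @param set an \linkS4class{AnnotationSet}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(set, path) {
  rows <- do.call(rbind, lapply(set@tracks, function(t)
    data.frame(time_s = seq_along(t@values) - 1, name = t@name,
               value = t@values, modality = t@modality, kind = t@kind)))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Load annotation tracks from TSV
#'
#' Expects the long format written by \code{\link{writeAnnotations}}
#' (\code{modality}/\code{kind} columns optional; kinds are inferred from
#' the values when absent).  Validates the 1-Hz grid (no gaps) and the
#' value ranges of boxcar and ordinal tracks, naming the offending row on
#' failure.
#'
#' @param path TSV path with columns \code{time_s}, \code{name},
#'   \code{value}.
#' @return an \linkS4class{AnnotationSet}.
#' @export
loadAnnotations <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("time_s", "name", "value")
  if (!all(need %in% names(d)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  tracks <- lapply(split(seq_len(nrow(d)), d$name), function(rows) {
    sub <- d[rows, ]
    sub <- sub[order(sub$time_s), ]
    if (!all(diff(sub$time_s) == 1))
      stop("gap in the 1-Hz grid for track '", sub$name[1], "' near row ",
           rows[which(diff(sub$time_s) != 1)[1] + 1])
    kind <- if ("kind" %in% names(sub)) sub$kind[1] else {
      if (all(sub$value %in% c(0, 1))) "boxcar"
      else if (all(sub$value %in% 0:4)) "ordinal"
      else "continuous"
    }
    modality <- if ("modality" %in% names(sub)) sub$modality[1] else "auditory"
    if (kind == "ordinal" && !all(sub$value %in% 0:4))
      stop("ordinal value out of range 0..4 for track '", sub$name[1],
           "' at row ", rows[which(!sub$value %in% 0:4)[1]])
    if (kind == "boxcar" && !all(sub$value %in% c(0, 1)))
      stop("boxcar value out of range {0,1} for track '", sub$name[1],
           "' at row ", rows[which(!sub$value %in% c(0, 1))[1]])
    annotationTrack(sub$name[1], sub$value, modality, kind)
  })
  ## preserve file order of first appearance
  ord <- match(unique(d$name), names(tracks))
  annotationSet(tracks[ord])
}

#' Write object tracks as TSV
#'
#' @param tracks track data.frame (\code{frame}, \code{object_id},
#'   \code{category}, \code{x0}, \code{y0}, \code{x1}, \code{y1}, ...).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTracks <- function(tracks, path) {
  utils::write.table(tracks, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Load object tracks from TSV
#' @param path TSV path written by \code{\link{writeTracks}}.
#' @return track data.frame.
#' @export
loadTracks <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a design matrix as TSV
#' @param design a \linkS4class{DesignMatrix}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeDesign <- function(design, path) {
  m <- designMatrix(design)
  utils::write.table(as.data.frame(m), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Load a design matrix from TSV
#' @param path TSV with a header row of feature names.
#' @param tr repetition time in seconds.
#' @param modelId model label.
#' @return a \linkS4class{DesignMatrix}.
#' @export
loadDesign <- function(path, tr = 2, modelId = "custom") {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  new("DesignMatrix", modelId = modelId, features = colnames(m),
      matrix = unname(m), tr = tr)
}

#' Write a component set to NIfTI + TSV
#'
#' Spatial maps are written as a 4-D NIfTI (component along the fourth
#' axis) using the stored mask geometry; group time courses, stability
#' indices and run counts as TSV.
#'
#' @param components a \linkS4class{ComponentSet} with \code{maskDim} set.
#' @param mask logical array giving the voxel linearisation.
#' @param mapsPath output NIfTI path for the maps.
#' @param tablePath output TSV path for time courses + stability.
#' @return invisibly, the paths.
#' @export
writeComponentSet <- function(components, mask, mapsPath, tablePath) {
  dims <- dim(mask)
  k <- nComponents(components)
  flat <- matrix(0, prod(dims), k)
  flat[which(mask), ] <- t(components@spatialMaps)
  RNifti::writeNifti(RNifti::asNifti(array(flat, c(dims, k))), mapsPath)
  tc <- components@groupTimecourses
  tab <- data.frame(component = seq_len(k),
                    stability = components@stabilityIndex,
                    runCount = components@runCount)
  utils::write.table(tab, tablePath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (nrow(tc)) {
    tcPath <- sub("\\.tsv$", "_timecourses.tsv", tablePath)
    utils::write.table(as.data.frame(t(tc)), tcPath, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(c(mapsPath, tablePath))
}

## ---------------------------------------------------------------- WAV I/O
## Minimal RIFF/WAVE support (mono/stereo, PCM16 or IEEE float32), enough
## for the synthetic audio fixtures to round-trip.

#' Write a waveform as WAV
#'
#' @param wave numeric vector (mono) or matrix (samples x channels) with
#'   values in [-1, 1].
#' @param path output path.
#' @param sampleRate sampling rate in Hz.
#' @param format \code{"pcm16"} or \code{"float32"}.
#' @return \code{path}, invisibly.
#' @export
writeWav <- function(wave, path, sampleRate = 8000L,
                     format = c("pcm16", "float32")) {
  format <- match.arg(format)
  m <- if (is.matrix(wave)) wave else matrix(wave, ncol = 1)
  nch <- ncol(m); n <- nrow(m)
  bytesPer <- if (format == "pcm16") 2L else 4L
  fmtCode <- if (format == "pcm16") 1L else 3L
  dataSize <- n * nch * bytesPer
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmtCode, con, size = 2, endian = "little")
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * nch * bytesPer), con, size = 4,
           endian = "little")
  writeBin(as.integer(nch * bytesPer), con, size = 2, endian = "little")
  writeBin(8L * bytesPer, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  inter <- as.numeric(t(m))            # interleave channels
  if (format == "pcm16") {
    writeBin(as.integer(round(pmax(pmin(inter, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(inter, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' @param path WAV path (PCM16 or IEEE float32).
#' @return list with \code{wave} (numeric vector for mono, samples x
#'   channels matrix otherwise, scaled to [-1, 1]) and \code{sampleRate}.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmtCode <- nch <- sampleRate <- bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmtCode <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      sampleRate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (id == "data") {
      n <- if (bits == 16) sz / 2 else sz / 4
      raw <- if (fmtCode == 1 && bits == 16) {
        readBin(con, integer(), n = n, size = 2, signed = TRUE,
                endian = "little") / 32767
      } else if (fmtCode == 3 && bits == 32) {
        readBin(con, numeric(), n = n, size = 4, endian = "little")
      } else stop("unsupported WAV encoding (PCM16 and float32 only)")
      m <- matrix(raw, ncol = nch, byrow = TRUE)
      return(list(wave = if (nch == 1) as.numeric(m) else m,
                  sampleRate = sampleRate))
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
}
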