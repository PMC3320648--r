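test_that("acoustic descriptors match analytic values on the audio fixture", {
  au <- genAudio()
  f <- extractAudioFeatures(au$wave, au$sampleRate)
  zcr <- trackValues(getTrack(f, "zcr"))
  rms <- trackValues(getTrack(f, "rms"))
  spread <- trackValues(getTrack(f, "spectral_spread"))
  tr <- au$truth
  tone <- which(tr$type == "tone")
  expect_equal(zcr[tone], tr$zcr[tone])                      # 2f, exact
  expect_equal(rms[tone], tr$rms[tone], tolerance = 1e-3)
  chord <- which(tr$type == "chord")
  expect_equal(spread[chord], tr$spread[chord], tolerance = 0.01)
  sil <- which(tr$type == "silence")
  expect_equal(rms[sil], rep(0, length(sil)))
  expect_equal(zcr[sil], rep(0, length(sil)))
  ## exactly floor(duration) windows
  expect_length(zcr, floor(length(au$wave) / au$sampleRate))
})

test_that("entropy is normalised to [0,1] with flat spectrum at 1", {
  ## impulse has a flat magnitude spectrum
  x <- c(1, rep(0, 1999))
  expect_equal(naturalfmri:::spectrumStats(x, 2000)$entropy, 1)
  au <- genAudio()
  ent <- trackValues(getTrack(extractAudioFeatures(au$wave, au$sampleRate),
                              "entropy"))
  expect_true(all(ent >= 0 & ent <= 1))
})

test_that("white-noise spread matches a direct-summation oracle", {
  set.seed(41)
  x <- rnorm(4000)
  got <- naturalfmri:::spectrumStats(x, 4000)$spread
  ## brute-force: probability mass over FFT magnitudes, direct sums
  mag <- Mod(fft(x))[1:2001]
  p <- mag / sum(mag)
  f <- (0:2000) * 1
  mu <- 0
  for (i in seq_along(f)) mu <- mu + p[i] * f[i]
  v <- 0
  for (i in seq_along(f)) v <- v + p[i] * (f[i] - mu)^2
  expect_equal(got, sqrt(v), tolerance = 0.05)
})

test_that("silence substitution follows the most-silent-window rule", {
  ent <- c(NA, NA, NA, 0.5, 0.8, 0.2)
  rms <- c(0, 0, 0, 0.1, 0.9, 0.05)
  out <- substituteSilence(ent, rms)
  expect_equal(out[1:3], rep(0.2, 3))   # argmin nonzero rms is window 6
  ## no silent windows: identity
  expect_identical(substituteSilence(c(0.4, 0.6), c(1, 2)), c(0.4, 0.6))
  ## tie on minimal rms: earliest window wins
  out2 <- substituteSilence(c(NA, 0.7, 0.3), c(0, 0.2, 0.2))
  expect_equal(out2[1], 0.7)
  expect_error(substituteSilence(c(NA, NA), c(0, 0)), "all-silent")
  expect_error(substituteSilence(c(NA), c(0, 1)), "aligned")
})

test_that("stereo and empty audio inputs are rejected with guidance", {
  expect_error(extractAudioFeatures(matrix(0, 100, 2), 100), "downmix")
  expect_error(extractAudioFeatures(numeric(0), 100), "zero-length")
})

test_that("edge density removes DC, tracks the FFT oracle, scales linearly", {
  u <- matrix(0.42, 24, 24)
  expect_lt(trackValues(edgeDensity(list(u), fps = 1)), 1e-10)
  cb <- matrix(rep(c(0, 1), 24 * 24 / 2), 24, 24)
  got <- trackValues(edgeDensity(list(cb), fps = 1))
  expect_equal(got, fftHighpassOracle(cb), tolerance = 0.01)
  ## invariance to additive shift; linearity in contrast
  expect_equal(trackValues(edgeDensity(list(cb + 0.3), fps = 1)), got,
               tolerance = 1e-10)
  expect_equal(trackValues(edgeDensity(list(cb * 0.5), fps = 1)), got / 2,
               tolerance = 1e-10)
  expect_error(edgeDensity(list(u, matrix(0, 10, 10)), fps = 1), "same size")
  ## separable mask option also kills a uniform frame
  expect_lt(trackValues(edgeDensity(list(u), fps = 1,
            spec = edgeFilterSpec(maskGeometry = "separable"))), 1e-10)
})

test_that("manual motion scoring enforces the zero-when-still rule", {
  expect_equal(scoreMotionManual(2, 0), 0)
  expect_equal(scoreMotionManual(1, 2), 3)
  expect_equal(scoreMotionManual(0, 1), 1)
  expect_equal(scoreMotionManual(c(2, 1), c(0, 1)), c(0, 2))
  expect_error(scoreMotionManual(3, 1), "0..2")
})

test_that("track-based motion scores follow the threshold table", {
  mkTrack <- function(cat, id, areaFrac, speedTotal, fps = 25,
                      frameArea = 100 * 100) {
    side <- sqrt(areaFrac * frameArea)
    step <- speedTotal / fps
    data.frame(frame = 1:(2 * fps), object_id = id, category = cat,
               x0 = 1 + step * (0:(2 * fps - 1)), y0 = 1,
               x1 = side + step * (0:(2 * fps - 1)), y1 = side,
               cx = (1 + side) / 2 + step * (0:(2 * fps - 1)),
               cy = (1 + side) / 2)
  }
  ## area 0.05 (score 0), speed 30 (score 1) -> 1
  t1 <- mkTrack("hand", 1, 0.05, 30)
  s1 <- scoreMotionTracks(t1, 100 * 100, 25)
  expect_equal(trackValues(getTrack(s1, "hand"))[2], 1)
  ## area 0.2 (2), speed 60 (2) -> 4
  t2 <- mkTrack("body", 1, 0.2, 60)
  s2 <- scoreMotionTracks(t2, 100 * 100, 25)
  expect_equal(trackValues(getTrack(s2, "body"))[2], 4)
  ## per-measure maxima taken independently across objects: (2,0) and (0,2) -> 4
  t3 <- rbind(mkTrack("mechanical", 1, 0.2, 0),
              mkTrack("mechanical", 2, 0.01, 60))
  s3 <- scoreMotionTracks(t3, 100 * 100, 25)
  expect_equal(trackValues(getTrack(s3, "mechanical"))[2], 4)
  ## parity rule: still objects score 0 regardless of size
  t4 <- mkTrack("head", 1, 0.5, 0)
  s4 <- scoreMotionTracks(t4, 100 * 100, 25)
  expect_equal(trackValues(getTrack(s4, "head"))[2], 0)
  s4b <- scoreMotionTracks(t4, 100 * 100, 25, zeroWhenStill = FALSE)
  expect_equal(trackValues(getTrack(s4b, "head"))[2], 2)
  expect_error(scoreMotionTracks(transform(t4, category = "alien"),
                                 1e4, 25), "unknown category")
})

test_that("track scores agree with a brute-force per-object enumerator and stay in range", {
  set.seed(43)
  fps <- 10; frameArea <- 64 * 64
  spec <- motionScoringSpec()
  for (rep in 1:20) {
    nObj <- sample(1:3, 1)
    rows <- do.call(rbind, lapply(seq_len(nObj), function(id) {
      side <- runif(1, 2, 40)
      step <- runif(1, 0, 8)
      nfr <- 3 * fps
      data.frame(frame = 1:nfr, object_id = id,
                 category = sample(c("body", "hand"), 1),
                 x0 = 1 + step * (0:(nfr - 1)), y0 = 1,
                 x1 = side + step * (0:(nfr - 1)), y1 = side,
                 cx = (1 + side) / 2 + step * (0:(nfr - 1)),
                 cy = (1 + side) / 2)
    }))
    got <- scoreMotionTracks(rows, frameArea, fps)
    ## brute force, independent loop structure
    for (cat in trackNames(got)) {
      vals <- trackValues(getTrack(got, cat))
      expect_true(all(vals %in% 0:4))
      for (w in seq_along(vals)) {
        fr <- ((w - 1) * fps + 1):(w * fps)
        sub <- rows[rows$category == cat & rows$frame %in% fr, ]
        aSc <- sSc <- 0
        for (id in unique(sub$object_id)) {
          ob <- sub[sub$object_id == id, ]
          af <- mean((ob$x1 - ob$x0 + 1) * (ob$y1 - ob$y0 + 1)) / frameArea
          full <- rows[rows$object_id == id & rows$category == cat, ]
          full$sp <- c(0, sqrt(diff(full$cx)^2 + diff(full$cy)^2))
          sp <- sum(full$sp[full$frame %in% fr])
          aSc <- max(aSc, if (af < 1/10) 0 else if (af <= 1/6) 1 else 2)
          sSc <- max(sSc, if (sp < 15) 0 else if (sp <= 50) 1 else 2)
        }
        want <- if (sSc == 0) 0 else aSc + sSc
        expect_equal(vals[w], want)
      }
    }
  }
})

test_that("annotation pair comparison matches the textbook formula", {
  a <- annotationTrack("m1", c(0, 1, 1, 0, 1), "visual", "boxcar")
  expect_equal(compareAnnotationPair(a, a), 1)
  neg <- annotationTrack("m2", 1 - trackValues(a), "visual", "boxcar")
  expect_equal(compareAnnotationPair(a, neg), -1)
  set.seed(47)
  x <- rnorm(1000); y <- rnorm(1000)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(compareAnnotationPair(x, y), direct, tolerance = 1e-12)
  ## convolved comparison is available and differs from the raw one
  h <- compareAnnotationPair(x, y, hrf = hrfSpec())
  expect_false(isTRUE(all.equal(h, direct)))
  expect_error(compareAnnotationPair(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(compareAnnotationPair(1:2, 1:2), "at least 3")
})
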