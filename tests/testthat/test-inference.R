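test_that("annotation GLM matches the normal-equations oracle", {
  set.seed(81)
  for (i in 1:20) {
    X <- matrix(rnorm(60 * 5), 60)
    colnames(X) <- paste0("f", 1:5)
    y <- rnorm(60)
    f <- fitAnnotationModel(X, y)
    want <- olsOracle(X, y)
    expect_equal(unname(c(f@intercept, f@betas)), want, tolerance = 1e-10)
    expect_equal(f@rSquared, f@r^2, tolerance = 1e-14)
    expect_equal(max(abs(f@normalizedWeights)), 1)
  }
})

test_that("normalized weights give the main explanatory variable weight 1", {
  set.seed(83)
  x1 <- rnorm(100)
  x2 <- residuals(lm(rnorm(100) ~ x1))       # orthogonal to x1
  y <- 2 * x1 + 1 * x2
  f <- fitAnnotationModel(cbind(a = x1, b = x2), y)
  expect_equal(unname(f@normalizedWeights), c(1, 0.5), tolerance = 1e-10)
  expect_equal(f@r, 1, tolerance = 1e-10)
  ## exact single-regressor fit
  f2 <- fitAnnotationModel(cbind(only = x1), x1)
  expect_equal(unname(f2@normalizedWeights), 1)
  expect_equal(f2@r, 1, tolerance = 1e-12)
  ## negative-dominant model keeps its sign
  f3 <- fitAnnotationModel(cbind(a = x1, b = x2), -2 * x1 + x2)
  expect_equal(unname(f3@normalizedWeights), c(-1, 0.5), tolerance = 1e-10)
  ## collinearity raises an error naming the dependent column
  expect_error(fitAnnotationModel(cbind(a = x1, b = x1), y), "collinear")
})

test_that("single-feature slopes recover constructed coefficients", {
  set.seed(85)
  x <- rnorm(50)
  Y <- rbind(3 * x, 3 * x, 3 * x)
  expect_equal(unname(singleFeatureFits(x, Y)), c(3, 3, 3), tolerance = 1e-12)
  expect_equal(unname(singleFeatureFits(x, rbind(-x))), -1, tolerance = 1e-12)
  ## sampling check: betas drawn around 0.5 recovered on average
  n <- 10
  betas <- rnorm(n, 0.5, 0.1)
  Y2 <- t(sapply(betas, function(b) b * x + rnorm(50, sd = 0.01)))
  got <- singleFeatureFits(x, Y2)
  expect_lt(abs(mean(got) - 0.5), 3 * 0.1 / sqrt(n))
})

test_that("weight tests behave on degenerate and strong-signal cases", {
  set.seed(87)
  b <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  same <- weightTests(b, b)
  expect_true(all(same$pPaired == 1))
  expect_true(all(same$tPaired == 0))
  ## constant positive weights with tiny jitter: tiny one-sample p
  bc <- matrix(2 + rnorm(30, sd = 1e-3), 10, 3)
  wt <- weightTests(bc, bc + 1e-3)
  expect_true(all(wt$p1 < 0.001))
  expect_error(weightTests(b[1:2, ], b[1:2, ]), "3 subjects")
})

test_that("one-sample weight test type-I rate is calibrated", {
  set.seed(89)
  nRep <- 4000
  b1 <- matrix(rnorm(10 * nRep), 10, nRep)
  p <- apply(b1, 2, function(v) stats::t.test(v)$p.value)
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.042)
  expect_lt(rate, 0.058)
})

test_that("ISC is a Fisher-z mean with clipping and permutation p", {
  ## identical series: clipped mean near 1
  Y <- matrix(rep(sin(1:50), 3), 3, byrow = TRUE)
  expect_gte(iscMean(Y, nPerm = 0)@meanR, 1 - 1e-6)
  ## equal pairwise correlations are returned exactly
  expect_equal(fisherZmean <- iscMean(rbind(c(1, 2, 3, 4, 5),
                                            c(1, 2, 3, 4, 5)) +
                 0, nPerm = 0)@meanR, 1 - 1e-12, tolerance = 1e-9)
  ## hand-computed Fisher-z mean of (0, 0.8)
  expect_equal(tanh((atanh(0) + atanh(0.8)) / 2), 0.4999, tolerance = 1e-3)
  set.seed(91)
  ## construct three series with known pairwise r, check z-mean identity
  x <- rnorm(200); Y3 <- rbind(x, x + rnorm(200), x + rnorm(200, sd = 2))
  res <- iscMean(Y3, nPerm = 0)
  expect_equal(res@meanR, tanh(mean(atanh(res@pairwiseR))), tolerance = 1e-12)
  expect_equal(res@dispersionSd^2, res@dispersion, tolerance = 1e-12)
  ## stimulus-locked shared signal gives small permutation p
  sig <- makeRegressor(rep(c(0, 1), each = 20, times = 5), tr = 2,
                       nTimepoints = 100)
  Ys <- t(sapply(1:4, function(i) sig + rnorm(100, sd = 0.4)))
  expect_lt(iscMean(Ys, nPerm = 400, seed = 3)@pValue, 0.01)
  expect_error(iscMean(Y[1, , drop = FALSE]), "2 subjects")
})

test_that("circular-shift model null has the exact realization arithmetic", {
  set.seed(93)
  X <- matrix(rnorm(60 * 3), 60)
  Y <- matrix(rnorm(60 * 5), 60)
  nul <- suppressWarnings(circularNull(X, Y))
  expect_length(nul@rSamples, 60 * 5)
  ## identity rotation contributes the observed r exactly once per series
  obs <- attr(nul, "observedR")
  for (j in 1:5) {
    direct <- cor(fitAnnotationModel(X, Y[, j])@fitted, Y[, j])
    expect_equal(obs[j], direct, tolerance = 1e-10)
    expect_true(any(abs(nul@rSamples - direct) < 1e-12))
  }
  ## FFT rotation path agrees with explicit refits at a few shifts
  Q <- qr.Q(qr(scale(X, center = TRUE, scale = FALSE)))
  rAll <- naturalfmri:::rotationR(Q, Y[, 1])
  for (s in c(0, 7, 31)) {
    ys <- naturalfmri:::rotateVec(Y[, 1], s)
    expect_equal(rAll[s + 1], cor(fitAnnotationModel(X, ys)@fitted, ys),
                 tolerance = 1e-10)
  }
  expect_warning(circularNull(X[1:40, ], Y[1:40, ]), "unstable")
})

test_that("single-regressor null threshold matches the analytic correlation null", {
  set.seed(95)
  Tt <- 679
  x <- rnorm(Tt)
  Y <- matrix(rnorm(Tt * 40), Tt)
  nul <- circularNull(matrix(x, ncol = 1), Y)
  got <- thresholdAt(nul, 0.001)
  ## |r| of two independent normal vectors: r^2 ~ Beta(1/2, (n-2)/2)
  want <- sqrt(qbeta(1 - 0.001, 1 / 2, (Tt - 2) / 2))
  expect_lt(abs(got - want), 0.02)
  ## threshold is monotone decreasing in p
  ps <- c(0.001, 0.01, 0.05, 0.2)
  expect_true(all(diff(thresholdAt(nul, ps)) < 0))
})

test_that("single-annotation nulls use two-step shifts and symmetric medians", {
  set.seed(97)
  Tt <- 101
  x <- rnorm(Tt)
  Y <- matrix(rnorm(Tt * 3), Tt)
  nul <- singleAnnotationNull(x, Y)
  expect_length(nul@rSamples, ceiling(Tt / 2) * 3)
  expect_lt(abs(thresholdAt(nul, 0.5)), 0.02)
  ## modality threshold is the arithmetic mean of the members
  n1 <- singleAnnotationNull(x, Y[, 1]); n2 <- singleAnnotationNull(x, Y[, 2])
  m <- modalityThreshold(list(n1, n2), p = 0.05)
  expect_equal(m, mean(c(thresholdAt(n1, 0.05), thresholdAt(n2, 0.05))),
               tolerance = 1e-12)
})

test_that("auditory and visual nulls differ when regressor counts differ", {
  cfg <- tinyConfig(seed = 99)
  ann <- genAnnotations(cfg)
  aud <- buildDesignMatrix(subsetTracks(ann, "auditory"), tr = cfg$tr,
                           nTimepoints = cfg$nTimepoints, modelId = "auditory")
  vis <- buildDesignMatrix(subsetTracks(ann, "visual"), tr = cfg$tr,
                           nTimepoints = cfg$nTimepoints, modelId = "visual")
  set.seed(100)
  Y <- matrix(rnorm(cfg$nTimepoints * 30), cfg$nTimepoints)
  tA <- thresholdAt(circularNull(aud, Y), 0.01)
  tV <- thresholdAt(circularNull(vis, Y), 0.01)
  expect_false(isTRUE(all.equal(tA, tV, tolerance = 1e-4)))
  expect_gt(tA, tV)   # more regressors fit noise better
})

test_that("annotation correlation matrices are symmetric with unit diagonal", {
  cfg <- tinyConfig(seed = 101)
  ann <- genAnnotations(cfg)
  res <- annotationCorrelationMatrix(ann)
  expect_equal(res$r, t(res$r))
  expect_equal(unname(diag(res$r)), rep(1, ncol(res$r)))
  expect_length(res$undefined, 0)
  ## duplicated track correlates at 1
  m <- cbind(a = rnorm(500), b = rnorm(500))
  m <- cbind(m, dup = m[, "a"])
  res2 <- annotationCorrelationMatrix(m)
  expect_equal(res2$r["a", "dup"], 1)
  expect_lt(abs(res2$r["a", "b"]), 0.1)
  ## constant track flagged undefined
  res3 <- annotationCorrelationMatrix(cbind(a = rnorm(50), k = rep(1, 50)))
  expect_equal(res3$undefined, "k")
  ## HRF-convolved variant runs and changes the off-diagonals
  res4 <- annotationCorrelationMatrix(m, convolve = hrfSpec())
  expect_false(isTRUE(all.equal(res4$r["a", "b"], res2$r["a", "b"])))
})

test_that("component selection applies all three criteria", {
  maps <- matrix(rnorm(3 * 100), 3)
  cs <- new("ComponentSet", spatialMaps = maps, rawMaps = maps,
            stabilityIndex = c(0.95, 0.95, 0.85),
            runCount = c(10L, 10L, 10L), nRuns = 10L)
  isc <- list(new("IscResult", pairwiseR = 0.5, meanR = 0.5,
                  dispersion = 0, dispersionSd = 0, pValue = 1e-4),
              new("IscResult", pairwiseR = 0.5, meanR = 0.5,
                  dispersion = 0, dispersionSd = 0, pValue = 0.5),
              new("IscResult", pairwiseR = 0.5, meanR = 0.5,
                  dispersion = 0, dispersionSd = 0, pValue = 1e-4))
  mkFit <- function(r) new("ModelFit", betas = c(a = 1), intercept = 0,
                           normalizedWeights = c(a = 1),
                           fitted = rnorm(5), r = r, rSquared = r^2)
  set.seed(103)
  nul <- suppressWarnings(
    circularNull(matrix(rnorm(60), ncol = 1), matrix(rnorm(60 * 20), 60)))
  thr <- thresholdAt(nul, 0.001)
  fits <- list(mkFit(min(thr + 0.2, 0.99)), mkFit(min(thr + 0.2, 0.99)),
               mkFit(min(thr + 0.2, 0.99)))
  cfg <- icaConfig(nComponents = 3, nRuns = 10)
  ## comp 1 passes everything; comp 2 fails only ISC; comp 3 fails only
  ## stability
  expect_equal(selectComponents(cs, isc, fitsAud = fits, nullAud = nul,
                                config = cfg), 1L)
  ## low model fit excludes as well
  lowFits <- list(mkFit(thr - 0.1), mkFit(thr - 0.1), mkFit(thr - 0.1))
  expect_length(selectComponents(cs, isc, fitsAud = lowFits, nullAud = nul,
                                 config = cfg), 0)
})
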