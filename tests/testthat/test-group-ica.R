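## Shared noiseless rank-4 fixture.
noiselessSim <- function(seed = 61) {
  cfg <- tinyConfig(seed = seed, sharedNoiseSd = 0, subjectNoiseSd = 0.2,
                    voxelNoiseSd = 0)
  ann <- genAnnotations(cfg)
  des <- buildDesignMatrix(subsetTracks(ann, "auditory"), tr = cfg$tr,
                           nTimepoints = cfg$nTimepoints)
  list(cfg = cfg, sim = genBold(cfg, des))
}

test_that("concatenation + PCA retains exact-rank data and matches the eigen oracle", {
  fx <- noiselessSim()
  pre <- standardizeDatasets(fx$sim$datasets)
  cfg <- icaConfig(nComponents = 4, nRuns = 2)
  red <- concatAndReduce(pre, cfg)
  expect_gte(red$explained, 0.999)
  ## single subject without subject PCA equals plain PCA of that subject
  one <- concatAndReduce(pre[1], cfg)
  Y <- boldMatrix(pre[[1]])
  e <- eigen(tcrossprod(Y), symmetric = TRUE)
  oracle <- crossprod(e$vectors[, 1:4], Y)
  ## same subspace: canonical correlations of the row spaces are all 1
  Q1 <- qr.Q(qr(t(one$reduced)))
  Q2 <- qr.Q(qr(t(oracle)))
  expect_equal(svd(crossprod(Q1, Q2))$d, rep(1, 4), tolerance = 1e-8)
  ## truncation residual equals the PCA oracle residual (noisy data so the
  ## residual is non-trivial)
  set.seed(62)
  noisy <- pre[[1]]
  noisy@data <- noisy@data + matrix(rnorm(length(noisy@data)),
                                    nrow(noisy@data))
  redN <- concatAndReduce(list(noisy), cfg)
  recon <- redN$eigVectors %*% redN$reduced
  resid <- sqrt(sum((boldMatrix(noisy) - recon)^2))
  eN <- eigen(tcrossprod(boldMatrix(noisy)), symmetric = TRUE)
  oracleResid <- sqrt(sum(pmax(eN$values[-(1:4)], 0)))
  expect_equal(resid, oracleResid, tolerance = 1e-8)
  expect_error(concatAndReduce(pre, icaConfig(nComponents = 400)),
               "rank")
})

test_that("the fixed-point estimator separates independent sources deterministically", {
  set.seed(63)
  S <- matrix(runif(2 * 4000, -1, 1), 2)
  A <- matrix(c(1.2, -0.4, 0.7, 2.1), 2)
  red <- list(reduced = A %*% S, concat = NULL, gram = NULL)
  dec <- runIcaOnce(red, seed = 64)
  expect_true(dec$converged)
  rho <- matchSignals <- naturalfmri:::matchSignals(t(S), t(dec$maps))$rho
  expect_true(all(rho > 0.99))
  expect_identical(dec$maps, runIcaOnce(red, seed = 64)$maps)
  ## different seed still recovers the same sources (up to sign/permutation)
  rho2 <- naturalfmri:::matchSignals(t(S), t(runIcaOnce(red, seed = 99)$maps))$rho
  expect_true(all(rho2 > 0.99))
})

test_that("stability clustering gives unit stability for identical runs", {
  set.seed(65)
  maps <- matrix(rnorm(3 * 500), 3)
  dec <- list(maps = maps, mixing = diag(3), converged = TRUE)
  comps <- icassoCluster(rep(list(dec), 10), icaConfig(nComponents = 3))
  expect_equal(stabilityIndex(comps), rep(1, 3))
  expect_equal(runCount(comps), rep(10L, 3))
  expect_error(icassoCluster(list(dec), icaConfig(nComponents = 3)),
               "at least 2")
})

test_that("bootstrapped runs on planted sources are stable, pure noise is less so", {
  fx <- noiselessSim(seed = 67)
  pre <- standardizeDatasets(fx$sim$datasets)
  cfg <- icaConfig(nComponents = 4, nRuns = 8, randomSeed = 3)
  comp <- groupICA(pre, cfg)
  expect_true(all(stabilityIndex(comp) > 0.9))
  expect_true(all(runCount(comp) == 8L))
  ## pure-noise data: mean stability falls below the planted-source case
  noise <- lapply(pre, function(d) {
    d@data <- matrix(rnorm(length(d@data)), nrow(d@data))
    d
  })
  compN <- groupICA(noise, cfg)
  expect_lt(mean(stabilityIndex(compN)), mean(stabilityIndex(comp)))
})

test_that("stability filtering honours the threshold and the all-runs rule", {
  cs <- new("ComponentSet", spatialMaps = matrix(rnorm(300), 3),
            stabilityIndex = c(1, 0.85, 0.95), runCount = c(10L, 10L, 9L),
            nRuns = 10L)
  cfg <- icaConfig(nComponents = 3, nRuns = 10)
  kept <- selectStable(cs, cfg)
  expect_equal(nComponents(kept), 1L)          # 0.85 < 0.9; 9 < 10 runs
  cfg$requireAllRuns <- FALSE
  expect_equal(nComponents(selectStable(cs, cfg)), 2L)
  cfgAll <- icaConfig(nComponents = 3, nRuns = 10, stabilityMin = 0.8,
                      requireAllRuns = FALSE)
  expect_equal(nComponents(selectStable(cs, cfgAll)), 3L)
})

test_that("back-reconstruction is the pseudo-inverse projection", {
  ## orthonormal maps: projection equals the plain weighted average
  set.seed(69)
  S <- qr.Q(qr(matrix(rnorm(50 * 3), 50)))[, 1:3]   # 50 voxels, 3 maps
  maps <- t(S)
  cs <- new("ComponentSet", spatialMaps = maps,
            stabilityIndex = rep(1, 3), runCount = rep(2L, 3), nRuns = 2L)
  Y <- matrix(rnorm(20 * 50), 20)
  d <- new("BoldDataset", data = Y, mask = array(TRUE, c(50, 1, 1)), tr = 2)
  out <- backReconstruct(cs, list(d))
  expect_equal(out@subjectTimecourses[[1]], t(Y %*% t(maps)),
               tolerance = 1e-10)
  ## zero data give zero time courses
  d0 <- new("BoldDataset", data = matrix(0, 20, 50),
            mask = array(TRUE, c(50, 1, 1)), tr = 2)
  expect_equal(max(abs(backReconstruct(cs, list(d0))@groupTimecourses)), 0)
  ## projection onto the true maps reproduces the generating time courses
  ## exactly on noiseless data (the projection itself, no estimation step)
  fx <- noiselessSim(seed = 71)
  truthMaps <- fx$sim$truth$spatialMaps
  cs2 <- new("ComponentSet", spatialMaps = truthMaps, rawMaps = truthMaps,
             stabilityIndex = rep(1, 4), runCount = rep(2L, 4), nRuns = 2L)
  out2 <- backReconstruct(cs2, fx$sim$datasets)
  for (s in 1:3) {
    truth <- t(fx$sim$truth$componentTimecourses[[s]])
    est <- t(out2@subjectTimecourses[[s]])
    expect_true(all(abs(diag(cor(truth, est))) > 0.999))
  }
  ## noiseless single-component data: the full ICA path is exact too
  cfg1 <- tinyConfig(seed = 72, nComponents = 1,
                     weightMatrix = defaultWeightMatrix(1),
                     sharedNoiseSd = 0, subjectNoiseSd = 0.2,
                     voxelNoiseSd = 0)
  ann1 <- genAnnotations(cfg1)
  des1 <- buildDesignMatrix(subsetTracks(ann1, "auditory"), tr = cfg1$tr,
                            nTimepoints = cfg1$nTimepoints)
  sim1 <- genBold(cfg1, des1)
  comp1 <- groupICA(standardizeDatasets(sim1$datasets),
                    icaConfig(nComponents = 1, nRuns = 4, randomSeed = 8))
  rho1 <- abs(cor(sim1$truth$componentTimecourses[[1]][1, ],
                  comp1@subjectTimecourses[[1]][1, ]))
  expect_gt(rho1, 0.999)
})

test_that("downstream statistics are invariant to component sign flips", {
  fx <- noiselessSim(seed = 73)
  pre <- standardizeDatasets(fx$sim$datasets)
  comp <- groupICA(pre, icaConfig(nComponents = 4, nRuns = 4, randomSeed = 2))
  flip <- comp
  flip@spatialMaps[2, ] <- -flip@spatialMaps[2, ]
  flip@rawMaps[2, ] <- -flip@rawMaps[2, ]
  flip <- backReconstruct(flip, pre)
  expect_equal(flip@groupTimecourses[2, ], -comp@groupTimecourses[2, ],
               tolerance = 1e-10)
  ## ISC and model-fit r are sign-invariant; stability uses |rho| already
  Y1 <- do.call(rbind, lapply(comp@subjectTimecourses, function(m) m[2, ]))
  Y2 <- do.call(rbind, lapply(flip@subjectTimecourses, function(m) m[2, ]))
  expect_equal(iscMean(Y1, nPerm = 0)@meanR, iscMean(Y2, nPerm = 0)@meanR,
               tolerance = 1e-10)
  des <- buildDesignMatrix(subsetTracks(genAnnotations(fx$cfg), "auditory"),
                           tr = fx$cfg$tr, nTimepoints = fx$cfg$nTimepoints)
  f1 <- fitAnnotationModel(des, comp@groupTimecourses[2, ])
  f2 <- fitAnnotationModel(des, flip@groupTimecourses[2, ])
  expect_equal(f1@r, f2@r, tolerance = 1e-10)
  ## stability index is invariant to reordering
  expect_equal(sort(stabilityIndex(comp[4:1])), sort(stabilityIndex(comp)))
})
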