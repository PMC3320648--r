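## End-to-end pipeline driver: annotations -> design -> group ICA ->
## selection -> inference -> networks, on synthetic or loaded data.

#' Run the full analysis pipeline on a synthetic study
#'
#' Generates a synthetic annotated study from \code{config}, builds the
#' auditory (4 boxcars + 4 acoustic descriptors) and visual (edge density +
#' 6 motion categories) design matrices, simulates multi-subject BOLD data
#' with planted networks driven by the auditory model, preprocesses
#' (high-pass detrend, voxel standardisation), runs bootstrapped group ICA
#' with stability clustering and back-reconstruction, screens components by
#' inter-subject correlation and model fit against circular-shift
#' permutation thresholds, and (optionally) runs the voxel-wise GLM,
#' cluster labeling, overlap classification and ROI connectivity testing.
#'
#' @param config a \code{\link{synthConfig}}; its seed drives every random
#'   stage, so a fixed config reproduces the summary exactly.
#' @param ica an \code{\link{icaConfig}}.
#' @param alpha significance level for ISC and model thresholds.
#' @param highpassSigma Gaussian running-line SD in seconds.
#' @param minClusterSize cluster size threshold for the network stage (the
#'   full-scale analysis used 125 voxels; desk-scale masks need a smaller
#'   value).
#' @param icThreshold |z| threshold binarising IC maps.
#' @param voxelwise run the voxel-wise GLM/cluster/overlap stage.
#' @param connectivityPerms permutations for the ROI connectivity null.
#' @param iscPerm permutations per component for the ISC p-value.
#' @param models which annotation models to fit (\code{"auditory"},
#'   \code{"visual"}); outputs of an omitted model are absent.
#' @param outDir optional output directory; when given, annotations,
#'   designs, component maps/tables and the summary are written there.
#' @return list with elements \code{annotations}, \code{designs},
#'   \code{truth}, \code{components} (stable \linkS4class{ComponentSet}),
#'   \code{isc}, \code{fits}, \code{nulls}, \code{selected} (indices into
#'   the stable set), \code{truthMatch} (per planted component: best
#'   selected match and |temporal r|), \code{networks} (when
#'   \code{voxelwise}), and \code{meta} (seed, config hash, stage log).
#' @examples
#' \donttest{
#' cfg <- synthConfig(nSubjects = 3, nTimepoints = 120, nVoxels = 500,
#'                    maskShape = c(10, 10, 5), seed = 7)
#' res <- runPipeline(cfg, ica = icaConfig(nComponents = 5, nRuns = 6),
#'                    voxelwise = FALSE, iscPerm = 100)
#' res$selected
#' }
#' @export
runPipeline <- function(config = synthConfig(), ica = icaConfig(),
                        alpha = 0.001, highpassSigma = 100,
                        minClusterSize = 25L, icThreshold = 3,
                        voxelwise = TRUE, connectivityPerms = 1e4,
                        iscPerm = 2000L, models = c("auditory", "visual"),
                        outDir = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  log <- list()
  stamp <- function(stage, ...) {
    log[[stage]] <<- c(list(time = format(Sys.time())), list(...))
  }

  ann <- genAnnotations(config)
  stamp("annotations", tracks = length(ann@tracks))
  designAud <- buildDesignMatrix(subsetTracks(ann, "auditory"),
                                 tr = config$tr,
                                 nTimepoints = config$nTimepoints,
                                 modelId = "auditory")
  designVis <- if ("visual" %in% models)
    buildDesignMatrix(subsetTracks(ann, "visual"), tr = config$tr,
                      nTimepoints = config$nTimepoints,
                      modelId = "visual") else NULL
  stamp("design", aud = ncol(designAud@matrix),
        vis = if (is.null(designVis)) 0L else ncol(designVis@matrix))

  sim <- genBold(config, designAud)
  stamp("bold", subjects = length(sim$datasets),
        voxels = nVoxels(sim$datasets[[1]]))

  pre <- standardizeDatasets(
    lapply(sim$datasets, highpassDetrend, sigma = highpassSigma))
  stamp("preprocess", sigma = highpassSigma)

  comp <- groupICA(pre, ica)
  stable <- selectStable(comp, ica)
  stable <- backReconstruct(stable, pre)
  stamp("ica", found = nComponents(comp), stable = nComponents(stable))

  k <- nComponents(stable)
  isc <- lapply(seq_len(k), function(j) {
    Y <- do.call(rbind, lapply(stable@subjectTimecourses,
                               function(tc) tc[j, ]))
    iscMean(Y, nPerm = iscPerm, seed = config$seed + j)
  })
  gtc <- t(stable@groupTimecourses)              # time x components
  fitAll <- function(design) lapply(seq_len(k), function(j)
    fitAnnotationModel(design, gtc[, j]))
  fitsAud <- if ("auditory" %in% models) fitAll(designAud) else NULL
  fitsVis <- if (!is.null(designVis)) fitAll(designVis) else NULL
  ## screening nulls need a dense realization population for a 0.001 tail;
  ## rotations of the standardized-average voxel series supply it at any
  ## scale (the same null population as the voxel-wise GLM threshold)
  groupMean <- standardizeAndAverage(pre)
  sel <- seq(1, nVoxels(groupMean),
             by = max(1L, floor(nVoxels(groupMean) / 200)))
  voxNull <- function(design, id) {
    nl <- circularNull(design, boldMatrix(groupMean)[, sel, drop = FALSE])
    nl@modelId <- id
    nl
  }
  nullAud <- if (!is.null(fitsAud)) voxNull(designAud, "auditory") else NULL
  nullVis <- if (!is.null(fitsVis)) voxNull(designVis, "visual") else NULL
  selected <- selectComponents(stable, isc, fitsAud, fitsVis,
                               nullAud, nullVis, config = ica, alpha = alpha)
  stamp("inference", selected = length(selected))

  ## match the planted stimulus-locked components to the selected ones
  planted <- which(rowSums(config$weightMatrix != 0) > 0)
  truthTc <- t(sim$truth$sharedTimecourses)       # time x components
  truthMatch <- NULL
  if (length(selected)) {
    mm <- matchSignals(truthTc[, planted, drop = FALSE],
                       gtc[, selected, drop = FALSE])
    truthMatch <- data.frame(planted = planted,
                             selected = selected[mm$index],
                             temporalR = mm$rho)
  }

  networks <- NULL
  if (voxelwise && k >= 1 && !is.null(nullAud)) {
    vr <- voxelModelR(designAud, boldMatrix(groupMean))
    nullVox <- nullAud
    thrVox <- thresholdAt(nullVox, alpha)
    mask <- sim$datasets[[1]]@mask
    voxMask <- array(FALSE, dim(mask))
    voxMask[which(mask)] <- vr$r > thrVox
    icIdx <- utils::head(selected, 2)
    icMasks <- lapply(icIdx, function(j) {
      m <- array(FALSE, dim(mask))
      m[which(mask)] <- abs(stable@spatialMaps[j, ]) > icThreshold
      m
    })
    overlap <- if (length(icMasks) == 2)
      classifyOverlap(voxMask, icMasks[[1]], icMasks[[2]]) else NULL
    cl <- labelClusters(voxMask, minClusterSize = minClusterSize,
                        data = boldMatrix(groupMean), maskArray = mask)
    conn <- if (length(cl@sizes) >= 2)
      roiConnectivityThreshold(cl@meanTimecourses,
                               nPermutations = connectivityPerms,
                               seed = config$seed) else NULL
    networks <- list(voxelMask = voxMask, voxelNull = nullVox,
                     voxelThreshold = thrVox, icMasks = icMasks,
                     overlap = overlap, clusters = cl, connectivity = conn)
    stamp("networks", clusters = length(cl@sizes))
  }

  meta <- list(seed = config$seed, configHash = configHash(config),
               stages = log)
  out <- list(annotations = ann,
              designs = list(auditory = designAud, visual = designVis),
              truth = sim$truth, components = stable, isc = isc,
              fits = list(auditory = fitsAud, visual = fitsVis),
              nulls = list(auditory = nullAud, visual = nullVis),
              selected = selected, truthMatch = truthMatch,
              networks = networks, meta = meta)
  if (!is.null(outDir)) writePipelineOutputs(out, sim, outDir)
  out
}

## Multiple correlation of the model with every voxel series.
voxelModelR <- function(design, Y) {
  M <- designMatrix(design)
  Q <- qr.Q(qr(scale(M, center = TRUE, scale = FALSE)))
  Yc <- sweep(Y, 2, colMeans(Y))
  num <- sqrt(colSums(crossprod(Q, Yc)^2))
  den <- sqrt(colSums(Yc^2))
  den[den == 0] <- Inf
  list(r = num / den, volumeIdx = seq_len(ncol(Y)))
}

## Small stable hash of a config list (hex of a polynomial byte roll).
configHash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2^31
  sprintf("%08x", as.integer(h))
}

writePipelineOutputs <- function(res, sim, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeAnnotations(res$annotations, file.path(outDir, "annotations.tsv"))
  writeDesign(res$designs$auditory, file.path(outDir, "design_auditory.tsv"))
  if (!is.null(res$designs$visual))
    writeDesign(res$designs$visual, file.path(outDir, "design_visual.tsv"))
  writeComponentSet(res$components, sim$datasets[[1]]@mask,
                    file.path(outDir, "components.nii.gz"),
                    file.path(outDir, "components.tsv"))
  summ <- data.frame(
    component = seq_len(nComponents(res$components)),
    stability = stabilityIndex(res$components),
    runCount = runCount(res$components),
    iscMeanR = vapply(res$isc, function(z) z@meanR, numeric(1)),
    iscP = vapply(res$isc, function(z) z@pValue, numeric(1)),
    rAud = vapply(res$fits$auditory, function(f) f@r, numeric(1)),
    rVis = vapply(res$fits$visual, function(f) f@r, numeric(1)),
    selected = seq_len(nComponents(res$components)) %in% res$selected,
    configHash = res$meta$configHash, seed = res$meta$seed)
  utils::write.table(summ, file.path(outDir, "summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(outDir)
}
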