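.configDefaults <- function() {
  list(
    version = 1L,
    seed = 1L,
    outDir = "premap-run",
    stages = c("parcellation", "bridge", "expression", "fingerprints",
               "crossmap", "b1map", "perturbation"),
    tracer = list(nInjections = 30L, profileSeparation = 3, noiseSd = 1,
                  smoothSigmaMm = NULL),
    parcellation = list(kMin = 2L, kMax = 8L, nRestarts = 50L,
                        nResamples = 20L, subsampleFrac = 0.8,
                        stabilityThreshold = 0.8, silhouetteTol = 0.05),
    bridge = list(nVoxels = 200L, nFeatures = 500L, sdSignal = 1,
                  sdA = 1.4, sdB = 1.4, nullDraws = 200L),
    expression = list(nGenes = 100L, fracAffected = 0.2,
                      effectSdUnits = 0.5, nPerm = 500L),
    fingerprints = list(nSubjects = 6L, nTimepoints = 200L, noiseSd = 1,
                        nPerm = 500L, alpha = 0.05, method = "maxstat"),
    b1map = list(nominalAngle = 40, m0 = 1, noiseSd = 0),
    perturbation = list(counts = c("3" = 15L, "4" = 9L))
  )
}

.mergeConfig <- function(user, defaults, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("config key ", full, " must be a list")
      defaults[key] <- list(.mergeConfig(user[[key]], defaults[[key]],
                                         full))
    } else {
      defaults[key] <- list(user[[key]])  # keeps explicit NULL values
    }
  }
  defaults
}

#' Validate and normalize a run configuration
#'
#' Fills schema defaults, rejects unknown keys (naming the offending
#' key), and checks cross-field constraints before any compute.
#' Normalization is idempotent.
#'
#' @param config a named list, or the path to a YAML file.
#' @return the normalized configuration list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  cfg <- .mergeConfig(config, .configDefaults())
  if (cfg$parcellation$kMin > cfg$parcellation$kMax)
    stop("invalid k range: kMin > kMax")
  if (cfg$parcellation$kMin < 2L) stop("kMin must be >= 2")
  bad <- setdiff(cfg$stages, .configDefaults()$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.writeCsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = !is.null(rownames(x)) &&
                     !identical(rownames(x), as.character(seq_len(nrow(x)))))
  path
}

# block-factor correlation matrix for the demo ROI panel (deterministic)
.demoTargetCorr <- function(nSeeds, nTargets) {
  L <- matrix(0, nSeeds + nTargets, nSeeds)
  for (s in seq_len(nSeeds)) {
    L[s, s] <- 0.9
    tgt <- nSeeds + ((s - 1L) %% nTargets) + 1L
    L[tgt, s] <- 0.7
    tgt2 <- nSeeds + (s %% nTargets) + 1L
    L[tgt2, s] <- 0.35
  }
  C <- L %*% t(L)
  u <- sqrt(pmax(diag(C), 0.999))
  C <- C / (u %o% u)
  diag(C) <- 1
  C
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the selected stages in dependency order on synthetic data
#' with planted ground truth, writes every figure-equivalent output
#' (metrics table, parcel labels, bridge statistics, expression tests,
#' fingerprint templates, divergence matrix and embedding,
#' winner-take-all map, B1+ recovery, perturbation radar percentages)
#' under \code{outDir}, and records a JSON manifest with parameters,
#' per-stage seeds, and MD5 checksums of all outputs. Reruns with an
#' identical configuration are bit-identical for deterministic stages.
#'
#' @param config a configuration list or YAML path (see
#'   \code{\link{validateConfig}}).
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  results <- list()
  geometry <- generateParcelGeometry()
  seeds <- list(tracer = cfg$seed + 101L, bridge = cfg$seed + 202L,
                expression = cfg$seed + 303L, fmri = cfg$seed + 404L,
                b1map = cfg$seed + 505L, perturb = cfg$seed + 606L)

  if ("parcellation" %in% cfg$stages) {
    gen <- generateTracerSet(geometry, cfg$tracer$nInjections,
                             cfg$tracer$profileSeparation,
                             cfg$tracer$smoothSigmaMm,
                             cfg$tracer$noiseSd, seed = seeds$tracer)
    parc <- parcellate(gen$tracers,
                       kRange = cfg$parcellation$kMin:cfg$parcellation$kMax,
                       nRestarts = cfg$parcellation$nRestarts,
                       nResamples = cfg$parcellation$nResamples,
                       subsampleFrac = cfg$parcellation$subsampleFrac,
                       stabilityThreshold = cfg$parcellation$stabilityThreshold,
                       silhouetteTol = cfg$parcellation$silhouetteTol,
                       seed = cfg$seed)
    outputs <- c(outputs,
                 .writeCsv(perKMetrics(parc), cfg$outDir, "parcel_metrics.csv"),
                 writeVolume(parcelLabels(parc),
                             file.path(cfg$outDir, "parcel_labels.nii.gz")))
    results$parcellation <- list(selectedK = selectedK(parc))
  }

  if ("bridge" %in% cfg$stages) {
    pm <- generatePairedModalities(cfg$bridge$nVoxels, cfg$bridge$nFeatures,
                                   cfg$bridge$sdSignal, cfg$bridge$sdA,
                                   cfg$bridge$sdB, seed = seeds$bridge)
    vc <- voxelwiseModalCorrelation(pm$a, pm$b)
    outPool <- generatePairedModalities(cfg$bridge$nVoxels,
                                        cfg$bridge$nFeatures,
                                        cfg$bridge$sdSignal, cfg$bridge$sdA,
                                        cfg$bridge$sdB,
                                        seed = seeds$bridge + 1L)$a
    nullR <- conservativeNull(pm$b, outPool, cfg$bridge$nullDraws,
                              seed = seeds$bridge + 2L)
    ks <- ksCompare(vc$r, nullR)
    results$bridge <- list(
      expectedR = pm$expectedR, meanR = mean(vc$r),
      medianR = stats::median(vc$r),
      fracSignificant = mean(vc$p < 0.001),
      nullMeanR = mean(nullR), nullMedianR = stats::median(nullR),
      ksStat = ks$ks_stat, ksP = ks$ks_p)
    path <- file.path(cfg$outDir, "bridge.json")
    jsonlite::write_json(results$bridge, path, auto_unbox = TRUE,
                         digits = NA)
    outputs <- c(outputs, path)
  }

  if ("expression" %in% cfg$stages) {
    ex <- generateExpression(geometry, cfg$expression$nGenes,
                             cfg$expression$fracAffected,
                             cfg$expression$effectSdUnits,
                             seed = seeds$expression)
    prof <- regionExpressionProfile(ex$expr, geometry)
    labs <- sort(unique(ex$voxelLabels))
    tests <- list()
    for (i in seq_along(labs)[-length(labs)]) {
      for (j in (i + 1):length(labs)) {
        a <- t(ex$expr[, ex$voxelLabels == labs[i], drop = FALSE])
        b <- t(ex$expr[, ex$voxelLabels == labs[j], drop = FALSE])
        mt <- manhattanPermTest(a, b, nPerm = cfg$expression$nPerm,
                                seed = seeds$expression + i * 10L + j)
        tests[[paste0(labs[i], "_vs_", labs[j])]] <-
          data.frame(regionA = labs[i], regionB = labs[j],
                     distance = mt$distance, p = mt$p)
      }
    }
    tests <- do.call(rbind, tests)
    outputs <- c(outputs,
                 .writeCsv(prof, cfg$outDir, "region_expression.csv"),
                 .writeCsv(tests, cfg$outDir, "expression_tests.csv"))
    results$expression <- list(minP = min(tests$p), maxP = max(tests$p))
  }

  templates <- NULL
  if (any(c("fingerprints", "crossmap") %in% cfg$stages)) {
    # shared ROI panel: 4 seed areas + 6 homolog targets on a small grid
    fg <- volumeGrid(c(12L, 12L, 2L), c(1, 1, 1), "allen-ccf-like")
    roiArr <- array(0L, gridDim(fg))
    ctrs <- list(c(2, 2, 1), c(2, 8, 1), c(8, 2, 1), c(8, 8, 1),
                 c(5, 2, 1), c(5, 5, 1), c(5, 8, 1), c(2, 5, 1),
                 c(8, 5, 1), c(11, 5, 1))
    for (i in seq_along(ctrs)) {
      c0 <- ctrs[[i]]
      roiArr[c0[1]:(c0[1] + 1), c0[2]:(c0[2] + 1), c0[3]] <- i
    }
    tnames <- c(motorAreaNames(), paste0("T", 1:6))
    rois <- labeledVolume(roiArr, fg,
                          stats::setNames(tnames, as.character(1:10)))
    targets <- labeledVolume(ifelse(roiArr > 4L, roiArr, 0L), fg,
                             stats::setNames(tnames[5:10],
                                             as.character(5:10)))
    C <- .demoTargetCorr(4L, 6L)
    mouseTs <- generateFmriTimeseries(cfg$fingerprints$nSubjects, rois, C,
                                      cfg$fingerprints$nTimepoints,
                                      cfg$fingerprints$noiseSd,
                                      seed = seeds$fmri)
    humanTs <- generateFmriTimeseries(cfg$fingerprints$nSubjects, rois, C,
                                      cfg$fingerprints$nTimepoints,
                                      cfg$fingerprints$noiseSd,
                                      seed = seeds$fmri + 50L)
    fps <- lapply(1:4, function(s) {
      sapply(mouseTs, function(ts)
        roiFingerprint(ts, labeledVolume(ifelse(roiArr == s, 1L, 0L), fg),
                       targets))
    })
    names(fps) <- motorAreaNames()
    templates <- lapply(fps, templateFingerprint)
    tplMat <- do.call(rbind, templates)
    outputs <- c(outputs,
                 .writeCsv(tplMat, cfg$outDir, "template_fingerprints.csv"))
  }

  if ("fingerprints" %in% cfg$stages) {
    humanMask <- roiArr >= 1L & roiArr <= 4L
    sims <- lapply(motorAreaNames(), function(a)
      similarityMaps(humanTs, templates[[a]], targets, humanMask,
                     seedName = a, nPerm = cfg$fingerprints$nPerm,
                     alpha = cfg$fingerprints$alpha,
                     method = cfg$fingerprints$method,
                     seed = seeds$fmri + 99L))
    names(sims) <- motorAreaNames()
    wta <- winnerTakeAll(sims, humanMask, grid = fg)
    outputs <- c(outputs,
                 writeVolume(wta$labels, file.path(cfg$outDir, "wta.nii.gz")))
    results$fingerprints <- list(
      nSignificant = vapply(sims, function(s) sum(s@sigMask), integer(1)),
      wtaCounts = table(wta$labels@data[humanMask]))
  }

  if ("crossmap" %in% cfg$stages) {
    humanFps <- lapply(1:4, function(s) {
      sapply(humanTs, function(ts)
        roiFingerprint(ts, labeledVolume(ifelse(roiArr == s, 1L, 0L), fg),
                       targets))
    })
    names(humanFps) <- paste0("human.", motorAreaNames())
    allFps <- c(templates, lapply(humanFps, templateFingerprint))
    D <- klMatrix(allFps)
    emb <- spectralEmbed(D)
    embSens <- spectralEmbed(klMatrix(leaveOutTargets(allFps,
                                                      c("T1", "T2"))))
    outputs <- c(outputs,
                 .writeCsv(D, cfg$outDir, "divergence.csv"),
                 .writeCsv(emb$coords, cfg$outDir, "embedding.csv"),
                 .writeCsv(embSens$coords, cfg$outDir,
                           "embedding_leaveout.csv"))
    results$crossmap <- list(kernelScale = emb$kernelScale)
  }

  if ("b1map" %in% cfg$stages) {
    bg <- volumeGrid(c(10L, 10L, 4L), c(0.1, 0.1, 0.1))
    xw <- (seq_len(10) - 5.5) / 5.5
    b1True <- scalarVolume(
      outer(outer(100 + 15 * xw, rep(1, 10)), rep(1, 4)), bg)
    pair <- generateDamPair(b1True, cfg$b1map$nominalAngle, cfg$b1map$m0,
                            cfg$b1map$noiseSd, seed = seeds$b1map)
    b1Est <- damB1Map(pair$A1, pair$A2, cfg$b1map$nominalAngle)
    results$b1map <- list(
      maxAbsErrorPct = max(abs(volData(b1Est)[volMask(b1Est)] -
                                 volData(b1True)[volMask(b1Est)])))
    outputs <- c(outputs,
                 writeVolume(b1Est, file.path(cfg$outDir, "b1map.nii.gz")))
  }

  if ("perturbation" %in% cfg$stages) {
    counts <- cfg$perturbation$counts
    if (is.null(names(counts))) names(counts) <- c("3", "4")
    tab <- generatePerturbationTable(as.list(counts), geometry,
                                     seed = seeds$perturb)
    assigned <- assignExperiments(tab, geometry)
    feats <- tabulateTaskFeatures(assigned)
    outputs <- c(outputs,
                 .writeCsv(assigned, cfg$outDir, "perturbation_assigned.csv"),
                 .writeCsv(feats$percent, cfg$outDir, "task_features.csv"),
                 .writeCsv(feats$normalized, cfg$outDir,
                           "task_features_normalized.csv"))
    results$perturbation <- list(
      countsByParcel = table(assigned$parcel))
  }

  manifest <- list(
    package = "premap",
    version = as.character(utils::packageVersion("premap")),
    rVersion = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    stageSeeds = seeds,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))),
    results = results)
  manifestPath <- file.path(cfg$outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
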