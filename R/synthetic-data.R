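#' The default connectivity-target panel
#'
#' The ordered 18-target panel of areas with known mouse-human homologs
#' used for connectivity fingerprints: bilateral sensory, limbic,
#' prefrontal and striatal targets plus three left-hemisphere
#' sensorimotor targets.
#'
#' @return character(18) of target names, in fingerprint order.
#' @export
defaultTargets <- function() {
  c("S1", "S2", "V1", "A1", "HPCd", "HPCv", "IL", "PL", "RSC", "OFCl",
    "BLA", "TPJp", "CPm", "CPl", "NAcc", "S1.left", "S2.left", "M1.left")
}

#' The mouse motor-system area names
#' @return character(4): M1, ALM, aM2, pM2 in label order.
#' @export
motorAreaNames <- function() c("M1", "ALM", "aM2", "pM2")

# Default stereotaxic grid for the motor-system preset: 0.2 mm voxels,
# AP -1.4..1.8, ML 0..2.6, DV 1.2..1.8 mm from bregma.
.motorSystemGrid <- function() {
  volumeGrid(c(17L, 14L, 4L), c(0.2, 0.2, 0.2),
             frame = "stereotaxic-bregma", originVoxel = c(7, 0, -6))
}

#' Generate a planted parcel geometry
#'
#' Builds a \linkS4class{LabeledVolume} of non-overlapping contiguous
#' parcels that jointly cover the mask. The \code{"motor-system"} preset
#' plants four parcels emulating the reported motor-cortex subdivision:
#' a lateral strip split antero-posteriorly into ALM and M1, and a
#' medial strip split into aM2 and pM2 by an oblique border that runs at
#' an angle to the midline (aM2 anterior-lateral, pM2 posterior-medial).
#' The \code{"two-block"} preset splits the grid into two equal halves.
#' Explicit \code{boxes} (0-based inclusive voxel ranges) may be given
#' instead; overlapping boxes are an error.
#'
#' @param grid a \linkS4class{VolumeGrid}; defaults to the preset's
#'   native grid (motor-system: 17 x 14 x 4 voxels of 0.2 mm in the
#'   stereotaxic-bregma frame).
#' @param preset \code{"motor-system"} or \code{"two-block"}.
#' @param boxes optional list of \code{list(lo =, hi =)} voxel boxes.
#' @param labelNames optional names for the parcels.
#' @return A \linkS4class{LabeledVolume}.
#' @export
generateParcelGeometry <- function(grid = NULL,
                                   preset = c("motor-system", "two-block"),
                                   boxes = NULL, labelNames = NULL) {
  if (!is.null(boxes)) {
    if (is.null(grid)) stop("explicit boxes require a grid")
    dat <- array(0L, grid@dim)
    for (i in seq_along(boxes)) {
      b <- boxes[[i]]
      sub <- dat[(b$lo[1] + 1):(b$hi[1] + 1),
                 (b$lo[2] + 1):(b$hi[2] + 1),
                 (b$lo[3] + 1):(b$hi[3] + 1)]
      if (any(sub != 0L)) stop("boxes overlap")
      dat[(b$lo[1] + 1):(b$hi[1] + 1),
          (b$lo[2] + 1):(b$hi[2] + 1),
          (b$lo[3] + 1):(b$hi[3] + 1)] <- i
    }
    return(labeledVolume(dat, grid, labelNames))
  }
  preset <- match.arg(preset)
  if (preset == "two-block") {
    if (is.null(grid)) grid <- volumeGrid(c(20L, 20L, 20L), c(1, 1, 1))
    dat <- array(0L, grid@dim)
    half <- grid@dim[1] %/% 2L
    dat[seq_len(half), , ] <- 1L
    dat[(half + 1L):grid@dim[1], , ] <- 2L
    return(labeledVolume(dat, grid, labelNames))
  }
  # motor-system preset
  if (is.null(grid)) grid <- .motorSystemGrid()
  dat <- array(0L, grid@dim)
  idx <- which(array(TRUE, grid@dim))
  sub <- arrayInd(idx, grid@dim) - 1L
  world <- t(grid@affine[1:3, 1:3] %*% t(sub) + grid@affine[1:3, 4])
  ap <- world[, 1]; ml <- world[, 2]
  lab <- integer(length(idx))
  lat <- ml >= 1.3
  lab[lat & ap < 0.55] <- 1L                 # M1: posterior lateral
  lab[lat & ap >= 0.55] <- 2L                # ALM: anterior lateral
  # oblique aM2/pM2 border: AP = 0.8 - 0.6 * ML (angled to the midline)
  lab[!lat & ap > 0.8 - 0.6 * ml] <- 3L      # aM2: anterior-lateral MOs
  lab[!lat & ap <= 0.8 - 0.6 * ml] <- 4L     # pM2: posterior-medial MOs
  dat[idx] <- lab
  if (is.null(labelNames))
    labelNames <- stats::setNames(motorAreaNames(), as.character(1:4))
  labeledVolume(dat, grid, labelNames)
}

#' Generate a tracer-like experiment set with planted parcel structure
#'
#' Each parcel receives a latent per-injection connectivity profile
#' (drawn N(0, separation^2)); every voxel's raw value is its parcel's
#' profile plus spatially smoothed Gaussian noise standardized to
#' \code{noiseSd}, and each volume is then min-max normalized to [0, 1]
#' within the mask, mirroring how projection volumes are prepared before
#' clustering.
#'
#' @param geometry a \linkS4class{LabeledVolume} of planted parcels.
#' @param nInjections number of injection volumes (>= 2; default 30).
#' @param profileSeparation between-parcel effect size in noise-SD units
#'   (default 3).
#' @param smoothSigmaMm noise smoothing sigma in mm (default one voxel).
#' @param noiseSd noise standard deviation after smoothing (default 1).
#' @param seed RNG seed.
#' @return list with \code{tracers} (a
#'   \linkS4class{TracerExperimentSet}) and \code{truth} (planted labels,
#'   latent profiles, parameters, seed).
#' @export
generateTracerSet <- function(geometry, nInjections = 30L,
                              profileSeparation = 3, smoothSigmaMm = NULL,
                              noiseSd = 1, seed = 1L) {
  if (nInjections < 2L) stop("nInjections must be >= 2")
  if (noiseSd <= 0 && profileSeparation == 0)
    warning("degenerate generator: no noise and no separation")
  grid <- geometry@grid
  if (is.null(smoothSigmaMm)) smoothSigmaMm <- grid@voxelSize[1]
  mask <- geometry@data != 0L
  labs <- sort(unique(as.integer(geometry@data[mask])))
  nP <- length(labs)
  .withSeed(seed, {
    mu <- matrix(stats::rnorm(nP * nInjections, 0, profileSeparation),
                 nP, nInjections,
                 dimnames = list(as.character(labs), NULL))
    sigmaVox <- rep(smoothSigmaMm, length.out = 3) / grid@voxelSize
    vols <- vector("list", nInjections)
    for (j in seq_len(nInjections)) {
      eps <- array(stats::rnorm(prod(grid@dim)), grid@dim)
      if (any(sigmaVox > 0)) {
        eps <- .gaussSmooth3d(eps, sigmaVox, pad = "replicate")
        s <- stats::sd(eps[mask])
        if (s > 0) eps <- eps / s
      }
      raw <- array(0, grid@dim)
      raw[mask] <- mu[match(geometry@data[mask], labs), j] +
        noiseSd * eps[mask]
      vols[[j]] <- volData(normalizeUnitInterval(
        scalarVolume(raw, grid, mask)))
    }
  })
  tracers <- new("TracerExperimentSet", grid = grid, volumes = vols,
                 mask = mask,
                 injectionIds = sprintf("inj%03d", seq_len(nInjections)))
  truth <- list(plantedLabels = geometry, latentProfiles = mu,
                noiseSd = noiseSd, profileSeparation = profileSeparation,
                smoothSigmaMm = smoothSigmaMm, seed = seed)
  list(tracers = tracers, truth = truth)
}

#' Generate paired modalities with a calibrated cross-modal correlation
#'
#' Both matrices share a latent per-voxel profile with SD
#' \code{sdSignal}; modality-specific Gaussian noise with SDs \code{sdA}
#' and \code{sdB} is added. The population per-voxel Pearson correlation
#' between the two modalities is the closed form
#' \deqn{r = sd_s^2 / \sqrt{(sd_s^2 + sd_a^2)(sd_s^2 + sd_b^2)}}
#' returned as \code{expectedR}.
#'
#' @param nVoxels number of voxels (rows), or a
#'   \linkS4class{LabeledVolume} whose in-mask voxel count is used.
#' @param nFeatures number of shared features (columns).
#' @param sdSignal latent signal SD (> 0).
#' @param sdA,sdB modality noise SDs (>= 0).
#' @param seed RNG seed.
#' @return list(\code{a}, \code{b}: voxel x feature matrices;
#'   \code{expectedR}).
#' @export
generatePairedModalities <- function(nVoxels, nFeatures, sdSignal = 1,
                                     sdA = 1.4, sdB = 1.4, seed = 1L) {
  if (is(nVoxels, "LabeledVolume")) nVoxels <- sum(nVoxels@data != 0L)
  if (sdSignal <= 0) stop("sdSignal must be > 0")
  if (sdA < 0 || sdB < 0) stop("noise sds must be >= 0")
  .withSeed(seed, {
    lat <- matrix(stats::rnorm(nVoxels * nFeatures, 0, sdSignal),
                  nVoxels, nFeatures)
    a <- lat + matrix(stats::rnorm(nVoxels * nFeatures, 0, sdA),
                      nVoxels, nFeatures)
    b <- lat + matrix(stats::rnorm(nVoxels * nFeatures, 0, sdB),
                      nVoxels, nFeatures)
  })
  expectedR <- sdSignal^2 /
    sqrt((sdSignal^2 + sdA^2) * (sdSignal^2 + sdB^2))
  list(a = a, b = b, expectedR = expectedR)
}

#' Generate multi-subject 4D time series with a planted ROI correlation
#' structure
#'
#' ROI-mean time courses are drawn from a multivariate normal whose
#' population correlation is \code{targetCorr}; each voxel's series is
#' its ROI's course plus white noise, and background voxels are pure
#' noise.
#'
#' @param nSubjects number of subjects.
#' @param rois a \linkS4class{LabeledVolume} of seed and target ROIs.
#' @param targetCorr symmetric positive semi-definite correlation matrix
#'   (unit diagonal) over the ROI labels, in ascending label order.
#' @param nTimepoints time series length (default 900 volumes).
#' @param noiseSd voxelwise white-noise SD (default 1).
#' @param seed RNG seed.
#' @return list of per-subject 4D arrays (x, y, z, t) with attribute
#'   \code{roiLabels}.
#' @export
generateFmriTimeseries <- function(nSubjects, rois, targetCorr,
                                   nTimepoints = 900L, noiseSd = 1,
                                   seed = 1L) {
  labs <- sort(unique(as.integer(rois@data[rois@data != 0L])))
  L <- length(labs)
  if (!isTRUE(all.equal(targetCorr, t(targetCorr))) ||
      !isTRUE(all.equal(diag(targetCorr), rep(1, L))))
    stop("targetCorr must be symmetric with unit diagonal")
  ev <- eigen(targetCorr, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("targetCorr is not positive semi-definite")
  W <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), L, L)
  d <- rois@grid@dim
  .withSeed(seed, {
    out <- vector("list", nSubjects)
    for (s in seq_len(nSubjects)) {
      G <- matrix(stats::rnorm(nTimepoints * L), nTimepoints, L)
      courses <- G %*% t(W)   # T x L, population correlation targetCorr
      ts <- array(stats::rnorm(prod(d) * nTimepoints, 0, noiseSd),
                  c(d, nTimepoints))
      nv <- prod(d)
      for (li in seq_len(L)) {
        vox <- which(rois@data == labs[li])
        idx4 <- rep(vox, times = nTimepoints) +
          rep((seq_len(nTimepoints) - 1L) * nv, each = length(vox))
        ts[idx4] <- ts[idx4] + rep(courses[, li], each = length(vox))
      }
      attr(ts, "roiLabels") <- labs
      out[[s]] <- ts
    }
  })
  out
}

#' Generate a gene-by-voxel expression matrix with planted region effects
#'
#' Baseline expression is N(0, 1) per gene and voxel. A fraction of
#' genes is "affected": their mean differs between two designated
#' regions by \code{effectSdUnits} standard deviations (added to region
#' B's voxels). All other genes are exchangeable across regions.
#'
#' @param geometry a \linkS4class{LabeledVolume}; columns are its
#'   in-mask voxels in linearization order.
#' @param nGenes number of genes.
#' @param fracAffected proportion of genes with a planted effect.
#' @param effectSdUnits effect size in SD units.
#' @param regionA,regionB the designated parcel labels (defaults: the two
#'   smallest labels).
#' @param seed RNG seed.
#' @return list(\code{expr}: gene x voxel matrix; \code{affected}:
#'   affected gene indices; \code{voxelLabels}: parcel label per column;
#'   \code{regionA}, \code{regionB}).
#' @export
generateExpression <- function(geometry, nGenes = 100L, fracAffected = 0.2,
                               effectSdUnits = 0.5, regionA = NULL,
                               regionB = NULL, seed = 1L) {
  if (fracAffected < 0 || fracAffected > 1)
    stop("fracAffected must lie in [0, 1]")
  maskIdx <- which(geometry@data != 0L)
  voxelLabels <- as.integer(geometry@data[maskIdx])
  labs <- sort(unique(voxelLabels))
  if (is.null(regionA)) regionA <- labs[1]
  if (is.null(regionB)) regionB <- labs[2]
  nA <- round(nGenes * fracAffected)
  .withSeed(seed, {
    expr <- matrix(stats::rnorm(nGenes * length(maskIdx)),
                   nGenes, length(maskIdx))
    affected <- if (nA > 0) sort(sample.int(nGenes, nA)) else integer()
    if (length(affected))
      expr[affected, voxelLabels == regionB] <-
        expr[affected, voxelLabels == regionB] + effectSdUnits
  })
  list(expr = expr, affected = affected, voxelLabels = voxelLabels,
       regionA = regionA, regionB = regionB)
}

#' Generate a double-angle mapping FLASH signal pair from a known B1+ field
#'
#' With per-voxel actual flip angle \eqn{\theta = \alpha B1 / 100} (in
#' degrees, \eqn{\alpha} the nominal angle), the two acquisitions are
#' \eqn{A_1 = m_0 \sin\theta + \epsilon} and
#' \eqn{A_2 = m_0 \sin 2\theta + \epsilon}.
#'
#' @param b1Truth a \linkS4class{ScalarVolume} of B1+ in percent (> 0).
#' @param nominalAngle nominal flip angle of A1 in degrees (default 40,
#'   the lower of the 40/80-degree pair).
#' @param m0 signal scale.
#' @param noiseSd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return list(\code{A1}, \code{A2}: \linkS4class{ScalarVolume}s).
#' @export
generateDamPair <- function(b1Truth, nominalAngle = 40, m0 = 1,
                            noiseSd = 0, seed = 1L) {
  if (nominalAngle <= 0) stop("nominalAngle must be > 0")
  if (any(b1Truth@data[b1Truth@mask] <= 0))
    stop("b1Truth must be strictly positive in-mask")
  theta <- nominalAngle * pi / 180 * b1Truth@data / 100
  .withSeed(seed, {
    n <- prod(dim(theta))
    a1 <- m0 * sin(theta) +
      array(stats::rnorm(n, 0, noiseSd), dim(theta))
    a2 <- m0 * sin(2 * theta) +
      array(stats::rnorm(n, 0, noiseSd), dim(theta))
  })
  list(A1 = scalarVolume(a1, b1Truth@grid, b1Truth@mask),
       A2 = scalarVolume(a2, b1Truth@grid, b1Truth@mask))
}

#' Generate a synthetic perturbation-experiment table
#'
#' Emits one record per inactivation experiment with stereotaxic AP/ML
#' coordinates planted inside an assigned parcel (at the parcel map's
#' reference depth) and Bernoulli-drawn task descriptors matching the
#' database's prespecified categories.
#'
#' @param nPerParcel named integer vector: number of studies per parcel
#'   label (names are label ids as strings).
#' @param geometry a \linkS4class{LabeledVolume} in the
#'   stereotaxic-bregma frame.
#' @param categoryProbs optional list per parcel label of
#'   \code{list(taskType = c(sens, context, memory, other), pComplex,
#'   pMultiAction, pSimpleMove)}; defaults are uniform-ish.
#' @param refSlice 0-based z-slice at which coordinates are drawn
#'   (default: middle slice).
#' @param seed RNG seed.
#' @return data.frame of \code{study_id, AP, ML, task_type,
#'   complexity_index, n_actions, movement_complexity, n_mice,
#'   true_parcel}.
#' @export
generatePerturbationTable <- function(nPerParcel, geometry,
                                      categoryProbs = NULL,
                                      refSlice = NULL, seed = 1L) {
  if (geometry@grid@frame != "stereotaxic-bregma")
    stop("geometry must be in the stereotaxic-bregma frame")
  if (is.null(refSlice)) refSlice <- (geometry@grid@dim[3] - 1L) %/% 2L
  slice <- geometry@data[, , refSlice + 1L]
  defProbs <- list(taskType = c(0.4, 0.25, 0.25, 0.1), pComplex = 0.4,
                   pMultiAction = 0.4, pSimpleMove = 0.5)
  types <- c("sensorimotor transformation", "context/rule-based",
             "memory/delay", "other")
  recs <- list()
  .withSeed(seed, {
    sid <- 0L
    for (lab in names(nPerParcel)) {
      labi <- as.integer(lab)
      vox <- which(slice == labi, arr.ind = TRUE)
      if (!nrow(vox)) stop("parcel ", lab, " is empty at the reference slice")
      pr <- if (!is.null(categoryProbs[[lab]])) categoryProbs[[lab]] else defProbs
      for (i in seq_len(nPerParcel[[lab]])) {
        sid <- sid + 1L
        pick <- vox[sample.int(nrow(vox), 1L), ]
        w <- voxelToWorld(geometry@grid,
                          c(pick[1] - 1L, pick[2] - 1L, refSlice))
        jit <- stats::runif(2, -0.45, 0.45) * geometry@grid@voxelSize[1:2]
        cplx <- if (stats::runif(1) < pr$pComplex) stats::runif(1, 5.5, 9)
                else stats::runif(1, 1, 5)
        recs[[sid]] <- data.frame(
          study_id = sprintf("study%03d", sid),
          AP = w[1] + jit[1], ML = w[2] + jit[2],
          task_type = sample(types, 1L, prob = pr$taskType),
          complexity_index = cplx,
          n_actions = if (stats::runif(1) < pr$pMultiAction)
            sample(2:4, 1L) else 1L,
          movement_complexity = if (stats::runif(1) < pr$pSimpleMove) 1L
            else sample(2:3, 1L),
          n_mice = sample(4:12, 1L),
          true_parcel = labi,
          stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, recs)
}
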