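# Helpers shared by fingerprint operations -----------------------------------

# view a 4D (x,y,z,t) array as voxels x time
.tsMatrix <- function(ts) {
  d <- dim(ts)
  matrix(ts, prod(d[1:3]), d[4])
}

# resolve targets into a named list of linear voxel-index vectors
.targetIndices <- function(targets) {
  if (is(targets, "LabeledVolume")) {
    labs <- sort(unique(as.integer(targets@data[targets@data != 0L])))
    out <- lapply(labs, function(l) which(targets@data == l))
    names(out) <- unname(targets@labelNames[as.character(labs)])
    return(out)
  }
  out <- lapply(targets, function(t) {
    if (is(t, "LabeledVolume")) which(t@data != 0L) else which(t)
  })
  if (is.null(names(out)) || any(!nzchar(names(out))))
    names(out) <- paste0("target", seq_along(out))
  out
}

.meanCourse <- function(tsm, vox) {
  if (length(vox) == 1L) tsm[vox, ] else colMeans(tsm[vox, , drop = FALSE])
}

.safeCorAll <- function(x, courses) {
  bad <- stats::sd(x) == 0 | apply(courses, 2, stats::sd) == 0
  r <- rep(0, ncol(courses))
  if (any(!bad))
    r[!bad] <- as.numeric(stats::cor(x, courses[, !bad, drop = FALSE]))
  if (any(bad))
    warning(sum(bad), " zero-variance time course(s); correlation set to 0")
  stats::setNames(r, colnames(courses))
}

#' Connectivity fingerprint of a seed region
#'
#' Pearson correlation between the seed's mean time course and each
#' target's mean time course, in target order. Fingerprints are named
#' numeric vectors over the target panel (see
#' \code{\link{defaultTargets}}).
#'
#' @param ts 4D (x, y, z, t) time-series array.
#' @param seedRoi a \linkS4class{LabeledVolume} or logical array marking
#'   the seed voxels.
#' @param targets a multi-label \linkS4class{LabeledVolume} (targets in
#'   ascending label order) or a named list of ROIs.
#' @return named numeric fingerprint.
#' @export
roiFingerprint <- function(ts, seedRoi, targets) {
  tsm <- .tsMatrix(ts)
  seedVox <- if (is(seedRoi, "LabeledVolume")) which(seedRoi@data != 0L)
             else which(seedRoi)
  if (!length(seedVox)) stop("seed ROI is empty")
  tIdx <- .targetIndices(targets)
  if (!all(lengths(tIdx) > 0)) stop("empty target ROI")
  seedCourse <- .meanCourse(tsm, seedVox)
  courses <- vapply(tIdx, function(v) .meanCourse(tsm, v),
                    numeric(ncol(tsm)))
  .safeCorAll(seedCourse, courses)
}

#' @rdname roiFingerprint
#' @param voxel 0-based voxel index triple (single-voxel seed).
#' @export
voxelFingerprint <- function(ts, voxel, targets) {
  d <- dim(ts)[1:3]
  sel <- array(FALSE, d)
  sel[voxel[1] + 1L, voxel[2] + 1L, voxel[3] + 1L] <- TRUE
  roiFingerprint(ts, sel, targets)
}

#' Template fingerprint: elementwise median across subjects
#'
#' @param fps a targets x subjects matrix, or a list of equally named
#'   fingerprints.
#' @return named numeric fingerprint (for an even subject count, the
#'   mean of the two middle values per target).
#' @export
templateFingerprint <- function(fps) {
  if (is.list(fps)) {
    nms <- names(fps[[1]])
    if (!all(vapply(fps, function(f) identical(names(f), nms), logical(1))))
      stop("fingerprints have mismatched target lists")
    fps <- do.call(cbind, fps)
  }
  apply(fps, 1, stats::median)
}

#' Correlate fingerprints against a template
#'
#' Row-wise Pearson correlation of a voxel x target fingerprint matrix
#' with a template fingerprint; constant fingerprints correlate 0 with a
#' warning. \code{z} is the Fisher transform with r clipped to
#' +/- (1 - 1e-6) to avoid infinities.
#'
#' @param fpMatrix numeric matrix, voxels x targets.
#' @param template numeric template fingerprint (same target order).
#' @return list(\code{r}, \code{z}) numeric vectors.
#' @export
matchFingerprints <- function(fpMatrix, template) {
  fpMatrix <- as.matrix(fpMatrix)
  if (ncol(fpMatrix) < 3L) stop("need at least 3 targets")
  if (ncol(fpMatrix) != length(template))
    stop("fingerprint and template lengths differ")
  constRows <- apply(fpMatrix, 1, function(x) stats::sd(x) == 0)
  if (any(constRows))
    warning(sum(constRows), " constant fingerprint(s); r set to 0")
  tpl <- matrix(template, nrow(fpMatrix), length(template), byrow = TRUE)
  r <- .rowCor(fpMatrix, tpl)
  r[constRows] <- 0
  list(r = r, z = .fisherZ(r))
}

#' Voxelwise fingerprint-match maps for one subject
#'
#' Extracts a connectivity fingerprint for every in-mask voxel of a
#' subject's scan, correlates it with the (mouse) template fingerprint
#' across targets, and assigns the correlation to the voxel; z is the
#' Fisher r-to-Z transform.
#'
#' @param ts 4D time-series array.
#' @param template named template fingerprint.
#' @param targets target ROIs (as in \code{\link{roiFingerprint}}).
#' @param mask logical array of voxels to map.
#' @return list(\code{r}, \code{z}: 3D arrays, 0 outside the mask).
#' @export
matchMap <- function(ts, template, targets, mask) {
  d <- dim(ts)[1:3]
  tsm <- .tsMatrix(ts)
  vox <- which(mask)
  tIdx <- .targetIndices(targets)
  if (length(tIdx) < 3L) stop("need at least 3 targets")
  courses <- vapply(tIdx, function(v) .meanCourse(tsm, v),
                    numeric(dim(ts)[4]))       # T x L
  fp <- suppressWarnings(stats::cor(t(tsm[vox, , drop = FALSE]), courses))
  fp[!is.finite(fp)] <- 0                      # zero-variance voxels
  mm <- matchFingerprints(fp, template[colnames(fp)])
  rArr <- array(0, d); zArr <- array(0, d)
  rArr[vox] <- mm$r
  zArr[vox] <- mm$z
  list(r = rArr, z = zArr)
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Integrates cluster extent over thresholds: each voxel accumulates
#' \eqn{e(h)^E h^H \, dh} where e(h) is the size of its suprathreshold
#' 6-connected component at height h. Conventional parameters E = 0.5,
#' H = 2, dh = 0.1.
#'
#' @param stat 3D statistic array (only positive values are enhanced).
#' @param mask logical array.
#' @param E,H,dh TFCE parameters.
#' @return 3D array of TFCE scores.
#' @export
tfceScore <- function(stat, mask, E = 0.5, H = 2, dh = 0.1) {
  out <- array(0, dim(stat))
  mx <- max(stat[mask], 0)
  if (mx <= 0) return(out)
  hs <- seq(dh, mx, by = dh)
  for (h in hs) {
    fg <- mask & stat >= h
    if (!any(fg)) break
    comp <- .labelComponents(fg)
    sizes <- tabulate(comp[comp > 0L])
    inc <- sizes[comp[fg]]^E * h^H * dh
    out[fg] <- out[fg] + inc
  }
  out
}

#' Group one-sample permutation inference on subject maps
#'
#' One-sample t per voxel across subjects, with the null built by random
#' sign-flipping of whole subject maps and family-wise error control via
#' the distribution of the image-wise maximum statistic (max t, or max
#' TFCE score with \code{method = "tfce"}). With 12 or fewer subjects
#' all 2^n sign flips are enumerated exactly; otherwise \code{nPerm}
#' random flips are drawn and p = (b + 1) / (nPerm + 1). Inference is
#' one-sided (positive), since only positive fingerprint similarity is
#' meaningful for assignment.
#'
#' @param zMaps list of per-subject 3D arrays (e.g. Fisher-z match maps).
#' @param mask logical array of voxels to test.
#' @param nPerm number of random sign flips (default 1000).
#' @param alpha FWE level for \code{sigMask} (default 0.05).
#' @param method \code{"maxstat"} (default) or \code{"tfce"}.
#' @param seed RNG seed.
#' @param E,H,dh TFCE parameters (used when \code{method = "tfce"}).
#' @param exhaustive override the automatic choice between exact
#'   enumeration and random sampling (default \code{NULL}: exact when
#'   n <= 12).
#' @return list(\code{tMap}, \code{pFweMap}, \code{sigMask}) arrays; p is
#'   1 outside the mask.
#' @export
groupOnesamplePerm <- function(zMaps, mask, nPerm = 1000L, alpha = 0.05,
                               method = c("maxstat", "tfce"), seed = 1L,
                               E = 0.5, H = 2, dh = 0.1,
                               exhaustive = NULL) {
  method <- match.arg(method)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  n <- length(zMaps)
  if (n < 2L) stop("need at least 2 subjects")
  vox <- which(mask)
  X <- matrix(vapply(zMaps, function(m) m[vox], numeric(length(vox))),
              ncol = n)
  X <- t(X)                                                        # n x V
  d <- dim(mask)
  tStat <- function(xs) {
    mu <- colMeans(xs)
    sd <- sqrt(colSums(sweep(xs, 2, mu)^2) / (n - 1))
    tt <- numeric(length(mu))
    ok <- sd > 0
    tt[ok] <- mu[ok] / (sd[ok] / sqrt(n))
    tt
  }
  imageStat <- function(tv) {
    if (method == "maxstat") return(max(tv))
    arr <- array(0, d); arr[vox] <- tv
    max(tfceScore(arr, mask, E, H, dh)[mask])
  }
  voxelScore <- function(tv) {
    if (method == "maxstat") return(tv)
    arr <- array(0, d); arr[vox] <- tv
    tfceScore(arr, mask, E, H, dh)[vox]
  }
  tObs <- tStat(X)
  scoreObs <- voxelScore(tObs)
  if (is.null(exhaustive)) exhaustive <- n <= 12L
  if (exhaustive) {
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    nullMax <- apply(flips, 1, function(s) imageStat(tStat(X * s)))
    pFwe <- vapply(scoreObs, function(v) mean(nullMax >= v), numeric(1))
  } else {
    nullMax <- .withSeed(seed, vapply(seq_len(nPerm), function(b) {
      s <- sample(c(1, -1), n, replace = TRUE)
      imageStat(tStat(X * s))
    }, numeric(1)))
    pFwe <- vapply(scoreObs,
                   function(v) (sum(nullMax >= v) + 1) / (nPerm + 1),
                   numeric(1))
  }
  tMap <- array(0, d); tMap[vox] <- tObs
  pMap <- array(1, d); pMap[vox] <- pFwe
  sig <- array(FALSE, d); sig[vox] <- pFwe <= alpha
  list(tMap = tMap, pFweMap = pMap, sigMask = sig,
       exhaustive = exhaustive)
}

#' Similarity maps for one mouse seed across human subjects
#'
#' Convenience wrapper: per-subject \code{\link{matchMap}} against the
#' seed's template fingerprint, then group sign-flip permutation
#' inference on the Fisher-z maps.
#'
#' @param tsList list of per-subject 4D arrays.
#' @param template named template fingerprint for the seed.
#' @param targets target ROIs.
#' @param mask analysis mask.
#' @param seedName seed area name.
#' @param ... passed to \code{\link{groupOnesamplePerm}}.
#' @return A \linkS4class{SimilarityMaps}.
#' @export
similarityMaps <- function(tsList, template, targets, mask,
                           seedName = "seed", ...) {
  maps <- lapply(tsList, matchMap, template = template, targets = targets,
                 mask = mask)
  zMaps <- lapply(maps, `[[`, "z")
  grp <- groupOnesamplePerm(zMaps, mask, ...)
  new("SimilarityMaps", seedName = seedName,
      rMaps = lapply(maps, `[[`, "r"), zMaps = zMaps,
      tMap = grp$tMap, pFweMap = grp$pFweMap, sigMask = grp$sigMask,
      mask = mask)
}

#' Manhattan-distance permutation test between two groups of profiles
#'
#' The statistic is the L1 distance between the two groups' mean feature
#' vectors; the null permutes unit-to-group labels (10,000 permutations
#' by default). When the total number of distinct label assignments is
#' at most 20,000 the permutation distribution is enumerated exactly;
#' otherwise p = (b + 1) / (nPerm + 1). The exchangeable unit is
#' whatever the rows are (voxels for expression/myelin region profiles,
#' subjects for fingerprint comparisons).
#'
#' @param a,b unit x feature matrices with identical feature columns.
#' @param nPerm number of label permutations (default 10000).
#' @param seed RNG seed.
#' @return list(\code{distance}, \code{p}, \code{exhaustive}).
#' @export
manhattanPermTest <- function(a, b, nPerm = 10000L, seed = 1L) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("feature columns differ between groups")
  if (nrow(a) < 2L || nrow(b) < 2L) stop("need >= 2 units per group")
  x <- rbind(a, b)
  nA <- nrow(a); nTot <- nrow(x)
  isA <- c(rep(TRUE, nA), rep(FALSE, nTot - nA))
  obs <- sum(.manhattanStat(x, isA))
  nComb <- choose(nTot, nA)
  if (nComb <= 20000) {
    combs <- utils::combn(nTot, nA)
    nullD <- apply(combs, 2, function(sel) {
      ind <- seq_len(nTot) %in% sel
      sum(.manhattanStat(x, ind))
    })
    p <- mean(nullD >= obs)   # exact: includes the observed labeling
    exhaustive <- TRUE
  } else {
    nullD <- .withSeed(seed, vapply(seq_len(nPerm), function(i) {
      ind <- seq_len(nTot) %in% sample.int(nTot, nA)
      sum(.manhattanStat(x, ind))
    }, numeric(1)))
    p <- (sum(nullD >= obs) + 1) / (nPerm + 1)
    exhaustive <- FALSE
  }
  list(distance = obs, p = p, exhaustive = exhaustive)
}
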