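#' Winner-take-all cross-species assignment
#'
#' Assigns each in-mask voxel to the candidate (mouse) area whose
#' fingerprint-match t statistic is largest at that voxel. Exact ties
#' break to the first area in the supplied map order (the tie count is
#' logged). When per-area significance masks are supplied, voxels
#' significant for no area are labeled \code{"unassigned"} (label 0 is
#' still background outside the mask, so \code{"unassigned"} receives
#' its own label).
#'
#' @param tMaps named list of 3D t-statistic arrays (or
#'   \linkS4class{SimilarityMaps}, whose \code{tMap}/\code{sigMask} are
#'   used), all on one grid.
#' @param mask logical array over which to assign.
#' @param sigMasks optional named list of logical arrays enabling the
#'   significance-restricted mode; by default every in-mask voxel is
#'   assigned.
#' @param restrictToSignificant when the inputs are
#'   \linkS4class{SimilarityMaps}, set \code{TRUE} to use their
#'   \code{sigMask}s (supplementary-style restricted map).
#' @param grid optional \linkS4class{VolumeGrid} for the output labels.
#' @return list(\code{labels}: a \linkS4class{LabeledVolume} with the
#'   area names plus \code{"unassigned"}; \code{sourceT}: winning t per
#'   voxel; \code{nTies}: number of tied voxels).
#' @export
winnerTakeAll <- function(tMaps, mask, sigMasks = NULL,
                          restrictToSignificant = FALSE, grid = NULL) {
  if (length(tMaps) < 2L) stop("need at least 2 t maps")
  if (all(vapply(tMaps, is, logical(1), "SimilarityMaps"))) {
    if (restrictToSignificant && is.null(sigMasks))
      sigMasks <- lapply(tMaps, function(s) s@sigMask)
    tMaps <- lapply(tMaps, function(s) s@tMap)
  }
  d <- dim(tMaps[[1]])
  for (m in tMaps) if (!identical(dim(m), d)) stop("t maps differ in grid")
  areaNames <- names(tMaps)
  if (is.null(areaNames)) areaNames <- paste0("area", seq_along(tMaps))
  vox <- which(mask)
  T <- vapply(tMaps, function(m) m[vox], numeric(length(vox)))
  T <- matrix(T, nrow = length(vox))
  win <- max.col(T, ties.method = "first")
  best <- T[cbind(seq_len(nrow(T)), win)]
  nTies <- sum(rowSums(T == best) > 1L)
  if (nTies > 0)
    message("winnerTakeAll: ", nTies,
            " tied voxel(s) assigned to the first area in order")
  if (!is.null(sigMasks)) {
    sigAny <- Reduce(`|`, lapply(sigMasks, function(s) s[vox]))
    win[!sigAny] <- length(areaNames) + 1L
    areaNames <- c(areaNames, "unassigned")
  }
  lab <- array(0L, d)
  lab[vox] <- win
  tArr <- array(0, d)
  tArr[vox] <- best
  if (is.null(grid)) grid <- volumeGrid(d, c(1, 1, 1), "mni-like")
  list(labels = labeledVolume(lab, grid,
         stats::setNames(areaNames, seq_along(areaNames))),
       sourceT = tArr, nTies = nTies)
}

#' Normalize a fingerprint into a probability distribution
#'
#' KL divergence requires strictly positive distributions; fingerprints
#' (correlations or normalized weights) are shifted by their minimum,
#' offset by \code{epsilon}, and divided by the sum. A constant
#' fingerprint maps to the uniform distribution.
#'
#' @param fp numeric fingerprint.
#' @param epsilon positivity offset (default 1e-6).
#' @return numeric probability vector summing to 1.
#' @export
fingerprintToDistribution <- function(fp, epsilon = 1e-6) {
  if (length(fp) < 2L) stop("need at least 2 targets")
  p <- fp - min(fp) + epsilon
  p / sum(p)
}

#' Symmetrized Kullback-Leibler divergence matrix between areas
#'
#' Each area's fingerprint is normalized via
#' \code{\link{fingerprintToDistribution}}; the divergence is the
#' symmetrized KL
#' \deqn{D(i,j) = \tfrac12 [KL(p_i \| p_j) + KL(p_j \| p_i)]}
#' yielding a symmetric non-negative matrix with zero diagonal.
#'
#' @param fps named list of fingerprints (common target order) or an
#'   area x target matrix.
#' @param epsilon passed to \code{\link{fingerprintToDistribution}}.
#' @param normalize set \code{FALSE} when the rows already are strictly
#'   positive probability vectors (skips the shift-and-offset step).
#' @return symmetric numeric matrix with area dimnames.
#' @export
klMatrix <- function(fps, epsilon = 1e-6, normalize = TRUE) {
  if (is.list(fps)) {
    nms <- names(fps[[1]])
    if (!is.null(nms) &&
        !all(vapply(fps, function(f) identical(names(f), nms), logical(1))))
      stop("fingerprints have mismatched target lists")
    fps <- do.call(rbind, fps)
  }
  P <- if (normalize)
    t(apply(fps, 1, fingerprintToDistribution, epsilon = epsilon))
  else {
    if (any(fps <= 0)) stop("normalize = FALSE requires positive rows")
    fps / rowSums(fps)
  }
  n <- nrow(P)
  D <- matrix(0, n, n, dimnames = list(rownames(fps), rownames(fps)))
  kl <- function(p, q) sum(p * log(p / q))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <-
        0.5 * (kl(P[i, ], P[j, ]) + kl(P[j, ], P[i, ]))
    }
  }
  D
}

#' 2D spectral embedding of a divergence matrix
#'
#' Laplacian eigenmaps: affinity \eqn{A = \exp(-D / s)} with s the
#' median off-diagonal divergence by default, then the eigenvectors of
#' the symmetric normalized graph Laplacian belonging to the 2nd and 3rd
#' smallest eigenvalues give the 2D coordinates. Signs are fixed by
#' making the first nonzero loading of each axis positive. Areas with
#' identical fingerprints land on coincident points.
#'
#' @param d symmetric divergence matrix (>= 3 areas).
#' @param kernelScale positive scale or \code{"median"} (default).
#' @return list(\code{coords}: area x 2 matrix; \code{eigenvalues}: the
#'   two Laplacian eigenvalues used; \code{kernelScale}).
#' @export
spectralEmbed <- function(d, kernelScale = "median") {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 areas")
  off <- d[upper.tri(d)]
  if (identical(kernelScale, "median")) {
    kernelScale <- stats::median(off)
    if (kernelScale <= 0) {
      warning("degenerate divergence matrix; all areas embedded at one point")
      coords <- matrix(0, n, 2, dimnames = list(rownames(d), c("x", "y")))
      return(list(coords = coords, eigenvalues = c(0, 0),
                  kernelScale = NA_real_))
    }
  }
  A <- exp(-d / kernelScale)
  diag(A) <- 0
  deg <- rowSums(A)
  if (any(deg <= 0)) stop("isolated area in affinity graph")
  iS <- 1 / sqrt(deg)
  L <- diag(n) - (iS * A) * rep(iS, each = n)   # I - D^-1/2 A D^-1/2
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- order(ev$values)                       # ascending
  vecs <- ev$vectors[, ord[2:3], drop = FALSE]
  for (j in 1:2) {
    nz <- which(abs(vecs[, j]) > 1e-12)[1]
    if (!is.na(nz) && vecs[nz, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(rownames(d), c("x", "y"))
  list(coords = vecs, eigenvalues = ev$values[ord[2:3]],
       kernelScale = kernelScale)
}

#' Restrict fingerprints to a subset of targets
#'
#' Drops the named targets from every fingerprint, preserving the order
#' of the remaining ones (used e.g. to repeat the embedding without V1
#' and A1).
#'
#' @param fps named list of fingerprints or an area x target matrix with
#'   column names.
#' @param drop character vector of target names to remove.
#' @return same shape as \code{fps}, restricted.
#' @export
leaveOutTargets <- function(fps, drop) {
  if (!length(drop)) return(fps)
  nms <- if (is.list(fps)) names(fps[[1]]) else colnames(fps)
  if (!all(drop %in% nms))
    stop("unknown target name(s): ",
         paste(setdiff(drop, nms), collapse = ", "))
  keep <- setdiff(nms, drop)
  if (length(keep) < 3L) stop("fewer than 3 targets would remain")
  if (is.list(fps)) lapply(fps, function(f) f[keep])
  else fps[, keep, drop = FALSE]
}
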