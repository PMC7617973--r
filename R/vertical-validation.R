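#' Voxelwise correlation between two connectivity modalities
#'
#' For each in-mask voxel, the Pearson correlation (and two-sided p via
#' the exact t transform, df = features - 2) between its tracer-based
#' and fMRI-based connectivity profiles across the shared feature space.
#' Constant profiles yield r = 0, p = 1 with a warning.
#'
#' @param tracerConn,fmriConn voxel x feature matrices or
#'   \linkS4class{ConnectivityMatrix} objects with matching rows and
#'   features (>= 4 features).
#' @return list(\code{r}, \code{p}: per-voxel vectors; \code{rMap},
#'   \code{pMap}: 3D arrays when a grid is available).
#' @export
voxelwiseModalCorrelation <- function(tracerConn, fmriConn) {
  a <- .asMatrix(tracerConn); b <- .asMatrix(fmriConn)
  if (!all(dim(a) == dim(b))) stop("matrices must match in rows and features")
  if (ncol(a) < 4L) stop("need at least 4 features")
  constRows <- apply(a, 1, stats::sd) == 0 | apply(b, 1, stats::sd) == 0
  if (any(constRows))
    warning(sum(constRows), " constant profile(s); r = 0, p = 1")
  r <- .rowCor(a, b)
  p <- .corPval(r, ncol(a))
  r[constRows] <- 0
  p[constRows] <- 1
  out <- list(r = r, p = p)
  if (is(tracerConn, "ConnectivityMatrix")) {
    d <- tracerConn@grid@dim
    rMap <- array(0, d); pMap <- array(1, d)
    rMap[tracerConn@voxelIdx] <- r
    pMap[tracerConn@voxelIdx] <- p
    out$rMap <- rMap; out$pMap <- pMap
  }
  out
}

#' Conservative null for the tracer-fMRI bridge
#'
#' Correlates in-network fMRI connectivity profiles with tracer profiles
#' drawn at random from voxels outside the network — a mismatched
#' pairing whose correlations should center on zero. Outside voxels are
#' sampled without replacement until the pool is exhausted, then with
#' replacement (logged).
#'
#' @param fmriConnIn in-network voxel x feature matrix (or
#'   \linkS4class{ConnectivityMatrix}).
#' @param tracerConnOut outside-network voxel x feature matrix.
#' @param nDraws number of null pairs (default: one per in-network
#'   voxel).
#' @param seed RNG seed.
#' @return numeric vector of null correlation coefficients.
#' @export
conservativeNull <- function(fmriConnIn, tracerConnOut, nDraws = NULL,
                             seed = 1L) {
  a <- .asMatrix(fmriConnIn); pool <- .asMatrix(tracerConnOut)
  if (!nrow(pool)) stop("outside-network pool is empty")
  if (ncol(a) != ncol(pool)) stop("feature spaces differ")
  if (is.null(nDraws)) nDraws <- nrow(a)
  .withSeed(seed, {
    inSel <- rep_len(seq_len(nrow(a)), nDraws)
    nFull <- nDraws %/% nrow(pool)
    rem <- nDraws %% nrow(pool)
    outSel <- integer(0)
    for (i in seq_len(nFull)) outSel <- c(outSel, sample.int(nrow(pool)))
    if (rem > 0) outSel <- c(outSel, sample.int(nrow(pool), rem))
    if (nFull >= 1L && nDraws > nrow(pool))
      message("conservativeNull: outside pool exhausted; ",
              "continuing with replacement")
  })
  .rowCor(a[inSel, , drop = FALSE], pool[outSel, , drop = FALSE])
}

#' Two-sample Kolmogorov-Smirnov comparison of r distributions
#'
#' @param realR,nullR numeric samples (>= 2 each).
#' @return list(\code{ks_stat}, \code{ks_p}) from the asymptotic
#'   two-sample test.
#' @export
ksCompare <- function(realR, nullR) {
  if (length(realR) < 2L || length(nullR) < 2L)
    stop("both samples need >= 2 values")
  kt <- suppressWarnings(stats::ks.test(realR, nullR))
  list(ks_stat = unname(kt$statistic), ks_p = kt$p.value)
}

#' Mean expression of each gene per region
#'
#' Averages a gene x voxel expression matrix over the voxels of each
#' labeled region; voxel columns must follow the label volume's mask
#' linearization (ascending linear index). The resulting region x gene
#' profiles feed \code{\link{manhattanPermTest}} for pairwise region
#' comparisons.
#'
#' @param expr gene x voxel matrix.
#' @param labels a \linkS4class{LabeledVolume}, or an integer vector of
#'   per-column region labels.
#' @return region x gene matrix of means (rownames = region names).
#' @export
regionExpressionProfile <- function(expr, labels) {
  if (is(labels, "LabeledVolume")) {
    nm <- labels@labelNames
    labels <- labels@data[labels@data != 0L]  # mask linearization order
  } else nm <- NULL
  labels <- as.integer(labels)
  if (length(labels) != ncol(expr))
    stop("label count does not match expression columns")
  labs <- sort(unique(labels))
  out <- t(vapply(labs, function(l) {
    sel <- labels == l
    if (!any(sel)) stop("empty region ", l)
    rowMeans(expr[, sel, drop = FALSE])
  }, numeric(nrow(expr))))
  rownames(out) <- if (!is.null(nm)) unname(nm[as.character(labs)])
                   else as.character(labs)
  out
}

#' Double-angle B1+ map from a FLASH signal pair
#'
#' Estimates the transmit field as a percentage of nominal flip angle:
#' \deqn{B1^+ = \frac{180/\pi}{\alpha_1} \arccos\!\left(\frac{A_2}{2 A_1}\right) \times 100}
#' with \eqn{\alpha_1} the nominal angle of the lower-flip-angle scan
#' (40 degrees for the 40/80-degree pair). The arccos argument is
#' clamped to [-1, 1] (noise can push it past 1); the clamp count is
#' reported as a QC message. Voxels with A1 <= 0 are masked out with a
#' warning.
#'
#' @param A1,A2 \linkS4class{ScalarVolume}s (lower/higher flip angle).
#' @param nominalAngle nominal flip angle of A1 in degrees (default 40).
#' @return A \linkS4class{ScalarVolume} of B1+ in percent.
#' @export
damB1Map <- function(A1, A2, nominalAngle = 40) {
  if (nominalAngle <= 0) stop("nominalAngle must be > 0")
  if (!identical(dim(A1@data), dim(A2@data))) stop("grids differ")
  mask <- A1@mask & A2@mask
  bad <- mask & A1@data <= 0
  if (any(bad)) {
    warning(sum(bad), " voxel(s) with A1 <= 0 masked out")
    mask <- mask & !bad
  }
  ratio <- array(0, dim(A1@data))
  ratio[mask] <- A2@data[mask] / (2 * A1@data[mask])
  nClamp <- sum(abs(ratio[mask]) > 1)
  if (nClamp > 0)
    message("damB1Map: clamped arccos argument at ", nClamp, " voxel(s)")
  ratio <- pmin(pmax(ratio, -1), 1)
  b1 <- array(0, dim(A1@data))
  b1[mask] <- (180 / pi) / nominalAngle * acos(ratio[mask]) * 100
  scalarVolume(b1, A1@grid, mask)
}

#' Paired t-test of ROI means across subjects
#'
#' For each subject, the mean map value in each of two ROIs; a paired
#' two-sided t-test on the differences (the standard comparison of
#' myelin markers between two regions).
#'
#' @param maps list of per-subject \linkS4class{ScalarVolume}s or 3D
#'   arrays.
#' @param roiA,roiB \linkS4class{LabeledVolume}s or logical arrays.
#' @return list(\code{t}, \code{p}, \code{meansA}, \code{meansB});
#'   \code{t}/\code{p} are \code{NA} when the differences have zero
#'   variance.
#' @export
roiPairedTtest <- function(maps, roiA, roiB) {
  if (length(maps) < 2L) stop("need at least 2 subjects")
  vA <- if (is(roiA, "LabeledVolume")) which(roiA@data != 0L) else which(roiA)
  vB <- if (is(roiB, "LabeledVolume")) which(roiB@data != 0L) else which(roiB)
  if (!length(vA) || !length(vB)) stop("both ROIs must be nonempty")
  arrOf <- function(m) if (is(m, "ScalarVolume")) m@data else m
  meansA <- vapply(maps, function(m) mean(arrOf(m)[vA]), numeric(1))
  meansB <- vapply(maps, function(m) mean(arrOf(m)[vB]), numeric(1))
  diffs <- meansA - meansB
  if (stats::sd(diffs) == 0) {
    if (all(diffs == 0))
      return(list(t = 0, p = 1, meansA = meansA, meansB = meansB))
    return(list(t = NA_real_, p = NA_real_, meansA = meansA,
                meansB = meansB))
  }
  tt <- stats::t.test(meansA, meansB, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, meansA = meansA,
       meansB = meansB)
}

#' Assign perturbation experiments to parcels by stereotaxic coordinates
#'
#' Each record's (AP, ML) is evaluated at the parcel map's reference
#' depth; the record gets the label of the containing parcel, or
#' \code{"unassigned"} when the coordinate falls outside the grid or on
#' background (strict containment, no nearest-neighbor snapping).
#'
#' @param records data.frame with \code{AP} and \code{ML} columns (mm
#'   from bregma).
#' @param parcelMap a \linkS4class{LabeledVolume} in the
#'   stereotaxic-bregma frame.
#' @param refSlice 0-based z-slice used as the reference depth
#'   (default: middle slice).
#' @return \code{records} with added \code{parcel} (name) and
#'   \code{parcel_label} (integer; 0 = unassigned) columns.
#' @export
assignExperiments <- function(records, parcelMap, refSlice = NULL) {
  if (parcelMap@grid@frame != "stereotaxic-bregma")
    stop("parcel map must be in the stereotaxic-bregma frame")
  if (!all(c("AP", "ML") %in% names(records)))
    stop("records must have AP and ML columns")
  if (any(!is.finite(records$AP)) || any(!is.finite(records$ML)))
    stop("malformed coordinates")
  if (is.null(refSlice)) refSlice <- (parcelMap@grid@dim[3] - 1L) %/% 2L
  dv <- voxelToWorld(parcelMap@grid, c(0, 0, refSlice))[3]
  lab <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    v <- worldToVoxel(parcelMap@grid, c(records$AP[i], records$ML[i], dv))
    lab[i] <- if (.inGrid(parcelMap@grid, v))
      parcelMap@data[v[1] + 1L, v[2] + 1L, v[3] + 1L] else 0L
  }
  nOut <- sum(lab == 0L)
  if (nOut > 0)
    message("assignExperiments: ", nOut, " record(s) unassigned")
  records$parcel_label <- lab
  records$parcel <- ifelse(lab == 0L, "unassigned",
                           unname(parcelMap@labelNames[as.character(lab)]))
  records
}

#' Tabulate task features per parcel
#'
#' For each parcel, the percentage of its studies meeting each of the
#' six prespecified categories: the three task types (sensorimotor
#' transformation; context/rule-based; memory/delay), complexity index
#' strictly above 5, number of actions strictly above 1, and movement
#' complexity equal to 1. \code{normalized} rescales each category to
#' [0, 1] across parcels (radar-plot convention).
#'
#' @param assigned output of \code{\link{assignExperiments}} (records
#'   with a \code{parcel} column); unassigned records are dropped.
#' @return list(\code{percent}, \code{normalized}: parcel x category
#'   matrices; \code{n}: studies per parcel).
#' @export
tabulateTaskFeatures <- function(assigned) {
  assigned <- assigned[assigned$parcel != "unassigned", , drop = FALSE]
  if (!nrow(assigned)) stop("no assigned records")
  cats <- c("sensorimotor", "context", "memory", "complexity",
            "multi_action", "simple_movement")
  parcels <- unique(assigned$parcel)
  pct <- matrix(0, length(parcels), length(cats),
                dimnames = list(parcels, cats))
  n <- integer(length(parcels))
  for (i in seq_along(parcels)) {
    g <- assigned[assigned$parcel == parcels[i], ]
    n[i] <- nrow(g)
    pct[i, ] <- 100 * c(
      mean(g$task_type == "sensorimotor transformation"),
      mean(g$task_type == "context/rule-based"),
      mean(g$task_type == "memory/delay"),
      mean(g$complexity_index > 5),      # strictly above 5
      mean(g$n_actions > 1),             # strictly above 1
      mean(g$movement_complexity == 1))  # equal to 1
  }
  norm <- apply(pct, 2, function(col) {
    if (max(col) > 0) col / max(col) else col
  })
  norm <- matrix(norm, nrow(pct), dimnames = dimnames(pct))
  list(percent = pct, normalized = norm,
       n = stats::setNames(n, parcels))
}
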