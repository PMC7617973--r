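#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based triples; world coordinates are mm in the
#' grid's frame. \code{worldToVoxel} returns the nearest voxel;
#' \code{worldToVoxelContinuous} the unrounded position.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param voxel 0-based voxel index triple.
#' @param world world coordinate triple (mm).
#' @return numeric triple.
#' @export
voxelToWorld <- function(grid, voxel) {
  as.numeric(grid@affine %*% c(as.numeric(voxel), 1))[1:3]
}

#' @rdname voxelToWorld
#' @export
worldToVoxelContinuous <- function(grid, world) {
  as.numeric(solve(grid@affine) %*% c(as.numeric(world), 1))[1:3]
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(grid, world) {
  as.integer(round(worldToVoxelContinuous(grid, world)))
}

.inGrid <- function(grid, voxel) {
  all(voxel >= 0) && all(voxel <= grid@dim - 1L)
}

#' Map stereotaxic bregma coordinates to the nearest voxel
#'
#' The grid frame must be \code{"stereotaxic-bregma"}; world axes are read
#' as (AP, ML, DV) mm from bregma. \code{voxelToStereotaxic} is the
#' inverse and round-trips within half a voxel.
#'
#' @param coords numeric (AP, ML, DV) in mm from bregma.
#' @param grid a \linkS4class{VolumeGrid} in the stereotaxic frame.
#' @param voxel 0-based voxel index triple.
#' @return \code{stereotaxicToVoxel}: integer voxel triple;
#'   \code{voxelToStereotaxic}: numeric (AP, ML, DV).
#' @export
stereotaxicToVoxel <- function(coords, grid) {
  if (grid@frame != "stereotaxic-bregma")
    stop("grid frame must be 'stereotaxic-bregma', got '", grid@frame, "'")
  v <- worldToVoxel(grid, coords)
  if (!.inGrid(grid, v))
    stop("coordinate (", paste(coords, collapse = ", "), ") is outside the grid")
  v
}

#' @rdname stereotaxicToVoxel
#' @export
voxelToStereotaxic <- function(voxel, grid) {
  if (grid@frame != "stereotaxic-bregma")
    stop("grid frame must be 'stereotaxic-bregma', got '", grid@frame, "'")
  voxelToWorld(grid, voxel)
}

.sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a volume to NIfTI-1 with a JSON sidecar
#'
#' The sidecar records the coordinate frame, the exact affine (NIfTI
#' headers store transforms in single precision), the volume kind, label
#' names for \linkS4class{LabeledVolume}s, and the mask (as linear
#' indices) when it is not all-\code{TRUE}.
#'
#' @param v a \linkS4class{ScalarVolume} or \linkS4class{LabeledVolume}.
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(v, path) {
  isLab <- is(v, "LabeledVolume")
  dat <- v@data
  img <- RNifti::asNifti(dat)
  img <- RNifti::`sform<-`(img, structure(v@grid@affine, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (isLab) "int32" else "double")
  side <- list(frame = v@grid@frame,
               voxelSize = sprintf("%.17g", v@grid@voxelSize),
               affine = sprintf("%.17g", v@grid@affine),
               kind = if (isLab) "labels" else "scalar")
  if (isLab) {
    side$labelNames <- as.list(v@labelNames)
  } else if (!all(v@mask)) {
    side$maskIdx <- which(v@mask)
  }
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Returns a \linkS4class{LabeledVolume} when the sidecar declares labels
#' (or, without a sidecar, when the file stores integers), otherwise a
#' \linkS4class{ScalarVolume}. Errors on non-3D data and on a frame
#' mismatch when \code{expectedFrame} is given.
#'
#' @param path NIfTI file path.
#' @param expectedFrame optional frame name to enforce.
#' @return A \linkS4class{ScalarVolume} or \linkS4class{LabeledVolume}.
#' @export
readVolume <- function(path, expectedFrame = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dat <- array(as.vector(img), dim(img))
  if (length(dim(dat)) != 3L)
    stop("expected a 3D volume, got ", length(dim(dat)), "D data")
  sidePath <- .sidecarPath(path)
  side <- if (file.exists(sidePath)) jsonlite::read_json(sidePath) else NULL
  aff <- if (!is.null(side))
    matrix(as.numeric(unlist(side$affine)), 4, 4)
  else structure(RNifti::xform(img), code = NULL)
  frame <- if (!is.null(side)) side$frame
           else if (!is.null(expectedFrame)) expectedFrame
           else "allen-ccf-like"
  if (!is.null(expectedFrame) && frame != expectedFrame)
    stop("frame mismatch: file is '", frame, "', expected '",
         expectedFrame, "'")
  vs <- if (!is.null(side)) as.numeric(unlist(side$voxelSize))
        else abs(diag(aff[1:3, 1:3, drop = FALSE]))
  grid <- volumeGrid(dim(dat), vs, frame, affine = matrix(aff, 4, 4))
  isLab <- if (!is.null(side)) identical(side$kind, "labels")
           else is.integer(dat)
  if (isLab) {
    ln <- if (!is.null(side$labelNames)) unlist(side$labelNames) else NULL
    labeledVolume(dat, grid, labelNames = ln)
  } else {
    mask <- array(TRUE, dim(dat))
    if (!is.null(side$maskIdx)) {
      mask[] <- FALSE
      mask[unlist(side$maskIdx)] <- TRUE
    }
    scalarVolume(dat, grid, mask)
  }
}

#' Min-max normalize a volume to the unit interval
#'
#' Rescales so the in-mask minimum maps to 0 and the maximum to 1
#' (the standard 0-1 intensity normalization applied to tracer volumes).
#' Out-of-mask voxels are set to 0. A constant volume normalizes to all
#' zeros with a warning, so batch ingestion of degenerate injections
#' never aborts.
#'
#' @param v a \linkS4class{ScalarVolume}.
#' @return A \linkS4class{ScalarVolume} with in-mask values in [0, 1].
#' @export
normalizeUnitInterval <- function(v) {
  inm <- v@data[v@mask]
  if (!length(inm) || !any(is.finite(inm)))
    stop("normalizeUnitInterval requires at least one finite in-mask value")
  lo <- min(inm); hi <- max(inm)
  out <- array(0, dim(v@data))
  if (hi == lo) {
    warning("constant volume: normalized to all zeros")
  } else {
    out[v@mask] <- (inm - lo) / (hi - lo)
  }
  scalarVolume(out, v@grid, v@mask)
}

#' Gaussian smoothing in world (mm) units
#'
#' Separable Gaussian convolution with per-axis sigma given in mm
#' (converted to voxels via the grid's voxel size); sigma 0 on an axis
#' means no smoothing on that axis. For volumes with a full mask the
#' boundary is edge-replicated; with a proper mask, smoothing is
#' zero-filled outside the mask and renormalized by the smoothed mask
#' (standard masked smoothing), and out-of-mask voxels are returned as 0.
#'
#' @param v a \linkS4class{ScalarVolume}.
#' @param sigmaMm numeric(3) (or scalar, recycled) sigma in mm per axis.
#' @return A smoothed \linkS4class{ScalarVolume}.
#' @seealso \code{\link{smoothTwiceVoxelXY}} for the in-plane
#'   twice-voxel-size convention used for rs-fMRI volumes.
#' @export
gaussianSmooth <- function(v, sigmaMm) {
  sigmaMm <- rep(as.numeric(sigmaMm), length.out = 3)
  if (any(sigmaMm < 0)) stop("sigma must be non-negative")
  sigmaVox <- sigmaMm / v@grid@voxelSize
  if (all(sigmaVox == 0)) return(v)
  if (all(v@mask)) {
    out <- .gaussSmooth3d(v@data, sigmaVox, pad = "replicate")
  } else {
    num <- .gaussSmooth3d(v@data * v@mask, sigmaVox, pad = "zero")
    den <- .gaussSmooth3d(v@mask * 1, sigmaVox, pad = "zero")
    out <- array(0, dim(v@data))
    ok <- v@mask & den > .Machine$double.eps
    out[ok] <- num[ok] / den[ok]
  }
  scalarVolume(out, v@grid, v@mask)
}

#' @rdname gaussianSmooth
#' @details \code{smoothTwiceVoxelXY} applies the smoothing rule used for
#'   rs-fMRI volumes: sigma equal to twice the voxel size on the X and Y
#'   axes and no smoothing along Z (0.4 mm for 0.2 mm mouse voxels, 4 mm
#'   for 2 mm human voxels).
#' @export
smoothTwiceVoxelXY <- function(v) {
  gaussianSmooth(v, c(2 * v@grid@voxelSize[1:2], 0))
}

#' Build a cubic ROI around a world coordinate
#'
#' Labels a cube of \code{edgeVoxels}^3 voxels centered on the voxel
#' nearest to \code{centerWorld} (the 3x3x3-voxel convention used for
#' connectivity targets). The cube is clipped at the grid edges with a
#' message reporting the clipped voxel count.
#'
#' @param centerWorld world mm triple; must fall inside the grid.
#' @param grid a \linkS4class{VolumeGrid}.
#' @param edgeVoxels cube edge in voxels (default 3).
#' @param label integer label to assign (default 1).
#' @param name label name (default \code{"roi"}).
#' @return A \linkS4class{LabeledVolume} with the cube labeled.
#' @export
makeCubeRoi <- function(centerWorld, grid, edgeVoxels = 3L, label = 1L,
                        name = "roi") {
  ctr <- worldToVoxel(grid, centerWorld)
  if (!.inGrid(grid, ctr))
    stop("center (", paste(centerWorld, collapse = ", "),
         ") is outside the grid")
  e <- as.integer(edgeVoxels)
  lo <- ctr - (e - 1L) %/% 2L
  hi <- ctr + e %/% 2L
  cloLo <- pmax(lo, 0L)
  cloHi <- pmin(hi, grid@dim - 1L)
  full <- prod(hi - lo + 1L)
  got <- prod(cloHi - cloLo + 1L)
  if (got < full)
    message("makeCubeRoi: clipped ", full - got, " voxels at grid edge")
  dat <- array(0L, grid@dim)
  dat[(cloLo[1] + 1L):(cloHi[1] + 1L),
      (cloLo[2] + 1L):(cloHi[2] + 1L),
      (cloLo[3] + 1L):(cloHi[3] + 1L)] <- as.integer(label)
  labeledVolume(dat, grid,
                stats::setNames(name, as.character(label)))
}
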