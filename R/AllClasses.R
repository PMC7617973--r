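#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' VolumeGrid: the sampling grid of a volumetric image
#'
#' Describes the voxel lattice a volume lives on: its dimensions, voxel
#' size in mm, a named coordinate frame, and the voxel-to-world affine.
#' Voxel indices are 0-based in world-mapping arithmetic (the first voxel
#' has index (0,0,0)); R array subscripts remain 1-based as usual.
#'
#' @slot dim integer(3), number of voxels per axis.
#' @slot voxelSize numeric(3), voxel edge length in mm per axis.
#' @slot frame character(1), one of \code{"allen-ccf-like"},
#'   \code{"stereotaxic-bregma"}, \code{"mni-like"}.
#' @slot affine 4x4 voxel-to-world matrix (homogeneous coordinates, mm).
#'
#' @export
setClass("VolumeGrid",
  representation(
    dim = "integer",
    voxelSize = "numeric",
    frame = "character",
    affine = "matrix"
  )
)

setValidity("VolumeGrid", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be three positive integers")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three strictly positive values")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else if (abs(det(object@affine)) < .Machine$double.eps * 100)
    msg <- c(msg, "affine must be invertible")
  if (!object@frame %in% c("allen-ccf-like", "stereotaxic-bregma", "mni-like"))
    msg <- c(msg, "frame must be one of allen-ccf-like, stereotaxic-bregma, mni-like")
  if (length(msg)) msg else TRUE
})

#' Construct a VolumeGrid
#'
#' The default affine maps 0-based voxel indices to world mm as
#' \code{world = (voxel - originVoxel) * voxelSize}, so the voxel
#' \code{originVoxel} sits at world (0,0,0). For the
#' \code{"stereotaxic-bregma"} frame the world axes are read as
#' (AP, ML, DV) mm from bregma.
#'
#' @param dim integer(3) voxel counts.
#' @param voxelSize numeric(3) mm per voxel (default 0.2 mm isotropic,
#'   the resolution tracer volumes are resampled to).
#' @param frame coordinate frame name.
#' @param originVoxel 0-based voxel index placed at world origin.
#' @param affine optional explicit 4x4 voxel-to-world matrix; overrides
#'   \code{voxelSize}/\code{originVoxel} construction.
#' @return A \linkS4class{VolumeGrid}.
#' @examples
#' g <- volumeGrid(c(10L, 10L, 10L), c(0.2, 0.2, 0.2))
#' voxelToWorld(g, c(0, 0, 0))
#' @export
volumeGrid <- function(dim, voxelSize = c(0.2, 0.2, 0.2),
                       frame = "allen-ccf-like",
                       originVoxel = c(0, 0, 0), affine = NULL) {
  dim <- as.integer(dim)
  voxelSize <- as.numeric(voxelSize)
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(voxelSize, 3, 3)
    affine[1:3, 4] <- -originVoxel * voxelSize
  }
  new("VolumeGrid", dim = dim, voxelSize = voxelSize, frame = frame,
      affine = affine)
}

#' ScalarVolume: a real-valued volume with an analysis mask
#'
#' @slot grid a \linkS4class{VolumeGrid}.
#' @slot data numeric 3D array matching the grid.
#' @slot mask logical 3D array; voxels outside the mask are ignored by
#'   all statistics and forced to 0 by normalization.
#' @export
setClass("ScalarVolume",
  representation(grid = "VolumeGrid", data = "array", mask = "array"))

setValidity("ScalarVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@data), object@grid@dim))
    msg <- c(msg, "data dimensions must match grid")
  if (!identical(dim(object@mask), object@grid@dim))
    msg <- c(msg, "mask dimensions must match grid")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (any(object@mask) && any(!is.finite(object@data[object@mask])))
    msg <- c(msg, "all in-mask values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a ScalarVolume
#' @param data numeric 3D array.
#' @param grid a \linkS4class{VolumeGrid}; defaults to a unit-spaced grid
#'   matching \code{dim(data)}.
#' @param mask logical array; defaults to all \code{TRUE}.
#' @return A \linkS4class{ScalarVolume}.
#' @export
scalarVolume <- function(data, grid = NULL, mask = NULL) {
  data <- as.array(data)
  if (is.null(grid)) grid <- volumeGrid(dim(data), c(1, 1, 1))
  if (is.null(mask)) mask <- array(TRUE, dim(data))
  new("ScalarVolume", grid = grid, data = data, mask = mask)
}

#' LabeledVolume: integer parcel/ROI labels on a grid
#'
#' Label 0 is background; every nonzero label must be named.
#'
#' @slot grid a \linkS4class{VolumeGrid}.
#' @slot data integer 3D array of labels.
#' @slot labelNames named character; names are label integers as strings.
#' @export
setClass("LabeledVolume",
  representation(grid = "VolumeGrid", data = "array", labelNames = "character"))

setValidity("LabeledVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@data), object@grid@dim))
    msg <- c(msg, "data dimensions must match grid")
  labs <- sort(unique(as.integer(object@data)))
  labs <- labs[labs != 0L]
  if (length(labs) && !all(as.character(labs) %in% names(object@labelNames)))
    msg <- c(msg, "every nonzero label must be present in labelNames")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledVolume
#' @param data integer 3D array (0 = background).
#' @param grid a \linkS4class{VolumeGrid} (default unit grid).
#' @param labelNames named character vector mapping label ids (as names)
#'   to area names; defaults to \code{"parcel<k>"} for the labels present.
#' @return A \linkS4class{LabeledVolume}.
#' @export
labeledVolume <- function(data, grid = NULL, labelNames = NULL) {
  data <- as.array(data)
  storage.mode(data) <- "integer"
  if (is.null(grid)) grid <- volumeGrid(dim(data), c(1, 1, 1))
  if (is.null(labelNames)) {
    labs <- sort(unique(as.integer(data)))
    labs <- labs[labs != 0L]
    labelNames <- stats::setNames(paste0("parcel", labs), as.character(labs))
  }
  new("LabeledVolume", grid = grid, data = data, labelNames = labelNames)
}

#' TracerExperimentSet: a set of normalized projection volumes
#'
#' Per-injection 3D fluorescence volumes on a common grid, each
#' min-max normalized to [0,1] within the shared in-network mask.
#'
#' @slot grid a \linkS4class{VolumeGrid}.
#' @slot volumes list of numeric 3D arrays, one per injection.
#' @slot mask logical 3D array (in-network analysis mask).
#' @slot injectionIds character, one id per volume.
#' @export
setClass("TracerExperimentSet",
  representation(grid = "VolumeGrid", volumes = "list", mask = "array",
                 injectionIds = "character"))

setValidity("TracerExperimentSet", function(object) {
  msg <- character()
  if (length(object@volumes) != length(object@injectionIds))
    msg <- c(msg, "one injectionId per volume required")
  for (v in object@volumes) {
    if (!identical(dim(v), object@grid@dim)) {
      msg <- c(msg, "all volumes must match the grid")
      break
    }
    inm <- v[object@mask]
    if (any(!is.finite(inm)) || any(inm < -1e-9) || any(inm > 1 + 1e-9)) {
      msg <- c(msg, "in-mask tracer values must be finite and within [0,1]")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' ConnectivityMatrix: voxel-by-feature connectivity profiles
#'
#' Rows are in-mask voxels in column-major (R array) order of their linear
#' indices; this linearization is the documented stable order used
#' throughout the package.
#'
#' @slot values numeric matrix, voxels x features.
#' @slot voxelIdx integer linear indices (1-based, column-major) of the
#'   mask voxels, ascending.
#' @slot grid the \linkS4class{VolumeGrid} the voxels live on.
#' @slot featureIds character column identifiers.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", voxelIdx = "integer", grid = "VolumeGrid",
                 featureIds = "character"))

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@voxelIdx))
    msg <- c(msg, "row count must equal mask voxel count")
  if (ncol(object@values) != length(object@featureIds))
    msg <- c(msg, "one featureId per column required")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "all values must be finite")
  if (is.unsorted(object@voxelIdx, strictly = TRUE))
    msg <- c(msg, "voxelIdx must be strictly ascending")
  if (length(msg)) msg else TRUE
})

#' Parcellation: voxel labels plus per-k model-selection metrics
#'
#' @slot labels a \linkS4class{LabeledVolume} with the selected-k labels.
#' @slot k integer, number of parcels in \code{labels}.
#' @slot perKMetrics data.frame over candidate k with columns
#'   \code{k, inertia, silhouette, sizeVariance, stability}.
#' @slot selectedK integer, the k chosen by \code{\link{selectK}}.
#' @slot seedsUsed integer vector of RNG seeds consumed.
#' @export
setClass("Parcellation",
  representation(labels = "LabeledVolume", k = "integer",
                 perKMetrics = "data.frame", selectedK = "integer",
                 seedsUsed = "integer"))

setValidity("Parcellation", function(object) {
  msg <- character()
  labs <- unique(as.integer(object@labels@data))
  labs <- labs[labs != 0L]
  if (length(labs) != object@k)
    msg <- c(msg, "labels must take exactly k distinct nonzero values")
  if (nrow(object@perKMetrics)) {
    if (any(abs(object@perKMetrics$silhouette) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "silhouette must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' SimilarityMaps: voxelwise fingerprint-match maps for one seed area
#'
#' @slot seedName mouse seed area name.
#' @slot rMaps list of per-subject correlation arrays.
#' @slot zMaps list of per-subject Fisher-z arrays.
#' @slot tMap group one-sample t array.
#' @slot pFweMap family-wise-error-corrected p array.
#' @slot sigMask logical array of voxels with pFwe <= alpha.
#' @slot mask analysis mask the maps are defined on.
#' @export
setClass("SimilarityMaps",
  representation(seedName = "character", rMaps = "list", zMaps = "list",
                 tMap = "arrayOrNULL", pFweMap = "arrayOrNULL",
                 sigMask = "arrayOrNULL", mask = "array"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "VolumeGrid", function(object) {
  cat("VolumeGrid:", paste(object@dim, collapse = " x "),
      "voxels,", paste(format(object@voxelSize), collapse = " x "),
      "mm,", object@frame, "frame\n")
})

setMethod("show", "ScalarVolume", function(object) {
  inm <- object@data[object@mask]
  cat("ScalarVolume on", paste(object@grid@dim, collapse = " x "),
      "grid;", sum(object@mask), "in-mask voxels")
  if (length(inm))
    cat("; range", paste(format(range(inm), digits = 4), collapse = " .. "))
  cat("\n")
})

setMethod("show", "LabeledVolume", function(object) {
  labs <- table(object@data[object@data != 0L])
  cat("LabeledVolume on", paste(object@grid@dim, collapse = " x "),
      "grid;", length(labs), "labels\n")
  if (length(labs)) {
    nm <- object@labelNames[names(labs)]
    cat(paste0("  ", names(labs), " (", nm, "): ", as.integer(labs),
               " voxels", collapse = "\n"), "\n")
  }
})

setMethod("show", "TracerExperimentSet", function(object) {
  cat("TracerExperimentSet:", length(object@volumes), "injections on",
      paste(object@grid@dim, collapse = " x "), "grid;",
      sum(object@mask), "in-network voxels\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix:", nrow(object@values), "voxels x",
      ncol(object@values), "features\n")
})

setMethod("show", "Parcellation", function(object) {
  cat("Parcellation: selected k =", object@selectedK, "\n")
  if (nrow(object@perKMetrics)) print(object@perKMetrics, row.names = FALSE)
})

setMethod("show", "SimilarityMaps", function(object) {
  cat("SimilarityMaps for seed", object@seedName, ":",
      length(object@rMaps), "subjects")
  if (!is.null(object@sigMask))
    cat(";", sum(object@sigMask), "significant voxels")
  cat("\n")
})

# ---- accessors --------------------------------------------------------------

#' @rdname accessors
#' @param object a premap S4 object.
#' @export
setGeneric("gridDim", function(object) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("frameName", function(object) standardGeneric("frameName"))
#' @rdname accessors
#' @export
setGeneric("affineMatrix", function(object) standardGeneric("affineMatrix"))
#' @rdname accessors
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("volMask", function(object) standardGeneric("volMask"))
#' @rdname accessors
#' @export
setGeneric("volGrid", function(object) standardGeneric("volGrid"))
#' @rdname accessors
#' @export
setGeneric("labelNames", function(object) standardGeneric("labelNames"))
#' @rdname accessors
#' @export
setGeneric("perKMetrics", function(object) standardGeneric("perKMetrics"))
#' @rdname accessors
#' @export
setGeneric("selectedK", function(object) standardGeneric("selectedK"))
#' @rdname accessors
#' @export
setGeneric("parcelLabels", function(object) standardGeneric("parcelLabels"))
#' @rdname accessors
#' @export
setGeneric("connValues", function(object) standardGeneric("connValues"))
#' @rdname accessors
#' @export
setGeneric("voxelIndex", function(object) standardGeneric("voxelIndex"))

#' Accessors for premap objects
#'
#' Slot access for the package's S4 containers: grid geometry
#' (\code{gridDim}, \code{voxelSize}, \code{frameName},
#' \code{affineMatrix}), volume contents (\code{volData}, \code{volMask},
#' \code{volGrid}, \code{labelNames}), parcellation results
#' (\code{perKMetrics}, \code{selectedK}, \code{parcelLabels}) and
#' connectivity matrices (\code{connValues}, \code{voxelIndex}).
#'
#' @param object a premap S4 object.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("gridDim", "VolumeGrid", function(object) object@dim)
#' @rdname accessors
setMethod("voxelSize", "VolumeGrid", function(object) object@voxelSize)
#' @rdname accessors
setMethod("frameName", "VolumeGrid", function(object) object@frame)
#' @rdname accessors
setMethod("affineMatrix", "VolumeGrid", function(object) object@affine)
#' @rdname accessors
setMethod("volData", "ScalarVolume", function(object) object@data)
#' @rdname accessors
setMethod("volData", "LabeledVolume", function(object) object@data)
#' @rdname accessors
setMethod("volMask", "ScalarVolume", function(object) object@mask)
#' @rdname accessors
setMethod("volMask", "TracerExperimentSet", function(object) object@mask)
#' @rdname accessors
setMethod("volGrid", "ScalarVolume", function(object) object@grid)
#' @rdname accessors
setMethod("volGrid", "LabeledVolume", function(object) object@grid)
#' @rdname accessors
setMethod("volGrid", "TracerExperimentSet", function(object) object@grid)
#' @rdname accessors
setMethod("volGrid", "ConnectivityMatrix", function(object) object@grid)
#' @rdname accessors
setMethod("labelNames", "LabeledVolume", function(object) object@labelNames)
#' @rdname accessors
setMethod("perKMetrics", "Parcellation", function(object) object@perKMetrics)
#' @rdname accessors
setMethod("selectedK", "Parcellation", function(object) object@selectedK)
#' @rdname accessors
setMethod("parcelLabels", "Parcellation", function(object) object@labels)
#' @rdname accessors
setMethod("connValues", "ConnectivityMatrix", function(object) object@values)
#' @rdname accessors
setMethod("voxelIndex", "ConnectivityMatrix", function(object) object@voxelIdx)
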