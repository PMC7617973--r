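#' Build the voxel-by-injection connectivity matrix
#'
#' Concatenates the normalized tracer volumes into a matrix whose row i
#' is the vector of values of in-mask voxel i across injections. Rows
#' follow the ascending column-major linear-index order of the mask (the
#' package's documented stable linearization).
#'
#' @param tracers a \linkS4class{TracerExperimentSet}.
#' @param mask optional logical array or \linkS4class{LabeledVolume}
#'   restricting the analysis; defaults to the set's own mask.
#' @return A \linkS4class{ConnectivityMatrix}.
#' @export
buildConnectivityMatrix <- function(tracers, mask = NULL) {
  if (is.null(mask)) {
    m <- tracers@mask
  } else if (is(mask, "LabeledVolume")) {
    if (!identical(mask@grid@dim, tracers@grid@dim))
      stop("mask grid does not match tracer grid")
    m <- mask@data != 0L
  } else {
    m <- mask
  }
  if (!identical(dim(m), tracers@grid@dim))
    stop("mask dimensions do not match tracer grid")
  idx <- which(m)
  if (!length(idx)) stop("mask is empty")
  vals <- vapply(tracers@volumes, function(v) v[idx],
                 numeric(length(idx)))
  vals <- matrix(vals, nrow = length(idx))
  new("ConnectivityMatrix", values = vals, voxelIdx = as.integer(idx),
      grid = tracers@grid, featureIds = tracers@injectionIds)
}

.asMatrix <- function(m) {
  if (is(m, "ConnectivityMatrix")) m@values else as.matrix(m)
}

#' K-means parcellation of connectivity profiles
#'
#' Best-of-restarts k-means under squared Euclidean distance (Lloyd's
#' algorithm, each restart initialized from k distinct sampled rows).
#' Inertia is the within-cluster sum of squares of the best restart.
#'
#' @param m a \linkS4class{ConnectivityMatrix} or numeric matrix.
#' @param k number of clusters (>= 2, <= number of distinct rows).
#' @param nRestarts number of random restarts (default 50).
#' @param seed RNG seed.
#' @return list with \code{assignments} (integer per row),
#'   \code{inertia}, \code{centers}, and — when \code{m} carries a grid —
#'   \code{labels}, a \linkS4class{LabeledVolume} of cluster labels.
#' @export
kmeansParcellate <- function(m, k, nRestarts = 50L, seed = 1L) {
  x <- .asMatrix(m)
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(x)) stop("k exceeds the number of rows")
  ux <- unique(x)
  if (k > nrow(ux)) stop("k exceeds the number of distinct rows")
  best <- NULL
  .withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      ctr <- ux[sample.int(nrow(ux), k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = ctr, iter.max = 100L,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed for every restart")
  out <- list(assignments = as.integer(best$cluster),
              inertia = best$tot.withinss, centers = best$centers)
  if (is(m, "ConnectivityMatrix")) {
    dat <- array(0L, m@grid@dim)
    dat[m@voxelIdx] <- out$assignments
    out$labels <- labeledVolume(dat, m@grid)
  }
  out
}

#' Mean silhouette score of a clustering
#'
#' For each sample, a is the mean distance to its own cluster and b the
#' smallest mean distance to another cluster; the silhouette is
#' mean((b - a) / max(a, b)). Samples in singleton clusters score 0. For
#' data sets larger than \code{maxN} rows, a seeded subsample is scored
#' (documented approximation).
#'
#' @param m matrix or \linkS4class{ConnectivityMatrix}.
#' @param labels integer cluster assignment per row.
#' @param maxN subsampling cap (default 1000).
#' @param seed RNG seed for subsampling.
#' @return numeric in [-1, 1].
#' @export
silhouetteScore <- function(m, labels, maxN = 1000L, seed = 1L) {
  x <- .asMatrix(m)
  labels <- as.integer(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("silhouette requires at least 2 clusters")
  if (all(tab == 1L)) {
    warning("all clusters are singletons; silhouette defined as 0")
    return(0)
  }
  if (nrow(x) > maxN) {
    sel <- .withSeed(seed, sample.int(nrow(x), maxN))
    x <- x[sel, , drop = FALSE]
    labels <- labels[sel]
    if (length(unique(labels)) < 2L) {
      warning("subsample collapsed to one cluster; silhouette defined as 0")
      return(0)
    }
  }
  D <- as.matrix(stats::dist(x))
  labs <- sort(unique(labels))
  n <- nrow(x)
  meanD <- vapply(labs, function(l) {
    cols <- labels == l
    rowSums(D[, cols, drop = FALSE]) / sum(cols)
  }, numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- match(labels[i], labs)
    ni <- sum(labels == labels[i])
    if (ni == 1L) { s[i] <- 0; next }
    a <- meanD[i, li] * ni / (ni - 1)   # exclude self from own-cluster mean
    b <- min(meanD[i, -li])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Normalized variance of parcel sizes
#'
#' Population variance of the cluster voxel counts normalized by the
#' squared mean count (squared coefficient of variation), so masks of
#' different sizes are comparable. Equal-size parcels score 0.
#'
#' @param labels integer assignments, a \linkS4class{LabeledVolume}, or a
#'   table of sizes.
#' @return numeric >= 0.
#' @export
parcelSizeVariance <- function(labels) {
  if (is(labels, "LabeledVolume")) labels <- labels@data[labels@data != 0L]
  sizes <- as.numeric(table(labels[labels != 0L]))
  if (length(sizes) < 2L) stop("need at least 2 parcels")
  mu <- mean(sizes)
  mean((sizes - mu)^2) / mu^2
}

# all permutations of 1..n (n small), as a matrix with n columns
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# best one-to-one cluster matching maximizing summed Dice; returns mean Dice
.matchedDice <- function(a, b, k) {
  d <- matrix(0, k, k)
  for (i in seq_len(k)) {
    ai <- a == i
    for (j in seq_len(k)) {
      bj <- b == j
      den <- sum(ai) + sum(bj)
      d[i, j] <- if (den > 0) 2 * sum(ai & bj) / den else 0
    }
  }
  perms <- .permutations(k)
  scores <- perms
  for (col in seq_len(k)) scores[, col] <- d[cbind(col, perms[, col])]
  max(rowSums(matrix(scores, nrow(perms)))) / k
}

#' Subsampling stability of a k-means parcellation
#'
#' Runs k-means on repeated random subsamples; every pair of runs is
#' compared on their common voxels after matching clusters by the
#' one-to-one assignment that maximizes summed Dice overlap. The score is
#' the mean matched Dice over all pairs, in [0, 1]; noise-free separable
#' data score 1 and pure noise scores near the label-shuffle chance
#' level.
#'
#' @param m matrix or \linkS4class{ConnectivityMatrix}.
#' @param k number of clusters.
#' @param nResamples number of subsampled runs (default 20).
#' @param subsampleFrac fraction of rows per run (default 0.8).
#' @param nRestarts k-means restarts per run (default 10).
#' @param seed RNG seed.
#' @return numeric in [0, 1].
#' @export
stabilityScore <- function(m, k, nResamples = 20L, subsampleFrac = 0.8,
                           nRestarts = 10L, seed = 1L) {
  x <- .asMatrix(m)
  if (nResamples < 2L) stop("nResamples must be >= 2")
  nSub <- floor(nrow(x) * subsampleFrac)
  if (nSub < k) stop("subsample too small to contain k clusters")
  runs <- vector("list", nResamples)
  .withSeed(seed, {
    for (r in seq_len(nResamples)) {
      sel <- sort(sample.int(nrow(x), nSub))
      fit <- kmeansParcellate(x[sel, , drop = FALSE], k,
                              nRestarts = nRestarts,
                              seed = sample.int(1e6, 1))
      runs[[r]] <- list(sel = sel, cl = fit$assignments)
    }
  })
  pairScores <- c()
  for (i in seq_len(nResamples - 1L)) {
    for (j in (i + 1L):nResamples) {
      common <- intersect(runs[[i]]$sel, runs[[j]]$sel)
      if (length(common) < k) next
      a <- runs[[i]]$cl[match(common, runs[[i]]$sel)]
      b <- runs[[j]]$cl[match(common, runs[[j]]$sel)]
      pairScores <- c(pairScores, .matchedDice(a, b, k))
    }
  }
  mean(pairScores)
}

#' Elbow of an inertia curve
#'
#' Returns the candidate k with the greatest discrete second difference
#' of inertia (greatest curvature); ties break to the smallest k. If no
#' k has positive curvature the smallest candidate is returned with a
#' warning.
#'
#' @param inertiaByK data.frame with columns \code{k} and \code{inertia},
#'   or a named numeric vector (names = k).
#' @return integer k.
#' @export
elbowK <- function(inertiaByK) {
  if (is.data.frame(inertiaByK)) {
    k <- inertiaByK$k; inertia <- inertiaByK$inertia
  } else {
    k <- as.integer(names(inertiaByK)); inertia <- as.numeric(inertiaByK)
  }
  o <- order(k); k <- k[o]; inertia <- inertia[o]
  if (length(k) < 3L) stop("elbowK needs at least 3 consecutive k values")
  d2 <- inertia[-c(1, 2)] - 2 * inertia[-c(1, length(k))] +
    inertia[-c(length(k) - 1, length(k))]
  # d2[i] is the curvature at interior k[i + 1]
  if (max(d2) <= 0) {
    warning("no positive curvature in the inertia curve; returning smallest k")
    return(k[1])
  }
  k[-c(1, length(k))][which.max(d2)]
}

#' Select the number of parcels from per-k metrics
#'
#' Lexicographic filter mirroring the model-selection narrative:
#' (1) keep candidates with stability at or above the threshold (empty
#' set falls back to the max-stability k with a warning); (2) keep those
#' within \code{silhouetteTol} of the best silhouette among them;
#' (3) prefer the inertia-elbow k if it is in the shortlist; (4) break
#' remaining ties by minimal parcel-size variance, then smallest k.
#' Every filter step is logged via \code{message}.
#'
#' @param metrics data.frame with columns \code{k, inertia, silhouette,
#'   sizeVariance, stability}.
#' @param stabilityThreshold minimum stability (default 0.8).
#' @param silhouetteTol absolute tolerance below the top silhouette
#'   (default 0.05).
#' @return integer, the selected k.
#' @export
selectK <- function(metrics, stabilityThreshold = 0.8,
                    silhouetteTol = 0.05) {
  stopifnot(all(c("k", "inertia", "silhouette", "sizeVariance",
                  "stability") %in% names(metrics)))
  metrics <- metrics[order(metrics$k), ]
  stable <- metrics[metrics$stability >= stabilityThreshold, ]
  if (!nrow(stable)) {
    warning("no k meets the stability threshold; falling back to max stability")
    return(metrics$k[which.max(metrics$stability)])
  }
  message("selectK: stable candidates k = ",
          paste(stable$k, collapse = ", "))
  if (nrow(stable) == 1L) return(stable$k)
  top <- max(stable$silhouette)
  short <- stable[stable$silhouette >= top - silhouetteTol, ]
  message("selectK: silhouette shortlist k = ",
          paste(short$k, collapse = ", "))
  if (nrow(short) == 1L) return(short$k)
  eb <- tryCatch(elbowK(metrics[, c("k", "inertia")]),
                 warning = function(w) NA_integer_)
  if (!is.na(eb) && eb %in% short$k) {
    message("selectK: elbow k = ", eb, " is in the shortlist; selected")
    return(eb)
  }
  message("selectK: tie broken by minimal size variance")
  short <- short[order(short$sizeVariance, short$k), ]
  short$k[1]
}

#' Parcel overlap with an atlas
#'
#' Percentage of a parcel's voxels falling within each atlas label
#' (plus \code{"outside"} for atlas background); percentages sum to 100.
#'
#' @param parcel integer label id of the parcel of interest.
#' @param labels a \linkS4class{LabeledVolume} of parcels.
#' @param atlas a \linkS4class{LabeledVolume} on the same grid.
#' @return data.frame of \code{atlasLabel, name, nVoxels, percent}.
#' @export
atlasOverlap <- function(parcel, labels, atlas) {
  if (!identical(labels@grid@dim, atlas@grid@dim))
    stop("parcel and atlas grids do not match")
  sel <- labels@data == as.integer(parcel)
  if (!any(sel)) stop("parcel ", parcel, " is empty")
  at <- atlas@data[sel]
  tab <- table(at)
  ids <- as.integer(names(tab))
  nm <- ifelse(ids == 0L, "outside",
               unname(atlas@labelNames[as.character(ids)]))
  data.frame(atlasLabel = ids, name = nm, nVoxels = as.integer(tab),
             percent = 100 * as.integer(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' End-to-end connectivity-based parcellation with model selection
#'
#' Builds the connectivity matrix, runs best-of-restarts k-means for
#' every candidate k, computes the four model-selection metrics
#' (inertia, silhouette, parcel-size variance, subsampling stability),
#' and selects k via \code{\link{selectK}}.
#'
#' @param tracers a \linkS4class{TracerExperimentSet}.
#' @param mask optional analysis mask (defaults to the set's mask).
#' @param kRange candidate k values (default 2:8).
#' @param nRestarts k-means restarts for the main fit (default 50).
#' @param nResamples,subsampleFrac stability settings (default 20, 0.8).
#' @param stabilityThreshold,silhouetteTol selection settings.
#' @param silhouetteMaxN silhouette subsampling cap (default 800).
#' @param seed RNG seed; per-stage seeds are derived from it and
#'   recorded in the result.
#' @return A \linkS4class{Parcellation}.
#' @export
parcellate <- function(tracers, mask = NULL, kRange = 2:8,
                       nRestarts = 50L, nResamples = 20L,
                       subsampleFrac = 0.8, stabilityThreshold = 0.8,
                       silhouetteTol = 0.05, silhouetteMaxN = 800L,
                       seed = 1L) {
  cm <- buildConnectivityMatrix(tracers, mask)
  fits <- list()
  rows <- list()
  seedsUsed <- integer()
  for (k in kRange) {
    sFit <- as.integer(seed + k)
    sStab <- as.integer(seed + 1000L + k)
    seedsUsed <- c(seedsUsed, sFit, sStab)
    fit <- kmeansParcellate(cm, k, nRestarts = nRestarts, seed = sFit)
    fits[[as.character(k)]] <- fit
    rows[[as.character(k)]] <- data.frame(
      k = k,
      inertia = fit$inertia,
      silhouette = silhouetteScore(cm, fit$assignments,
                                   maxN = silhouetteMaxN, seed = sFit),
      sizeVariance = parcelSizeVariance(fit$assignments),
      stability = stabilityScore(cm, k, nResamples = nResamples,
                                 subsampleFrac = subsampleFrac,
                                 seed = sStab))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  kSel <- selectK(metrics, stabilityThreshold, silhouetteTol)
  new("Parcellation", labels = fits[[as.character(kSel)]]$labels,
      k = as.integer(kSel), perKMetrics = metrics,
      selectedK = as.integer(kSel), seedsUsed = seedsUsed)
}
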