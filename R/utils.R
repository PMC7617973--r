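# Internal numerical helpers.

# 1D convolution of a 3D array along one axis with a normalized kernel.
# pad = "replicate" repeats edge planes; pad = "zero" pads zeros.
.convolveAxis <- function(arr, kernel, axis, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(arr * kernel)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  n <- d[axis]
  m <- prod(d[-axis])
  dim(x) <- c(n, m)
  padded <- matrix(0, n + 2L * r, m)
  padded[(r + 1L):(r + n), ] <- x
  if (pad == "replicate") {
    padded[seq_len(r), ] <- rep(x[1L, ], each = r)
    padded[(r + n + 1L):(n + 2L * r), ] <- rep(x[n, ], each = r)
  }
  out <- matrix(0, n, m)
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[j:(j + n - 1L), , drop = FALSE]
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

# Discrete normalized Gaussian kernel for a sigma given in voxels.
.gaussKernel <- function(sigmaVox) {
  r <- max(1L, ceiling(4 * sigmaVox))
  k <- exp(-0.5 * ((-r:r) / sigmaVox)^2)
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array; sigmaVox per axis, 0 = skip.
.gaussSmooth3d <- function(arr, sigmaVox, pad = "replicate") {
  for (ax in 1:3) {
    if (sigmaVox[ax] > 0)
      arr <- .convolveAxis(arr, .gaussKernel(sigmaVox[ax]), ax, pad)
  }
  arr
}

# Connected components of a logical 3D array under 6-connectivity.
# Vectorized label propagation: every foreground voxel starts with a unique
# label; labels are repeatedly replaced by the minimum over the 6-neighborhood
# until a fixed point. Returns an integer array with components 1..n, 0 bg.
.labelComponents <- function(fg) {
  d <- dim(fg)
  lab <- array(0L, d)
  lab[fg] <- seq_len(sum(fg))
  if (!any(fg)) return(lab)
  repeat {
    old <- lab
    for (ax in 1:3) {
      idx <- vector("list", 3)
      for (i in 1:3) idx[[i]] <- seq_len(d[i])
      lo <- idx; lo[[ax]] <- seq_len(d[ax] - 1L)
      hi <- idx; hi[[ax]] <- 1L + seq_len(d[ax] - 1L)
      a <- do.call(`[`, c(list(lab), lo, list(drop = FALSE)))
      b <- do.call(`[`, c(list(lab), hi, list(drop = FALSE)))
      take <- a > 0L & b > 0L
      mn <- pmin(a, b)
      a[take] <- mn[take]
      b[take] <- mn[take]
      lab <- do.call(`[<-`, c(list(lab), lo, list(a)))
      lab <- do.call(`[<-`, c(list(lab), hi, list(b)))
    }
    if (identical(lab, old)) break
  }
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

# Fisher r-to-z with clipping away from |r| = 1.
.fisherZ <- function(r, clip = 1 - 1e-6) {
  atanh(pmin(pmax(r, -clip), clip))
}

# Fast rowwise Pearson correlation between paired matrices (rows = units).
.rowCor <- function(a, b) {
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  sa <- sqrt(rowSums(a * a))
  sb <- sqrt(rowSums(b * b))
  num <- rowSums(a * b)
  r <- rep(0, nrow(a))
  ok <- sa > 0 & sb > 0
  r[ok] <- num[ok] / (sa[ok] * sb[ok])
  pmin(pmax(r, -1), 1)
}

# Two-sided p for Pearson r via the exact t transform, df = m - 2.
.corPval <- function(r, m) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = m - 2)
}

# Evaluate an expression with a temporary RNG seed, restoring state after.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Mean feature profile per group and L1 distance between two group means.
.manhattanStat <- function(x, isA) {
  abs(colMeans(x[isA, , drop = FALSE]) - colMeans(x[!isA, , drop = FALSE]))
}
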