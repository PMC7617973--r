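# Shared fixtures, built in code.

smallGrid <- function(dim = c(10L, 10L, 10L), vox = c(1, 1, 1),
                      frame = "allen-ccf-like") {
  volumeGrid(dim, vox, frame)
}

# Exhaustive k-partition oracle: minimum within-cluster sum of squares
# over every assignment of the rows into k groups (empty groups allowed
# to collapse; assignments with fewer than k nonempty groups are valid
# relaxations and can only tie or beat the k-means optimum from above,
# so we restrict to exactly-k-nonempty assignments).
bruteForceInertia <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  ass <- rep(1L, n)
  total <- k^n
  for (code in seq_len(total) - 1L) {
    c0 <- code
    for (i in seq_len(n)) {
      ass[i] <- c0 %% k + 1L
      c0 <- c0 %/% k
    }
    if (length(unique(ass)) != k) next
    w <- 0
    for (g in unique(ass)) {
      xg <- x[ass == g, , drop = FALSE]
      ctr <- colMeans(xg)
      w <- w + sum(sweep(xg, 2, ctr)^2)
    }
    if (w < best) best <- w
  }
  best
}

# independent mean-silhouette oracle on the full formula, one point at a time
handSilhouette <- function(x, labels) {
  D <- as.matrix(dist(x))
  s <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    own <- which(labels == labels[i] & seq_len(nrow(x)) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small multi-label target volume: nT cubes of `edge` voxels on one grid
makeTargetVolume <- function(grid, nT, edge = 2L) {
  d <- grid@dim
  arr <- array(0L, d)
  pos <- floor(seq(1, d[1] - edge, length.out = nT))
  for (i in seq_len(nT))
    arr[pos[i]:(pos[i] + edge - 1L), 1:edge, 1] <- i
  labeledVolume(arr, grid,
                stats::setNames(paste0("T", seq_len(nT)),
                                as.character(seq_len(nT))))
}
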