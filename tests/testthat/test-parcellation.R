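test_that("connectivity matrices read values off the volumes in stable order", {
  g <- smallGrid(c(3L, 1L, 1L))
  mask <- array(TRUE, c(3, 1, 1))
  v1 <- array(c(0, 0.5, 1), c(3, 1, 1))
  v2 <- array(c(1, 0, 0.25), c(3, 1, 1))
  tr <- new("TracerExperimentSet", grid = g, volumes = list(v1, v2),
            mask = mask, injectionIds = c("a", "b"))
  cm <- buildConnectivityMatrix(tr)
  expect_equal(connValues(cm), cbind(c(0, 0.5, 1), c(1, 0, 0.25)))
  # permuting injection order permutes columns only
  tr2 <- new("TracerExperimentSet", grid = g, volumes = list(v2, v1),
             mask = mask, injectionIds = c("b", "a"))
  expect_equal(connValues(buildConnectivityMatrix(tr2)),
               connValues(cm)[, 2:1])
  # synthetic set equals the generator's latent + noise construction:
  # noise-free, values are the per-parcel profiles after 0-1 rescaling
  geo <- generateParcelGeometry(smallGrid(c(8L, 8L, 1L)), "two-block")
  gen <- generateTracerSet(geo, nInjections = 4L, noiseSd = 0, seed = 5)
  cmg <- buildConnectivityMatrix(gen$tracers)
  mu <- gen$truth$latentProfiles
  expected <- apply(mu, 2, function(col) {
    (col - min(col)) / (max(col) - min(col))
  })[volData(geo)[voxelIndex(cmg)], ]
  expect_equal(connValues(cmg), unname(expected), tolerance = 1e-12)
})

test_that("k-means matches the exhaustive-partition optimum on tiny data", {
  # duplicated rows: perfect split at zero inertia
  x <- rbind(matrix(1, 3, 2), matrix(5, 3, 2))
  fit <- kmeansParcellate(x, 2L, nRestarts = 10L, seed = 1)
  expect_equal(fit$inertia, 0)
  expect_equal(length(unique(fit$assignments[1:3])), 1L)
  # listed 6 x 2 instance: brute force over all 2-partitions
  y <- matrix(c(0, 0, 0, 1, 1, 0, 5, 5, 6, 5, 5, 6), 6, 2, byrow = TRUE)
  fit2 <- kmeansParcellate(y, 2L, nRestarts = 100L, seed = 2)
  expect_equal(fit2$inertia, bruteForceInertia(y, 2L), tolerance = 1e-10)
  # random instances with <= 8 rows, k = 2 and 3
  set.seed(7)
  for (rep in 1:4) {
    z <- matrix(rnorm(8 * 3), 8, 3)
    for (k in 2:3) {
      fitr <- kmeansParcellate(z, k, nRestarts = 100L, seed = rep)
      expect_equal(fitr$inertia, bruteForceInertia(z, k),
                   tolerance = 1e-8)
    }
  }
  expect_error(kmeansParcellate(rbind(c(1, 1), c(1, 1)), 2L),
               "distinct")
})

test_that("silhouette agrees with hand evaluation and the cluster package", {
  # two well-separated duplicate clusters: a = 0 so score 1
  x <- rbind(matrix(0, 3, 2), matrix(9, 3, 2))
  lab <- rep(1:2, each = 3)
  expect_equal(silhouetteScore(x, lab), 1)
  # 4 listed points in 2 clusters: term-by-term hand evaluation
  p <- matrix(c(0, 0, 0, 1, 4, 0, 4, 1), 4, 2, byrow = TRUE)
  lp <- c(1, 1, 2, 2)
  expect_equal(silhouetteScore(p, lp), handSilhouette(p, lp),
               tolerance = 1e-12)
  # independent cross-check against cluster::silhouette
  set.seed(11)
  q <- matrix(rnorm(40), 20, 2)
  lq <- rep(1:2, 10)
  sil <- cluster::silhouette(lq, dist(q))
  expect_equal(silhouetteScore(q, lq), mean(sil[, "sil_width"]),
               tolerance = 1e-12)
  # random labels on iid data score near zero; range stays in [-1, 1]
  set.seed(12)
  r <- matrix(rnorm(200), 100, 2)
  s <- silhouetteScore(r, sample(1:4, 100, replace = TRUE))
  expect_lt(abs(s), 0.2)
  expect_true(s >= -1 && s <= 1)
  expect_warning(silhouetteScore(p, 1:4), "singleton")
})

test_that("parcel size variance is CV^2 and grows with imbalance", {
  expect_equal(parcelSizeVariance(rep(1:4, each = 25)), 0)
  expect_equal(parcelSizeVariance(rep(1:2, c(10, 30))), 100 / 400)
  balanced <- parcelSizeVariance(rep(1:4, each = 10))
  merged <- parcelSizeVariance(rep(c(1, 1, 3, 4), each = 10))
  expect_gt(merged, balanced)
  # label-permutation invariance
  lab <- rep(1:3, c(5, 10, 15))
  perm <- c(3L, 1L, 2L)[lab]
  expect_equal(parcelSizeVariance(lab), parcelSizeVariance(perm))
})

test_that("stability is 1 for separable data, chance-level for noise", {
  x <- rbind(matrix(0, 20, 2), matrix(10, 20, 2)) +
    matrix(rnorm(80, sd = 1e-3), 40, 2)
  expect_equal(stabilityScore(x, 2L, nResamples = 5L, seed = 1), 1,
               tolerance = 1e-9)
  # identical labelings under permuted label ids count as agreement 1
  a <- rep(1:4, each = 5); b <- c(3L, 4L, 1L, 2L)[a]
  expect_equal(premap:::.matchedDice(a, b, 4L), 1)
  # pure high-dimensional noise: score near the label-shuffle chance
  # level (in low dimensions the fixed point geometry itself stabilizes
  # k-means partitions, so the chance comparison needs dims ~ features)
  set.seed(21)
  noise <- matrix(rnorm(100 * 30), 100, 30)
  st <- stabilityScore(noise, 4L, nResamples = 6L, seed = 2)
  fit <- kmeansParcellate(noise, 4L, nRestarts = 10L, seed = 3)
  chance <- mean(replicate(30, premap:::.matchedDice(
    fit$assignments, sample(fit$assignments), 4L)))
  expect_lt(st, 0.8)
  expect_lt(abs(st - chance), 0.25)
  expect_gt(st, chance - 0.05)  # real runs can only beat shuffled labels
})

test_that("elbow detection maximizes the discrete second difference", {
  tab <- data.frame(k = 2:6, inertia = c(100, 90, 50, 45, 42))
  expect_equal(elbowK(tab), 4L)
  lin <- data.frame(k = 2:6, inertia = c(100, 90, 80, 70, 60))
  expect_warning(kl <- elbowK(lin), "curvature")
  expect_equal(kl, 2L)
  expect_error(elbowK(data.frame(k = 2:3, inertia = c(2, 1))), "at least 3")
})

test_that("selectK reproduces the published selection narrative", {
  # stable k >= 3; silhouette tied at {3,4,5}; elbow 4; min size var at 4
  m <- data.frame(k = 2:6,
                  inertia = c(100, 72, 50, 46, 44),
                  silhouette = c(0.40, 0.60, 0.61, 0.59, 0.35),
                  sizeVariance = c(0.01, 0.05, 0.02, 0.08, 0.70),
                  stability = c(0.55, 0.92, 0.95, 0.90, 0.88))
  expect_equal(suppressMessages(selectK(m)), 4L)
  # single stable candidate wins outright
  m2 <- m; m2$stability <- c(0.1, 0.1, 0.9, 0.1, 0.1)
  expect_equal(suppressMessages(selectK(m2)), 4L)
  # empty stable set falls back to max stability with a warning
  m3 <- m; m3$stability <- rep(0.2, 5); m3$stability[2] <- 0.4
  expect_warning(k3 <- selectK(m3), "stability threshold")
  expect_equal(k3, 3L)
  # without the elbow in the shortlist, minimal size variance decides
  m4 <- m; m4$inertia <- c(100, 40, 30, 27, 26)   # elbow at 3, not in {4,5}
  m4$silhouette <- c(0.40, 0.20, 0.61, 0.60, 0.35)
  expect_equal(suppressMessages(selectK(m4)), 4L)
})

test_that("atlas overlap percentages count voxels and sum to 100", {
  g <- smallGrid(c(10L, 1L, 1L))
  parc <- labeledVolume(array(c(rep(1L, 10)), c(10, 1, 1)), g)
  atl <- labeledVolume(array(c(rep(1L, 7), rep(2L, 3)), c(10, 1, 1)), g,
                       c("1" = "MOp", "2" = "MOs"))
  ov <- atlasOverlap(1L, parc, atl)
  expect_equal(ov$percent[ov$name == "MOp"], 70)
  expect_equal(ov$percent[ov$name == "MOs"], 30)
  expect_equal(sum(ov$percent), 100)
  atl2 <- labeledVolume(array(1L, c(10, 1, 1)), g, c("1" = "MOp"))
  expect_equal(atlasOverlap(1L, parc, atl2)$percent, 100)
})

test_that("parcellation metrics are label-permutation invariant", {
  set.seed(31)
  x <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 4), 20, 2))
  lab <- rep(1:2, each = 20)
  perm <- c(2L, 1L)[lab]
  expect_equal(silhouetteScore(x, lab), silhouetteScore(x, perm))
  expect_equal(parcelSizeVariance(lab), parcelSizeVariance(perm))
})

test_that("planted labels are recovered on the motor-system preset", {
  geo <- generateParcelGeometry()
  gen <- generateTracerSet(geo, seed = 17)
  cm <- buildConnectivityMatrix(gen$tracers)
  fit <- kmeansParcellate(cm, 4L, nRestarts = 50L, seed = 17)
  truth <- volData(geo)[voxelIndex(cm)]
  agree <- premap:::.matchedDice(fit$assignments, truth, 4L)
  expect_gte(agree, 0.95)
})
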