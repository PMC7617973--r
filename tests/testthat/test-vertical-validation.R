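test_that("voxelwise modal correlation handles exact and calibrated cases", {
  a <- matrix(rnorm(40), 10, 4)
  self <- voxelwiseModalCorrelation(a, a)
  expect_equal(self$r, rep(1, 10))
  lin <- voxelwiseModalCorrelation(matrix(1:4, 1, 4),
                                   matrix(c(2, 4, 6, 8), 1, 4))
  expect_equal(lin$r, 1)
  cst <- rbind(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_warning(res <- voxelwiseModalCorrelation(cst, cst + 0),
                 "constant")
  expect_equal(res$r[1], 0)
  expect_equal(res$p[1], 1)
  # calibrated synthetic pair: mean r within 0.02 of the closed form
  pm <- generatePairedModalities(500, 2000, 1, 1.4, 1.4, seed = 8)
  vc <- voxelwiseModalCorrelation(pm$a, pm$b)
  expect_lt(abs(mean(vc$r) - pm$expectedR), 0.02)
  # p via the exact t transform with df = features - 2
  r <- vc$r[1]; m <- 2000
  expect_equal(vc$p[1],
               2 * pt(-abs(r * sqrt((m - 2) / (1 - r^2))), m - 2))
})

test_that("conservative null centers on zero and is dominated by real r", {
  pm <- generatePairedModalities(300, 400, 1, 1, 1, seed = 9)
  outPool <- generatePairedModalities(120, 400, 1, 1, 1, seed = 10)$a
  nullR <- conservativeNull(pm$b, outPool, seed = 1)
  expect_length(nullR, 300)
  expect_identical(nullR, conservativeNull(pm$b, outPool, seed = 1))
  expect_false(identical(nullR, conservativeNull(pm$b, outPool, seed = 2)))
  se <- 1 / sqrt(400 - 3)
  expect_lt(abs(mean(nullR)), 3 * se / sqrt(300) * 10)
  expect_message(conservativeNull(pm$b, outPool[1:50, ], seed = 1),
                 "replacement")
  # matched real distribution stochastically dominates the null
  realR <- voxelwiseModalCorrelation(pm$a, pm$b)$r
  expect_lt(wilcox.test(realR, nullR, alternative = "greater")$p.value,
            1e-6)
})

test_that("KS comparison flags separated r distributions", {
  same <- ksCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$ks_stat, 0)
  expect_equal(same$ks_p, 1)
  disj <- ksCompare(c(0, 0.1), c(0.9, 1.0))
  expect_equal(disj$ks_stat, 1)
  set.seed(70)
  res <- ksCompare(rnorm(500, 0.46, 0.1), rnorm(500, 0, 0.1))
  expect_lt(res$ks_p, 1e-10)
})

test_that("region expression profiles are per-region gene means", {
  g <- smallGrid(c(4L, 1L, 1L))
  lab <- labeledVolume(array(c(1L, 1L, 2L, 2L), c(4, 1, 1)), g,
                       c("1" = "A", "2" = "B"))
  expr <- rbind(g1 = c(1, 3, 5, 7), g2 = c(2, 2, 2, 2))
  prof <- regionExpressionProfile(expr, lab)
  expect_equal(prof["A", ], c(g1 = 2, g2 = 2))
  expect_equal(prof["B", ], c(g1 = 6, g2 = 2))
  # constant gene: equal means everywhere
  expect_equal(unname(prof[, "g2"]), c(2, 2))
  expect_error(regionExpressionProfile(expr[, 1:3], lab), "match")
})

test_that("DAM B1+ inversion matches the closed form and the generator", {
  g <- smallGrid(c(5L, 5L, 2L))
  # A2/A1 = 2 cos(40 deg) at nominal 40 -> exactly 100%
  a1 <- scalarVolume(array(1, c(5, 5, 2)), g)
  a2 <- scalarVolume(array(2 * cos(40 * pi / 180), c(5, 5, 2)), g)
  b1 <- damB1Map(a1, a2, 40)
  expect_equal(volData(b1), array(100, c(5, 5, 2)), tolerance = 1e-12)
  # A2 = 0: arccos(0) = 90 deg -> 225% of a 40-degree nominal
  b1z <- damB1Map(a1, scalarVolume(array(0, c(5, 5, 2)), g), 40)
  expect_equal(volData(b1z)[1], 225)
  # noise-free generator inversion recovers the planted field < 1e-6 %
  set.seed(71)
  truth <- scalarVolume(array(runif(50, 60, 140), c(5, 5, 2)), g)
  pair <- generateDamPair(truth, 40, m0 = 1.7, noiseSd = 0)
  rec <- damB1Map(pair$A1, pair$A2, 40)
  expect_lt(max(abs(volData(rec) - volData(truth))), 1e-6)
  # clamping is reported, A1 <= 0 masked with warning
  noisy <- scalarVolume(volData(a2) * 3, g)
  expect_message(damB1Map(a1, noisy, 40), "clamped")
  a1bad <- scalarVolume(array(c(-1, rep(1, 49)), c(5, 5, 2)), g)
  expect_warning(damB1Map(a1bad, a2, 40), "masked out")
})

test_that("paired ROI t-tests match the textbook formula", {
  g <- smallGrid(c(6L, 1L, 1L))
  roiA <- labeledVolume(array(c(1L, 1L, 1L, 0L, 0L, 0L), c(6, 1, 1)), g)
  roiB <- labeledVolume(array(c(0L, 0L, 0L, 1L, 1L, 1L), c(6, 1, 1)), g)
  mk <- function(dA) array(c(rep(dA, 3), rep(0, 3)), c(6, 1, 1))
  # differences {1, 2, 3}: mean 2, sd 1, n 3 -> t = 2 sqrt(3)
  res <- roiPairedTtest(list(mk(1), mk(2), mk(3)), roiA, roiB)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  # identical ROI means: t = 0, p = 1
  same <- roiPairedTtest(list(mk(0), mk(0)), roiA, roiB)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # constant nonzero differences: t undefined, reported as NA
  und <- roiPairedTtest(list(mk(2), mk(2)), roiA, roiB)
  expect_true(is.na(und$t))
  # planted 2-SD offset at n = 12: p < 0.01 in >= 95% of replicates
  set.seed(72)
  hits <- mean(replicate(40, {
    maps <- lapply(1:12, function(i) {
      arr <- array(rnorm(6), c(6, 1, 1)); arr[1:3] <- arr[1:3] + 2; arr
    })
    roiPairedTtest(maps, roiA, roiB)$p < 0.01
  }))
  expect_gte(hits, 0.95)
})

test_that("experiment assignment uses strict containment", {
  geo <- generateParcelGeometry()
  # records at parcel centroids recover their parcels
  ctrs <- data.frame(AP = c(-0.2, 1.7, 1.5, -0.2),
                     ML = c(1.5, 2.0, 0.6, 0.4))
  res <- assignExperiments(ctrs, geo)
  expect_equal(res$parcel, c("M1", "ALM", "aM2", "pM2"))
  # a coordinate outside the grid is unassigned, never snapped
  out <- suppressMessages(
    assignExperiments(data.frame(AP = 40, ML = 0), geo))
  expect_equal(out$parcel, "unassigned")
  expect_error(assignExperiments(data.frame(AP = NA, ML = 1), geo),
               "malformed")
})

test_that("task-feature tabulation applies strict thresholds", {
  rec <- data.frame(
    parcel = c("aM2", "aM2", "pM2", "pM2"),
    task_type = c("sensorimotor transformation", "context/rule-based",
                  "sensorimotor transformation", "memory/delay"),
    complexity_index = c(5, 7, 5.01, 2),   # exactly 5 must be excluded
    n_actions = c(1L, 2L, 1L, 1L),         # exactly 1 must be excluded
    movement_complexity = c(1L, 2L, 1L, 1L))
  feats <- tabulateTaskFeatures(rec)
  expect_equal(feats$percent["aM2", "sensorimotor"], 50)
  expect_equal(feats$percent["aM2", "complexity"], 50)    # the 5 excluded
  expect_equal(feats$percent["pM2", "complexity"], 50)    # 5.01 included
  expect_equal(feats$percent["aM2", "multi_action"], 50)
  expect_equal(feats$percent["pM2", "multi_action"], 0)
  expect_equal(feats$percent["pM2", "simple_movement"], 100)
  # per-category normalization maps the max parcel to 1
  expect_equal(max(feats$normalized[, "simple_movement"]), 1)
  expect_true(all(feats$percent >= 0 & feats$percent <= 100))
  # single-parcel sweep: a category met by every study reads 100%
  one <- rec[rec$parcel == "pM2", ]
  f1 <- tabulateTaskFeatures(one)
  expect_equal(unname(f1$percent[1, "simple_movement"]), 100)
})
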