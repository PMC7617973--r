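test_that("ROI and voxel fingerprints are consistent correlations", {
  g <- smallGrid(c(8L, 8L, 1L))
  targets <- makeTargetVolume(g, 3L)
  C <- matrix(c(1, .6, .3, .6, 1, 0, .3, 0, 1), 3, 3)
  rois <- makeTargetVolume(g, 3L)
  ts <- generateFmriTimeseries(1, rois, C, nTimepoints = 900L,
                               noiseSd = 0, seed = 2)[[1]]
  seed1 <- labeledVolume(ifelse(volData(rois) == 1L, 1L, 0L), g)
  fp <- roiFingerprint(ts, seed1, targets)
  expect_named(fp, c("T1", "T2", "T3"))
  expect_equal(unname(fp["T1"]), 1, tolerance = 1e-9)  # seed == target 1
  expect_lt(abs(fp["T2"] - 0.6), 0.08)
  expect_lt(abs(fp["T3"] - 0.3), 0.08)
  # single-voxel ROI equals voxelFingerprint at the same location
  vox <- which(volData(rois) == 1L)[1]
  sub <- arrayInd(vox, gridDim(g)) - 1L
  one <- array(FALSE, gridDim(g)); one[vox] <- TRUE
  expect_equal(voxelFingerprint(ts, as.integer(sub), targets),
               roiFingerprint(ts, one, targets))
  # all-zero voxel series: zero fingerprint with a warning
  ts0 <- ts; ts0[1, 5, 1, ] <- 0
  expect_warning(fz <- voxelFingerprint(ts0, c(0L, 4L, 0L), targets),
                 "zero-variance")
  expect_equal(unname(fz), c(0, 0, 0))
  # independent white noise at T = 900: all |r| below the Fisher bound
  # (targets disjoint from the seed so no voxels are shared)
  set.seed(77)
  tsn <- array(rnorm(8 * 8 * 1 * 900), c(8, 8, 1, 900))
  tArr <- array(0L, gridDim(g))
  tArr[1:2, 5:6, 1] <- 1L; tArr[4:5, 5:6, 1] <- 2L; tArr[7:8, 5:6, 1] <- 3L
  fpn <- roiFingerprint(tsn, seed1, labeledVolume(tArr, g))
  expect_true(all(abs(fpn) < 0.11))
})

test_that("template fingerprints are elementwise medians", {
  f1 <- c(A = 0.1, B = 0.5); f2 <- c(A = 0.5, B = 0.9)
  f3 <- c(A = 0.9, B = 0.1)
  expect_equal(templateFingerprint(list(f1)), f1)
  expect_equal(templateFingerprint(list(f1, f2, f3)),
               c(A = 0.5, B = 0.5))
  # even count: mean of the two middle values
  f4 <- c(A = 0.2, B = 0.2); f5 <- c(A = 0.6, B = 0.6)
  f6 <- c(A = 0.8, B = 0.8)
  expect_equal(unname(templateFingerprint(list(f1, f4, f5, f6))["A"]), 0.4)
  expect_error(templateFingerprint(list(f1, c(X = 1, B = 2))),
               "mismatched")
})

test_that("fingerprint matching follows the clipped Fisher transform", {
  tpl <- c(0.8, 0.2, -0.4, 0.6)
  m <- rbind(tpl, -tpl, c(0.1, 0.1, 0.1, 0.1))
  expect_warning(res <- matchFingerprints(m, tpl), "constant")
  expect_equal(res$r[1], 1)
  expect_equal(res$z[1], atanh(1 - 1e-6))
  expect_equal(res$r[2], -1)
  expect_equal(res$r[3], 0)
  expect_equal(premap:::.fisherZ(0.5), atanh(0.5))
  # invariant to common affine rescaling of the template
  set.seed(5)
  fp <- matrix(rnorm(40), 10, 4)
  r1 <- matchFingerprints(fp, tpl)$r
  r2 <- matchFingerprints(fp, 3 * tpl + 7)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("sign-flip inference is exact for small n and detects effects", {
  # 3 subjects, 1 voxel, values {1,2,3}: exhaustive 8 flips, p = 1/8
  mk <- function(v) array(v, c(1, 1, 1))
  mask <- array(TRUE, c(1, 1, 1))
  res <- groupOnesamplePerm(list(mk(1), mk(2), mk(3)), mask)
  expect_true(res$exhaustive)
  expect_equal(res$pFweMap[1, 1, 1], 1 / 8)
  expect_equal(res$tMap[1, 1, 1], 2 / (1 / sqrt(3)))
  # all-zero maps: t = 0 and nothing significant
  z <- lapply(1:4, function(i) array(0, c(2, 2, 1)))
  r0 <- groupOnesamplePerm(z, array(TRUE, c(2, 2, 1)))
  expect_true(all(r0$tMap == 0))
  expect_false(any(r0$sigMask))
  # planted cluster, 20 subjects: significant at FWE 0.05 in >= 95% of reps
  d <- c(6L, 6L, 1L)
  clust <- array(FALSE, d); clust[2:3, 2:3, 1] <- TRUE
  hits <- 0L
  set.seed(40)
  for (rep in 1:20) {
    maps <- lapply(1:20, function(i) {
      m <- array(rnorm(prod(d)), d); m[clust] <- m[clust] + 1; m
    })
    rr <- groupOnesamplePerm(maps, array(TRUE, d), nPerm = 500L,
                             seed = rep)
    if (any(rr$sigMask[clust])) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("sampled sign-flip p-values match exhaustive in distribution", {
  set.seed(41)
  pEx <- numeric(60); pSam <- numeric(60)
  mask <- array(TRUE, c(3, 1, 1))
  for (i in 1:60) {
    maps <- lapply(1:8, function(s) array(rnorm(3), c(3, 1, 1)))
    pEx[i] <- min(groupOnesamplePerm(maps, mask)$pFweMap)
    pSam[i] <- min(groupOnesamplePerm(maps, mask, nPerm = 300L,
                                      seed = i,
                                      exhaustive = FALSE)$pFweMap)
  }
  expect_gt(suppressWarnings(ks.test(pEx, pSam))$p.value, 0.01)
})

test_that("TFCE enhances contiguous clusters over isolated peaks", {
  d <- c(8L, 8L, 1L)
  mask <- array(TRUE, d)
  stat <- array(0, d)
  stat[2:5, 2:5, 1] <- 3          # 16-voxel cluster at height 3
  stat[7, 7, 1] <- 3              # isolated voxel at the same height
  sc <- tfceScore(stat, mask)
  expect_gt(sc[3, 3, 1], sc[7, 7, 1])
  # analytic check for a flat cluster: sum over thresholds of e^E h^H dh
  hs <- seq(0.1, 3, by = 0.1)
  expect_equal(sc[3, 3, 1], sum(16^0.5 * hs^2 * 0.1), tolerance = 1e-9)
  expect_equal(sc[7, 7, 1], sum(1^0.5 * hs^2 * 0.1), tolerance = 1e-9)
  # tfce method plugs into the permutation engine
  maps <- lapply(1:5, function(i) array(rnorm(64), d) + stat / 3)
  rt <- groupOnesamplePerm(maps, mask, method = "tfce")
  expect_true(all(dim(rt$tMap) == d))
})

test_that("Manhattan permutation test matches exhaustive enumeration", {
  # identical groups: distance 0, p = 1
  a <- matrix(c(1, 2, 3, 4), 2, 2)
  r0 <- manhattanPermTest(a, a)
  expect_equal(r0$distance, 0)
  expect_equal(r0$p, 1)
  # 2+2 units: all choose(4,2) = 6 label assignments enumerated directly
  b <- matrix(c(10, 11, 12, 13), 2, 2)
  res <- manhattanPermTest(a, b)
  expect_true(res$exhaustive)
  x <- rbind(a, b)
  nullD <- apply(combn(4, 2), 2, function(sel) {
    sum(abs(colMeans(x[sel, , drop = FALSE]) -
              colMeans(x[-sel, , drop = FALSE])))
  })
  expect_equal(res$p, mean(nullD >= res$distance))
  # overwhelming planted effect: minimal attainable sampled p
  set.seed(50)
  big <- manhattanPermTest(matrix(rnorm(200 * 5), 200, 5),
                           matrix(rnorm(200 * 5, 10), 200, 5),
                           nPerm = 1000L, seed = 1)
  expect_false(big$exhaustive)
  expect_equal(big$p, 1 / 1001)
})

test_that("Manhattan p-values are uniform on the achievable grid under null", {
  set.seed(51)
  ps <- replicate(200, {
    manhattanPermTest(matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3))$p
  })
  # exhaustive 3+3 case: complementary assignments pair up, so p lives
  # on the 10-point grid {0.1, 0.2, ..., 1} and is uniform over it
  expect_true(all(abs(ps * 20 - round(ps * 20)) < 1e-9))
  counts <- table(factor(round(ps * 10), levels = 1:10))
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
})
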