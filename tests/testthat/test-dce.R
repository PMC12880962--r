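test_that("TTP takes the first maximum of baseline-subtracted enhancement", {
  mk4 <- function(series) {
    a <- array(rep(series, each = 8), c(2, 2, 2, length(series)))
    ImageVolume(a, frameInterval = 10)
  }
  tm <- ttpMap(mk4(c(0, 1, 5, 3, 2)), baselineFrames = 1)
  expect_equal(unname(voxelData(tm)[1, 1, 1]), 20)
  # constant series: invalid voxel, NA value
  tc <- ttpMap(mk4(c(4, 4, 4, 4)), baselineFrames = 1)
  expect_false(any(tc@valid))
  expect_true(all(is.na(voxelData(tc))))
  # plateau peak: first frame attaining the maximum wins
  tp <- ttpMap(mk4(c(0, 5, 5, 5, 1)), baselineFrames = 1)
  expect_equal(unname(voxelData(tp)[1, 1, 1]), 10)
  expect_error(ttpMap(ImageVolume(array(0, c(2, 2, 2)))), "4D")
  expect_error(ttpMap(mk4(c(0, 1)), baselineFrames = 2), "baselineFrames")
})

test_that("step-kernel DCE phantom: TTP monotone along the path, front at 5 cm/frame", {
  spec <- dcePhantomSpec()
  g <- generateVesselTree(spec)
  mask <- rasterizeTree(g, spec)
  dce <- simulateDce(g, mask, velocityCmPerMin = 30, frameIntervalS = 10,
                     nFrames = 26)
  path <- graphSegments(g)[[1]]$points
  # TTP at points along the path is non-decreasing with path distance
  tm <- ttpMap(dce)
  samples <- path[seq(1, nrow(path), length.out = 12), ]
  tt <- apply(samples, 1, function(p) {
    v <- perfuseMRI:::worldToVoxel(tm, p)
    voxelData(tm)[v[1], v[2], v[3]]
  })
  expect_true(all(diff(tt) >= 0))
  # front advances 5 cm per 10 s frame at 30 cm/min
  fr <- trackBolusFront(dce, path)
  expect_true(all(diff(fr$front_distance_cm) >= 0))
  moving <- fr$front_distance_cm < max(fr$front_distance_cm)
  expect_equal(diff(fr$front_distance_cm[1:3]), c(4.95, 5), tolerance = 0.05)
  # velocity recovered within 10%, flow with the true diameter within 15%
  est <- estimateVelocity(fr)
  expect_lt(abs(est$velocity_cm_per_min - 30) / 30, 0.1)
  Q <- volumetricFlow(2 * 3 / 10, est$velocity_cm_per_min)
  expect_lt(abs(Q - volumetricFlow(0.6, 30)) / volumetricFlow(0.6, 30), 0.15)
  # velocity 0: only voxels at path distance 0 ever enhance, and the
  # enhanced set never grows over time
  dce0 <- simulateDce(g, mask, velocityCmPerMin = 0, frameIntervalS = 10,
                      nFrames = 5)
  v0 <- voxelData(dce0)
  enh1 <- v0[, , , 1] > 30
  enh5 <- v0[, , , 5] > 30
  expect_identical(enh5, enh1)
  idx0 <- which(enh5, arr.ind = TRUE)
  if (nrow(idx0)) expect_lt(max(idx0[, 3]), 8)   # all near the inlet
  # only the inlet cap (nearest to the path-distance-0 point) enhances
  expect_lt(sum(enh5), 0.05 * sum(voxelData(mask)))
})

test_that("ROI curves report the repeat envelope and arrival ordering", {
  spec <- dcePhantomSpec()
  g <- generateVesselTree(spec)
  mask <- rasterizeTree(g, spec)
  dce <- simulateDce(g, mask, velocityCmPerMin = 30, frameIntervalS = 10,
                     nFrames = 26)
  ctr <- c(12, 12, 20)
  cv <- roiEnhancementCurve(dce, rbind(ctr, ctr, ctr), roiSize = 4)
  expect_equal(cv$min_signal, cv$mean_signal)
  expect_equal(cv$max_signal, cv$mean_signal)
  expect_true(all(diff(cv$times_s) > 0))
  # an ROI near the outlet peaks later than one near the inlet
  inlet <- roiEnhancementCurve(dce, matrix(c(12, 12, 12), 1), roiSize = 4)
  outlet <- roiEnhancementCurve(dce, matrix(c(12, 12, 110), 1), roiSize = 4)
  expect_gt(which.max(diff(outlet$mean_signal)),
            which.max(diff(inlet$mean_signal)))
  expect_error(roiEnhancementCurve(dce, matrix(c(1, 1, 5), 1), roiSize = 10),
               "outside")
  # containment check against the vessel mask
  expect_error(roiEnhancementCurve(dce, matrix(c(4, 4, 20), 1), roiSize = 4,
                                   vesselMask = mask), "not entirely")
})

test_that("velocity regression handles plateaus, noise and degenerate fronts", {
  expect_equal(estimateVelocity(data.frame(
    time_s = c(0, 10, 20), front_distance_cm = c(0, 5, 10)))$velocity_cm_per_min,
    30)
  expect_equal(estimateVelocity(data.frame(
    time_s = c(0, 10, 20), front_distance_cm = c(2, 2, 2)))$velocity_cm_per_min,
    0)
  expect_error(estimateVelocity(data.frame(time_s = 0, front_distance_cm = 0)),
               "two front samples")
  # noisy fronts: mean estimate within 10% of truth
  set.seed(31)
  ests <- replicate(100, {
    t <- seq(0, 60, 10)
    x <- pmin(0.5 * t + rnorm(7, 0, 0.3), 35)    # 0.5 cm/s = 30 cm/min
    x <- cummax(pmax(x, 0))
    estimateVelocity(data.frame(time_s = t, front_distance_cm = x))$velocity_cm_per_min
  })
  expect_lt(abs(mean(ests) - 30) / 30, 0.1)
})

test_that("volumetric flow follows Q = pi d^2 v / 4 with the right units", {
  expect_equal(volumetricFlow(0, 10), 0)
  expect_equal(volumetricFlow(1, 4 / pi), 1)
  expect_equal(volumetricFlow(0.2, 31.25), 0.25 * pi * 0.04 * 31.25)
  # quadratic in d, linear in v
  set.seed(5)
  d <- runif(20, 0.1, 3); v <- runif(20, 1, 60)
  expect_equal(volumetricFlow(2 * d, v), 4 * volumetricFlow(d, v))
  expect_equal(volumetricFlow(d, 3 * v), 3 * volumetricFlow(d, v))
  expect_error(volumetricFlow(-1, 1), ">= 0")
})
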