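test_that("vessel tree generator: combinatorics, radii taper, determinism", {
  spec1 <- PhantomSpec(c(40, 40, 40), spacing = rep(1, 3), treeDepth = 1,
                       rootRadius = 3, segmentLength = 20,
                       tortuosityAmplitude = 0, seed = 1)
  g1 <- generateVesselTree(spec1)
  expect_equal(length(graphSegments(g1)), 1L)
  expect_equal(sum(graphNodes(g1)$degree == 1L), 2L)
  expect_equal(segmentMetrics(graphSegments(g1)[[1]])$tortuosity, 1)
  expect_equal(inletNode(g1), 1L)
  spec2 <- PhantomSpec(c(64, 64, 64), spacing = rep(1, 3), treeDepth = 2,
                       rootRadius = 3, radiusDecay = 0.7, segmentLength = 14,
                       tortuosityAmplitude = 0, seed = 1)
  g2 <- generateVesselTree(spec2)
  expect_equal(length(graphSegments(g2)), 3L)
  expect_equal(sum(graphNodes(g2)$degree == 3L), 1L)
  expect_equal(sum(graphNodes(g2)$degree == 1L), 3L)
  # radii taper by radiusDecay per generation
  r <- vapply(graphSegments(g2), function(s) s$radius[1], numeric(1))
  expect_equal(sort(unique(r)), c(3 * 0.7, 3))
  # deterministic for fixed seed; different seeds differ
  g2b <- generateVesselTree(spec2)
  expect_identical(graphNodes(g2), graphNodes(g2b))
  spec2c <- spec2; spec2c@seed <- 2L
  expect_false(identical(graphNodes(generateVesselTree(spec2c)),
                         graphNodes(g2)))
  # a tree that cannot fit errors, naming the generation
  tiny <- PhantomSpec(c(30, 30, 30), spacing = rep(1, 3), treeDepth = 3,
                      rootRadius = 3, segmentLength = 20,
                      tortuosityAmplitude = 0, seed = 1)
  expect_error(generateVesselTree(tiny), "generation")
})

test_that("sinusoidal perturbation yields the numerically integrated tortuosity", {
  # half-sine lateral displacement of amplitude A over chord L:
  # p(t) = chord(t) + A sin(pi t) n; arc length integral as the oracle
  L <- 40; A <- L / 2
  oracle <- integrate(function(t) sqrt(L^2 + (A * pi * cos(pi * t))^2),
                      0, 1, rel.tol = 1e-10)$value / L
  spec <- PhantomSpec(c(60, 60, 60), spacing = rep(1, 3), treeDepth = 1,
                      rootRadius = 3, segmentLength = L,
                      tortuosityAmplitude = A, seed = 3)
  g <- generateVesselTree(spec)
  m <- segmentMetrics(graphSegments(g)[[1]])
  expect_equal(m$straight_length_mm, L, tolerance = 1e-9)
  expect_equal(m$tortuosity, oracle, tolerance = 1e-3)
})

test_that("capsule rasterization approximates analytic volumes", {
  # straight capsule of radius 3, chord 30, 1 mm voxels: voxel count
  # approximates the analytic capsule volume (cylinder + spherical caps)
  capsuleVol <- pi * 9 * 30 + 4 / 3 * pi * 27
  spec <- PhantomSpec(c(21, 21, 42), spacing = rep(1, 3), treeDepth = 1,
                      rootRadius = 3, segmentLength = 30,
                      tortuosityAmplitude = 0, seed = 1)
  g <- generateVesselTree(spec)
  mask <- rasterizeTree(g, spec)
  vol <- maskVolumeMm3(mask)
  expect_lt(abs(vol - capsuleVol) / capsuleVol, 0.1)
  # convergence: finer voxels get closer to the analytic volume
  spec2 <- PhantomSpec(c(42, 42, 84), spacing = rep(0.5, 3), treeDepth = 1,
                       rootRadius = 3, segmentLength = 30,
                       tortuosityAmplitude = 0, seed = 1)
  vol2 <- maskVolumeMm3(rasterizeTree(generateVesselTree(spec2), spec2))
  expect_lt(abs(vol2 - capsuleVol), abs(vol - capsuleVol) + 1e-9)
  # empty graph: all background
  eg <- new("SpatialGraph")
  expect_false(any(voxelData(rasterizeTree(eg, spec))))
  # sub-voxel radii warn about resolvability
  gsmall <- g
  gsmall@segments[[1]]$radius[] <- 0.3
  expect_warning(rasterizeTree(gsmall, spec), "unresolvable")
})

test_that("T2 simulation separates compartments at the stated contrast", {
  spec <- PhantomSpec(c(48, 48, 48), spacing = rep(1, 3), treeDepth = 2,
                      rootRadius = 3, segmentLength = 12,
                      tortuosityAmplitude = 0, seed = 6)
  mask <- rasterizeTree(generateVesselTree(spec), spec)
  # zero noise: exactly two-valued
  t2 <- simulateT2Volume(mask, 200, 100, noiseSd = 0, seed = 1)
  expect_setequal(unique(as.vector(voxelData(t2))), c(100, 200))
  # noise 5: mid-band threshold recovers the mask at >= 99% agreement
  t2n <- simulateT2Volume(mask, 200, 100, noiseSd = 5, seed = 1)
  recovered <- voxelData(t2n) > 150
  expect_gte(mean(recovered == voxelData(mask)), 0.99)
  # all-background mask with zero noise: constant parenchyma value
  t2e <- simulateT2Volume(BinaryMask(array(FALSE, c(6, 6, 6))), 200, 100,
                          noiseSd = 0, seed = 1)
  expect_equal(unique(as.vector(voxelData(t2e))), 100)
  expect_error(simulateT2Volume(mask, 200, 100, noiseSd = -1), "noiseSd")
  expect_error(simulateT2Volume(mask, 100, 100), "distinct")
})

test_that("DWI simulation follows the monoexponential decay and noise model", {
  D <- array(1e-3, c(6, 6, 4))
  dwi <- simulateDwi(D, S0 = 100, bValues = c(90, 500, 1500, 2000),
                     directions = 1, noiseSd = 0, seed = 1)
  expect_equal(unname(voxelData(dwi$volumes[[1]][[4]])[1, 1, 1]),
               100 * exp(-2), tolerance = 1e-12)
  # D = 0: all volumes equal S0
  dwi0 <- simulateDwi(array(0, c(4, 4, 4)), S0 = 80,
                      bValues = c(90, 2000), directions = 2, noiseSd = 0,
                      seed = 1)
  for (dir in 1:2) for (b in 1:2)
    expect_true(all(voxelData(dwi0$volumes[[dir]][[b]]) == 80))
  # noise-free signal is non-negative and non-increasing in b
  set.seed(12)
  Dr <- array(runif(4 * 4 * 4, 0, 3e-3), c(4, 4, 4))
  dwir <- simulateDwi(Dr, S0 = 50, bValues = c(90, 500, 1500, 2000),
                      directions = 1, noiseSd = 0, seed = 1)
  sig <- sapply(dwir$volumes[[1]], function(v) as.vector(voxelData(v)))
  expect_true(all(sig >= 0))
  expect_true(all(diff(t(sig)) <= 1e-12))
  # noisy magnitudes stay non-negative
  dwin <- simulateDwi(Dr, S0 = 50, bValues = c(90, 2000), directions = 1,
                      noiseSd = 3, seed = 4)
  expect_true(all(voxelData(dwin$volumes[[1]][[1]]) >= 0))
  expect_error(simulateDwi(Dr, bValues = c(90, 90)), "distinct")
})

test_that("DCE simulation: onset is monotone in path distance, reproducible", {
  spec <- dcePhantomSpec()
  g <- generateVesselTree(spec)
  mask <- rasterizeTree(g, spec)
  dce <- simulateDce(g, mask, velocityCmPerMin = 30, frameIntervalS = 10,
                     nFrames = 20)
  expect_equal(dim(voxelData(dce))[4], 20L)
  expect_equal(frameIntervalS(dce), 10)
  # onset frame is non-decreasing along the vessel
  v <- voxelData(dce)
  onset <- function(z) which(v[12, 12, z, ] > 30)[1]
  on <- vapply(seq(6, 110, 8), onset, numeric(1))
  expect_true(all(diff(on) >= 0))
  # reproducible with a fixed seed (noise on)
  d1 <- simulateDce(g, mask, 30, 10, 6, noiseSd = 2, seed = 5)
  d2 <- simulateDce(g, mask, 30, 10, 6, noiseSd = 2, seed = 5)
  expect_identical(voxelData(d1), voxelData(d2))
  # a graph without an inlet is rejected
  gni <- g
  gni@inlet <- NA_integer_
  expect_error(simulateDce(gni, mask, 30, 10, 5), "inlet")
  # gamma kernel rises and falls
  dg <- simulateDce(g, mask, 30, 10, 30, kernel = "gamma", gammaPeakS = 20)
  curve <- voxelData(dg)[12, 12, 10, ]
  expect_lt(curve[30], max(curve))
  expect_equal(which.max(curve) > 1, TRUE)
})

test_that("histology simulator hits exact composites in degenerate settings", {
  m <- data.frame(group = "G", timepoint = "T", neutrophil = 1, necrosis = 1,
                  congestion = 2, oedema = 2)
  tab <- simulateHistology(m, dispersion = 0, nBiopsies = 5, seed = 1)
  expect_true(all(tab$composite == 6))
  mceil <- data.frame(group = "G", timepoint = "T", neutrophil = 3,
                      necrosis = 3, congestion = 3, oedema = 3)
  tc <- simulateHistology(mceil, dispersion = 0.5, nBiopsies = 6, seed = 2)
  expect_true(all(tc$composite <= 12))
  t0 <- simulateHistology(mceil, dispersion = 0, nBiopsies = 3, seed = 3)
  expect_true(all(t0$composite == 12))
  bad <- m; bad$necrosis <- 3.5
  expect_error(simulateHistology(bad), "\\[0, 3\\]")
})
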