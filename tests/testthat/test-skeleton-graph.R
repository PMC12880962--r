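test_that("chamfer map reproduces hand-computable distances and the Dijkstra oracle", {
  # single foreground voxel: face weight
  m <- BinaryMask(array(FALSE, c(5, 5, 5))); m@values[3, 3, 3] <- TRUE
  expect_equal(voxelData(chamferDistanceMap(m))[3, 3, 3], 3)
  # 5x1x1 row with background all around: every voxel one face step away
  m2 <- BinaryMask(array(FALSE, c(9, 3, 3))); m2@values[3:7, 2, 2] <- TRUE
  d2 <- voxelData(chamferDistanceMap(m2))
  expect_equal(unname(d2[3:7, 2, 2]), rep(3, 5))
  # solid 9^3 cube: centre is 5 face steps from outside
  m3 <- BinaryMask(array(TRUE, c(9, 9, 9)))
  expect_equal(voxelData(chamferDistanceMap(m3))[5, 5, 5], 15)
  # equality with exact shortest paths on random masks
  set.seed(7)
  for (rep in 1:5) {
    mk <- randomMask(c(12, 12, 12))
    if (!any(voxelData(mk))) next
    expect_equal(voxelData(chamferDistanceMap(mk)), bruteChamfer(mk))
  }
  # empty mask: zero map with warning
  expect_warning(dz <- chamferDistanceMap(BinaryMask(array(FALSE, c(4, 4, 4)))),
                 "empty")
  expect_true(all(voxelData(dz) == 0))
})

test_that("distance-ordered thinning preserves topology and centers tube skeletons", {
  # an already 1-voxel-wide curve is returned unchanged
  m <- BinaryMask(array(FALSE, c(12, 6, 6)))
  m@values[cbind(2:11, c(2, 2, 3, 3, 4, 4, 4, 3, 3, 2), 3)] <- TRUE
  sk <- distanceOrderedThinning(chamferDistanceMap(m), 2)
  expect_identical(voxelData(sk), voxelData(m))
  # solid cylinder radius 3: skeleton within 1 voxel of the axis
  cyl <- cylinderMask(c(21, 21, 40), 3, 3:38)
  sk2 <- distanceOrderedThinning(chamferDistanceMap(cyl), 2)
  idx <- which(voxelData(sk2), arr.ind = TRUE)
  offaxis <- sqrt((idx[, 1] - 11)^2 + (idx[, 2] - 11)^2)
  expect_gte(mean(offaxis <= 1 + 1e-9), 0.95)
  expect_gte(diff(range(idx[, 3])), 0.8 * diff(range(3:38)))
  # skeleton is a subset of the mask
  expect_true(all(voxelData(cyl)[voxelData(sk2)]))
  # solid 5^3 cube keeps exactly one connected component
  cube <- BinaryMask(array(TRUE, c(5, 5, 5)))
  sk3 <- distanceOrderedThinning(chamferDistanceMap(cube), 2)
  expect_equal(countComponents(sk3), 1L)
  # component count preserved on random blobby masks
  set.seed(13)
  for (rep in 1:5) {
    mk <- randomMask(c(14, 14, 14), nBalls = 2, speckle = 0.01)
    skr <- distanceOrderedThinning(chamferDistanceMap(mk), 2)
    expect_equal(countComponents(skr), countComponents(mk))
    expect_true(all(voxelData(mk)[voxelData(skr)]))
  }
})

test_that("line tracing turns skeleton voxels into the expected node/segment graph", {
  # straight voxel line: 2 nodes, 1 segment
  m <- BinaryMask(array(FALSE, c(10, 5, 5))); m@values[2:9, 3, 3] <- TRUE
  g <- traceLines(m)
  expect_equal(nrow(graphNodes(g)), 2L)
  expect_equal(length(graphSegments(g)), 1L)
  expect_equal(sort(graphNodes(g)$degree), c(1L, 1L))
  # Y-shaped skeleton: 4 nodes (one degree-3), 3 segments
  y <- BinaryMask(array(FALSE, c(11, 11, 5)))
  y@values[cbind(2:6, 6, 3)] <- TRUE              # stem
  y@values[cbind(7:10, 7:10, 3)] <- TRUE          # arm 1 (diagonal)
  y@values[cbind(7:10, 5:2, 3)] <- TRUE           # arm 2 (diagonal)
  gy <- traceLines(y)
  expect_equal(nrow(graphNodes(gy)), 4L)
  expect_equal(length(graphSegments(gy)), 3L)
  expect_equal(sort(graphNodes(gy)$degree), c(1L, 1L, 1L, 3L))
  # single closed loop: one artificial degree-2 node, one segment with
  # coincident ends
  lp <- BinaryMask(array(FALSE, c(10, 10, 4)))
  lp@values[cbind(c(3:7, rep(8, 3), 7:3, rep(2, 3)),
                  c(rep(2, 5), 3:5, rep(6, 5), 5:3), 2)] <- TRUE
  gl <- traceLines(lp)
  expect_equal(nrow(graphNodes(gl)), 1L)
  expect_equal(length(graphSegments(gl)), 1L)
  s <- graphSegments(gl)[[1]]
  expect_equal(s$a, s$b)
  expect_equal(s$points[1, ], s$points[nrow(s$points), ])
  # thick input is rejected
  thick <- BinaryMask(array(TRUE, c(4, 4, 4)))
  expect_error(traceLines(thick), "2x2x2")
})

test_that("polyline smoothing contracts zig-zags, fixes nodes and honours attach", {
  zig <- cbind(seq(0, 10, 0.5), rep(c(0, 1), 11)[1:21], 0)
  seg <- list(a = 1L, b = 2L, points = zig, radius = rep(1, 21))
  pos <- rbind(zig[1, ], zig[21, ])
  g <- perfuseMRI:::makeSpatialGraph(pos, list(seg))
  gs <- smoothLineSet(g, iterations = 10, smoothing = 0.5, attach = 0.25)
  before <- segmentMetrics(graphSegments(g)[[1]])$curved_length_mm
  after <- segmentMetrics(graphSegments(gs)[[1]])$curved_length_mm
  expect_lt(after, before)
  # node positions fixed
  expect_equal(graphSegments(gs)[[1]]$points[1, ], zig[1, ])
  expect_equal(graphSegments(gs)[[1]]$points[21, ], zig[21, ])
  # a straight polyline is a fixed point
  straight <- cbind(seq(0, 10, 1), 0, 0)
  seg2 <- list(a = 1L, b = 2L, points = straight, radius = rep(1, 11))
  g2 <- perfuseMRI:::makeSpatialGraph(rbind(straight[1, ], straight[11, ]),
                                      list(seg2))
  expect_equal(graphSegments(smoothLineSet(g2))[[1]]$points, straight)
  # attach = 1, smoothing = 0 is the identity
  gid <- smoothLineSet(g, iterations = 10, smoothing = 0, attach = 1)
  expect_equal(graphSegments(gid)[[1]]$points, zig)
})

test_that("radius assignment recovers cylinder radii and is spacing-invariant", {
  # 1 mm voxels: axis radii within 3 +/- 0.5 mm
  cyl <- cylinderMask(c(21, 21, 30), 3, 2:29)
  dm <- chamferDistanceMap(cyl)
  axis <- cbind(10.5, 10.5, seq(8, 22, 1))     # world mm, on-axis, away from caps
  seg <- list(a = 1L, b = 2L, points = axis, radius = rep(0, nrow(axis)))
  g <- perfuseMRI:::makeSpatialGraph(rbind(axis[1, ], axis[nrow(axis), ]),
                                     list(seg))
  gr <- assignRadii(g, dm)
  r1 <- graphSegments(gr)[[1]]$radius
  expect_true(all(abs(r1 - 3) <= 0.5 + 1e-9))
  # same physical cylinder at 2 mm voxels: radii unchanged within a coarser
  # half-voxel
  cyl2 <- cylinderMask(c(11, 11, 15), 1.5, 1:15, spacing = c(2, 2, 2))
  dm2 <- chamferDistanceMap(cyl2)
  axis2 <- cbind(10.5, 10.5, seq(8, 22, 1))
  seg2 <- list(a = 1L, b = 2L, points = axis2, radius = rep(0, nrow(axis2)))
  g2 <- perfuseMRI:::makeSpatialGraph(rbind(axis2[1, ], axis2[nrow(axis2), ]),
                                      list(seg2))
  r2 <- graphSegments(assignRadii(g2, dm2))[[1]]$radius
  expect_true(all(abs(r2 - r1) <= 1 + 1e-9))
  # a point on the mask surface has radius of at most one voxel
  surf <- cbind(10.5 + 3, 10.5, 15)
  sseg <- list(a = 1L, b = 2L, points = rbind(surf, surf + c(0, 0, 1)),
               radius = c(0, 0))
  gsurf <- perfuseMRI:::makeSpatialGraph(rbind(surf, surf + c(0, 0, 1)),
                                         list(sseg))
  rs <- graphSegments(assignRadii(gsurf, dm))[[1]]$radius
  expect_true(all(rs <= 1 + 1e-9))
  # off-mask points get radius 0 with a warning
  far <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 1.5))
  fseg <- list(a = 1L, b = 2L, points = far, radius = c(0, 0))
  gf <- perfuseMRI:::makeSpatialGraph(far, list(fseg))
  expect_warning(g0 <- assignRadii(gf, dm), "outside")
  expect_equal(graphSegments(g0)[[1]]$radius, c(0, 0))
})

test_that("full-chain recovery on a depth-2 phantom is topology-exact", {
  spec <- PhantomSpec(c(96, 96, 96), spacing = rep(1, 3), treeDepth = 2,
                      rootRadius = 3, radiusDecay = 0.8, segmentLength = 15,
                      tortuosityAmplitude = 0.8, seed = 7)
  gt <- generateVesselTree(spec)
  est <- extractVesselGraph(rasterizeTree(gt, spec))
  st <- networkSummary(gt)
  se <- networkSummary(est)
  expect_equal(se$n_branching_nodes, st$n_branching_nodes)   # 1 bifurcation
  expect_equal(se$n_terminal_nodes, st$n_terminal_nodes)     # 3 terminals
  expect_equal(se$mean_coordination_number, 3)
  expect_lt(abs(se$median_radius_mm - st$median_radius_mm) /
              st$median_radius_mm, 0.15)
  expect_lt(abs(se$median_tortuosity - st$median_tortuosity), 0.02)
})
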