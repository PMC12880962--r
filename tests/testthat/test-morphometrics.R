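test_that("segment metrics: lengths, tortuosity and frustum volume", {
  straight <- list(points = cbind(seq(0, 10, 1), 0, 0), radius = rep(2, 11))
  m <- segmentMetrics(straight)
  expect_equal(m$curved_length_mm, 10)
  expect_equal(m$straight_length_mm, 10)
  expect_equal(m$tortuosity, 1)
  expect_equal(m$volume_mm3, 40 * pi)           # cylinder of radius 2
  # semicircular arc: tortuosity pi/2 at fine sampling
  th <- seq(0, pi, length.out = 2001)
  arc <- list(points = cbind(5 - 5 * cos(th), 5 * sin(th), 0),
              radius = rep(1, 2001))
  expect_equal(segmentMetrics(arc)$tortuosity, pi / 2, tolerance = 1e-5)
  # closed loop: chord 0, tortuosity defined as 1
  loop <- list(points = cbind(cos(th * 2), sin(th * 2), 0),
               radius = rep(1, 2001))
  expect_equal(segmentMetrics(loop)$tortuosity, 1)
  expect_error(segmentMetrics(list(points = matrix(0, 1, 3), radius = 0)),
               "2 points")
})

test_that("network summary counts nodes and aggregates exactly on an enumerated tree", {
  # hand-built binary tree with a trunk: an inlet terminal feeding a root
  # branch point, two mid branch points, four leaves. Exhaustive count:
  # 3 branching nodes of degree 3, 5 terminals, fraction 5/8
  pos <- rbind(c(0, 0, -2),                        # 1 inlet terminal
               c(0, 0, 0),                         # 2 root branch point
               c(-2, 0, 1), c(2, 0, 1),            # 3, 4 branch points
               c(-3, 0, 2), c(-1, 0, 2), c(1, 0, 2), c(3, 0, 2))
  mkseg <- function(a, b) list(a = a, b = b,
                               points = rbind(pos[a, ], pos[b, ]),
                               radius = c(1, 1))
  segs <- list(mkseg(1L, 2L), mkseg(2L, 3L), mkseg(2L, 4L), mkseg(3L, 5L),
               mkseg(3L, 6L), mkseg(4L, 7L), mkseg(4L, 8L))
  g <- perfuseMRI:::makeSpatialGraph(pos, segs)
  s <- networkSummary(g)
  expect_equal(s$n_branching_nodes, 3L)
  expect_equal(s$n_terminal_nodes, 5L)
  expect_equal(s$terminal_fraction, 5 / 8)
  expect_equal(s$mean_coordination_number, 3)
  # a degree-2 node is excluded from both terminal and branching counts
  g2 <- perfuseMRI:::makeSpatialGraph(pos[1:3, ], list(mkseg(1L, 2L),
                                                       mkseg(2L, 3L)))
  s2 <- networkSummary(g2)
  expect_equal(s2$n_terminal_nodes, 2L)
  expect_equal(s2$n_branching_nodes, 0L)
  # single segment: 2 terminals, fraction 1
  s3 <- networkSummary(perfuseMRI:::makeSpatialGraph(pos[1:2, ],
                                                     list(mkseg(1L, 2L))))
  expect_equal(s3$terminal_fraction, 1)
  expect_error(networkSummary(new("SpatialGraph")), "empty")
})

test_that("totals are additive and tortuosity is rigid-motion invariant", {
  spec <- PhantomSpec(c(64, 64, 64), spacing = rep(1, 3), treeDepth = 3,
                      rootRadius = 3, segmentLength = 12,
                      tortuosityAmplitude = 1, seed = 5)
  g <- generateVesselTree(spec)
  s <- networkSummary(g)
  # additivity: per-segment sums equal the totals
  expect_equal(sum(s$segments$curved_length_mm), s$total_length_mm)
  expect_equal(sum(s$segments$volume_mm3), s$total_volume_mm3)
  # random rigid rotation + translation leaves tortuosity unchanged
  set.seed(8)
  for (rep in 1:3) {
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    tr <- rnorm(3, 0, 10)
    g2 <- g
    g2@segments <- lapply(g@segments, function(sg) {
      sg$points <- sweep(sg$points %*% R, 2, tr, "+")
      sg
    })
    g2@nodes[, c("x", "y", "z")] <-
      sweep(as.matrix(g@nodes[, c("x", "y", "z")]) %*% R, 2, tr, "+")
    s2 <- networkSummary(g2)
    expect_equal(s2$segments$tortuosity, s$segments$tortuosity,
                 tolerance = 1e-10)
    expect_equal(s2$total_length_mm, s$total_length_mm, tolerance = 1e-10)
  }
  # phantom trees are pure bifurcations: mean coordination exactly 3
  expect_equal(s$mean_coordination_number, 3)
})
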