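# Independent oracles and small fixture builders, used across the suite.

# solid cylinder mask along z; axis at (cx, cy) in voxel index units
cylinderMask <- function(dims, radius_vox, zRange, cx = (dims[1] + 1) / 2,
                         cy = (dims[2] + 1) / 2, spacing = c(1, 1, 1)) {
  v <- array(FALSE, dims)
  cc <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  sel <- (cc$x - cx)^2 + (cc$y - cy)^2 <= radius_vox^2 + 1e-9
  for (z in zRange) v[cbind(cc$x[sel], cc$y[sel], z)] <- TRUE
  BinaryMask(v, spacing = spacing)
}

# exact multi-source Dijkstra chamfer oracle on the 26-neighbour voxel graph
# (igraph backend); independent of the two-pass sweep it checks. Out-of-grid
# counts as background (the transform's convention), realized by padding.
bruteChamfer <- function(mask, weights = c(3, 4, 5)) {
  d0 <- dim(voxelData(mask))
  padded <- array(FALSE, d0 + 2L)
  padded[2:(d0[1] + 1), 2:(d0[2] + 1), 2:(d0[3] + 1)] <- voxelData(mask)
  mask <- BinaryMask(padded)
  d <- dim(voxelData(mask))
  n <- prod(d)
  fg <- as.vector(voxelData(mask))
  coords <- arrayInd(seq_len(n), d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
               (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    to <- coords[, 1] + offs[r, 1]
    tj <- coords[, 2] + offs[r, 2]
    tk <- coords[, 3] + offs[r, 3]
    ok <- to >= 1 & to <= d[1] & tj >= 1 & tj <= d[2] & tk >= 1 & tk <= d[3]
    from <- which(ok)
    dest <- to[ok] + (tj[ok] - 1) * d[1] + (tk[ok] - 1) * d[1] * d[2]
    ef <- c(ef, from); et <- c(et, dest)
    ew <- c(ew, rep(weights[sum(abs(offs[r, ]))], length(from)))
  }
  bg <- which(!fg)
  g <- igraph::make_graph(rbind(c(ef, bg), c(et, rep(n + 1L, length(bg)))),
                          n = n + 1L, directed = FALSE)
  dist <- igraph::distances(g, v = n + 1L,
                            weights = c(ew, rep(0, length(bg))))[1, ]
  out <- dist[seq_len(n)]
  out[!fg] <- 0
  dim(out) <- d
  out[2:(d0[1] + 1), 2:(d0[2] + 1), 2:(d0[3] + 1)]
}

# brute-force breadth-first flood fill oracle for seeded region growing
bruteFloodFill <- function(vol, seeds, low, high, connectivity) {
  v <- voxelData(vol)
  d <- dim(v)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  inMask <- array(FALSE, d)
  queue <- list()
  for (r in seq_len(nrow(seeds))) {
    s <- seeds[r, ]
    if (v[s[1], s[2], s[3]] >= low && v[s[1], s[2], s[3]] <= high &&
        !inMask[s[1], s[2], s[3]]) {
      inMask[s[1], s[2], s[3]] <- TRUE
      queue[[length(queue) + 1L]] <- s
    }
  }
  while (length(queue)) {
    cur <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (r in seq_len(nrow(offs))) {
      w <- cur + offs[r, ]
      if (any(w < 1) || any(w > d)) next
      if (!inMask[w[1], w[2], w[3]] && v[w[1], w[2], w[3]] >= low &&
          v[w[1], w[2], w[3]] <= high) {
        inMask[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1L]] <- w
      }
    }
  }
  inMask
}

# random blobby test mask: union of a few random balls plus salt speckle
randomMask <- function(dims, nBalls = 3, speckle = 0.02) {
  v <- array(FALSE, dims)
  coords <- arrayInd(seq_len(prod(dims)), dims)
  for (b in seq_len(nBalls)) {
    ctr <- runif(3, 3, dims - 2)
    r <- runif(1, 1.5, max(2.5, min(dims) / 4))
    v[rowSums(sweep(coords, 2, ctr)^2) <= r^2] <- TRUE
  }
  v[runif(prod(dims)) < speckle] <- TRUE
  BinaryMask(v)
}

# the stated-world phantom used by graph-recovery checks
recoveryPhantomSpec <- function(seed = 1L) {
  PhantomSpec(c(140, 140, 120), spacing = rep(0.83, 3), treeDepth = 4L,
              rootRadius = 4, radiusDecay = 0.75, segmentLength = 16,
              tortuosityAmplitude = 0.8, seed = seed)
}

# straight long-root phantom for DCE checks: one vessel along z
dcePhantomSpec <- function(seed = 1L) {
  PhantomSpec(c(24, 24, 130), spacing = rep(1, 3), treeDepth = 1L,
              rootRadius = 3, radiusDecay = 1, segmentLength = 110,
              tortuosityAmplitude = 0, seed = seed)
}
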