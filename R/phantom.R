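# Synthetic vascular phantoms with analytic ground truth: a binary
# bifurcating tree (all internal nodes are coordination-3 bifurcations,
# radii taper geometrically per generation, tortuosity induced by a
# half-sine lateral displacement), rasterized as a capsule union, plus
# simulators for T2-like contrast, multi-b DWI, a DCE bolus advancing along
# the tree, and biopsy-level histology score tables.

# evaluate expr under a temporary RNG state; the caller's stream is untouched
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  expr
}

#' Describe a synthetic vascular phantom
#'
#' @param gridShape voxel counts per axis (length 3).
#' @param spacing voxel spacing in mm (length 3, isotropic recommended).
#' @param treeDepth branching generations; generation 1 is the root
#'   segment, each later generation bifurcates, so the tree has
#'   `2^treeDepth - 1` segments.
#' @param rootRadius root vessel radius in mm (must be at least twice the
#'   coarsest voxel so the root is resolvable).
#' @param radiusDecay radius multiplier per generation, in (0, 1].
#' @param segmentLength straight (chord) length of each segment in mm.
#' @param tortuosityAmplitude amplitude (mm) of the half-sine lateral
#'   displacement added to each chord; 0 gives straight segments.
#' @param seed integer seed controlling branch azimuths.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- PhantomSpec(c(64, 64, 64), spacing = rep(1, 3), treeDepth = 3)
#' @export
PhantomSpec <- function(gridShape, spacing = c(1, 1, 1), treeDepth = 4L,
                        rootRadius = 4, radiusDecay = 0.75,
                        segmentLength = 20, tortuosityAmplitude = 1,
                        seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacing = rep_len(as.numeric(spacing), 3L),
      treeDepth = as.integer(treeDepth), rootRadius = as.numeric(rootRadius),
      radiusDecay = as.numeric(radiusDecay),
      segmentLength = as.numeric(segmentLength),
      tortuosityAmplitude = as.numeric(tortuosityAmplitude),
      seed = as.integer(seed))
}

unitPerp <- function(u) {
  # an arbitrary unit vector perpendicular to u
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v / sqrt(sum(v^2))
}

# polyline for one segment: chord from p0 along unit dir u, length L, plus a
# half-sine lateral displacement of amplitude A along unit normal nrm
segmentPolyline <- function(p0, u, L, A, nrm, step) {
  n <- max(9L, as.integer(ceiling(L / step)) * 2L + 1L)
  t <- seq(0, 1, length.out = n)
  P <- outer(t * L, u)
  P <- sweep(P, 2, p0, "+")
  if (A > 0) P <- P + outer(A * sin(pi * t), nrm)
  P
}

#' Generate a ground-truth vessel tree
#'
#' Grows a binary bifurcating tree: one inlet segment, then each tip splits
#' into two children whose directions deviate from the parent by a fixed
#' half-angle in a randomly oriented plane. Radii taper by `radiusDecay`
#' per generation, and each segment's polyline is its straight chord plus a
#' half-sine lateral displacement of amplitude `tortuosityAmplitude`
#' (endpoints unperturbed, so nodes are exact). Deterministic for a fixed
#' `seed`. Node 1 is the inlet.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [SpatialGraph-class] with per-point radii in mm and the inlet
#'   set.
#' @export
generateVesselTree <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    extent <- spec@gridShape * spec@spacing
    step <- min(spec@spacing)
    margin <- spec@rootRadius + 2 * max(spec@spacing)
    p0 <- c(extent[1] / 2, extent[2] / 2, margin)
    halfAngle <- 37 * pi / 180
    nodePos <- matrix(p0, 1, 3)
    segments <- list()
    addNode <- function(p) {
      nodePos <<- rbind(nodePos, p)
      nrow(nodePos)
    }
    checkBounds <- function(P, r, gen) {
      lo <- sweep(P, 2, rep(r, 3) * 0 + r, "-")
      hi <- sweep(P, 2, rep(r, 3) * 0 + r, "+")
      if (any(lo < 0) || any(t(hi) > extent))
        stop(sprintf(
          "vessel tree exits the grid bounds at generation %d; enlarge gridShape or shorten segments",
          gen))
    }
    # tips: list of (nodeIdx, position, direction)
    tips <- list(list(node = 1L, p = p0, u = c(0, 0, 1)))
    for (gen in seq_len(spec@treeDepth)) {
      r <- spec@rootRadius * spec@radiusDecay^(gen - 1)
      newTips <- list()
      for (tip in tips) {
        kids <- if (gen == 1L) {
          list(tip$u)                          # root: a single segment
        } else {
          e1 <- unitPerp(tip$u)
          e2 <- pracCross(tip$u, e1)
          phi <- runif(1, 0, 2 * pi)
          w <- cos(phi) * e1 + sin(phi) * e2
          list(cos(halfAngle) * tip$u + sin(halfAngle) * w,
               cos(halfAngle) * tip$u - sin(halfAngle) * w)
        }
        for (u in kids) {
          u <- u / sqrt(sum(u^2))
          nrm <- {
            e1 <- unitPerp(u)
            e2 <- pracCross(u, e1)
            psi <- runif(1, 0, 2 * pi)
            cos(psi) * e1 + sin(psi) * e2
          }
          P <- segmentPolyline(tip$p, u, spec@segmentLength,
                               spec@tortuosityAmplitude, nrm, step)
          checkBounds(P, r, gen)
          endIdx <- addNode(P[nrow(P), ])
          segments[[length(segments) + 1L]] <- list(
            a = tip$node, b = endIdx, points = P,
            radius = rep(r, nrow(P)))
          newTips[[length(newTips) + 1L]] <-
            list(node = endIdx, p = P[nrow(P), ], u = u)
        }
      }
      tips <- newTips
    }
    makeSpatialGraph(nodePos, segments, inlet = 1L)
  })
}

pracCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rasterize a vessel tree as a binary volume
#'
#' A voxel is foreground iff its center lies within the locally
#' interpolated radius of any segment polyline (capsule union), so the
#' voxel-count volume approximates the analytic tree volume as spacing
#' shrinks. Branches with radius below half a voxel trigger a warning:
#' such vessels are at or beyond the resolution limit and may not survive
#' rasterization.
#'
#' @param graph a [SpatialGraph-class] with radii.
#' @param spec a [PhantomSpec-class] supplying grid shape and spacing.
#' @return A [BinaryMask-class] with origin 0.
#' @export
rasterizeTree <- function(graph, spec) {
  stopifnot(is(graph, "SpatialGraph"), is(spec, "PhantomSpec"))
  if (length(graph@segments)) {
    rmin <- min(vapply(graph@segments, function(s) min(s$radius), numeric(1)))
    if (rmin < max(spec@spacing) / 2)
      warning(sprintf(
        "smallest branch radius (%.3g mm) is below half a voxel (%.3g mm); it may be unresolvable",
        rmin, max(spec@spacing) / 2))
  }
  segs <- lapply(graph@segments, function(s) cbind(s$points, s$radius))
  m <- cpp_rasterize(segs, spec@gridShape, spec@spacing, c(0, 0, 0))
  BinaryMask(m, spacing = spec@spacing, origin = c(0, 0, 0))
}

#' Simulate a T2-weighted structural volume from a vessel mask
#'
#' Vessel voxels draw from `Normal(vesselIntensity, noiseSd)`, parenchyma
#' from `Normal(parenchymaIntensity, noiseSd)`, clipped at zero.
#'
#' @param mask a [BinaryMask-class] of the vasculature.
#' @param vesselIntensity,parenchymaIntensity mean signal levels (distinct).
#' @param noiseSd Gaussian noise standard deviation (`>= 0`).
#' @param seed integer seed.
#' @return An [ImageVolume-class].
#' @export
simulateT2Volume <- function(mask, vesselIntensity = 200,
                             parenchymaIntensity = 100, noiseSd = 0,
                             seed = 1L) {
  stopifnot(is(mask, "BinaryMask"))
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (vesselIntensity == parenchymaIntensity)
    stop("vessel and parenchyma intensities must be distinct")
  withSeed(seed, {
    d <- dim(mask@values)
    vals <- array(parenchymaIntensity, d)
    vals[mask@values] <- vesselIntensity
    if (noiseSd > 0) vals <- vals + array(rnorm(prod(d), 0, noiseSd), d)
    vals[vals < 0] <- 0
    ImageVolume(vals, spacing = mask@spacing, origin = mask@origin)
  })
}

#' Simulate a multi-b, multi-direction DWI series
#'
#' Noise-free signal is the monoexponential `S0 * exp(-D * b)` per voxel.
#' Optional noise is Gaussian on two quadrature channels followed by the
#' magnitude (Rician at low SNR), the standard MR noise model.
#'
#' @param trueD a numeric 3D array (or [ImageVolume-class]) of true D in
#'   mm^2/s, or a list of such arrays (one per direction) for anisotropic
#'   phantoms.
#' @param S0 zero-b signal level.
#' @param bValues positive distinct b-values in s/mm^2; the default is the
#'   four-shell protocol `c(90, 500, 1500, 2000)`.
#' @param directions number of diffusion directions (default 3).
#' @param noiseSd channel noise standard deviation.
#' @param seed integer seed.
#' @param spacing voxel spacing of the output volumes (mm).
#' @return A list of class `DwiSeries`: `volumes[[direction]][[b-index]]`
#'   ([ImageVolume-class]), `bValues`, `directions`.
#' @export
simulateDwi <- function(trueD, S0 = 100, bValues = c(90, 500, 1500, 2000),
                        directions = 3L, noiseSd = 0, seed = 1L,
                        spacing = c(1, 1, 1)) {
  if (any(bValues <= 0) || anyDuplicated(bValues))
    stop("bValues must be positive and distinct")
  getMap <- function(i) {
    m <- if (is.list(trueD)) trueD[[i]] else trueD
    if (is(m, "ImageVolume")) { spacing <- m@spacing; m <- m@values }
    if (any(m < 0)) stop("true D map must be >= 0")
    m
  }
  withSeed(seed, {
    vols <- lapply(seq_len(directions), function(dir) {
      D <- getMap(dir)
      lapply(bValues, function(b) {
        S <- S0 * exp(-D * b)
        if (noiseSd > 0) {
          n <- prod(dim(D))
          S <- sqrt((S + array(rnorm(n, 0, noiseSd), dim(D)))^2 +
                    array(rnorm(n, 0, noiseSd), dim(D))^2)
        }
        ImageVolume(S, spacing = spacing)
      })
    })
    structure(list(volumes = vols, bValues = bValues,
                   directions = directions), class = "DwiSeries")
  })
}

gammaVariateKernel <- function(tau, peakTime = 30, shape = 2) {
  out <- numeric(length(tau))
  pos <- tau > 0
  out[pos] <- (tau[pos] / peakTime)^shape * exp(shape * (1 - tau[pos] / peakTime))
  out
}

#' Simulate a DCE time series of a bolus advancing along the tree
#'
#' Each vessel voxel is attached to its nearest centerline point; the voxel
#' starts to enhance when the bolus front — at path distance
#' `velocity * elapsed time` from the inlet — passes that point. The
#' default kernel is step-and-hold (the voxel stays enhanced after
#' arrival), so time-to-peak equals the arrival frame; a gamma-variate
#' kernel is available for realistic rise-and-fall curve shapes.
#'
#' @param graph a [SpatialGraph-class] with a designated inlet node.
#' @param mask the rasterized vessel [BinaryMask-class].
#' @param velocityCmPerMin bolus front speed (`>= 0`).
#' @param frameIntervalS seconds per frame, in `[1, 60]`.
#' @param nFrames number of frames.
#' @param bolusAmplitude enhancement added at/after arrival.
#' @param baseline pre-contrast signal everywhere.
#' @param kernel `"step"` (default) or `"gamma"`.
#' @param gammaPeakS,gammaShape gamma-variate kernel parameters (time to
#'   kernel peak in seconds, shape exponent).
#' @param noiseSd optional Gaussian noise.
#' @param seed integer seed.
#' @return A 4D [ImageVolume-class] with the stated frame interval.
#' @export
simulateDce <- function(graph, mask, velocityCmPerMin = 30,
                        frameIntervalS = 10, nFrames = 24,
                        bolusAmplitude = 100, baseline = 20,
                        kernel = c("step", "gamma"), gammaPeakS = 30,
                        gammaShape = 2, noiseSd = 0, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(is(graph, "SpatialGraph"), is(mask, "BinaryMask"))
  if (velocityCmPerMin < 0) stop("velocity must be >= 0")
  if (frameIntervalS < 1 || frameIntervalS > 60)
    stop("frameIntervalS must lie in [1, 60] seconds")
  if (is.na(graph@inlet)) stop("graph has no designated inlet node")
  pd <- graphPathDistances(graph)
  ctr <- do.call(rbind, lapply(graph@segments, function(s) s$points))
  ctrDist <- unlist(pd$segments)
  d <- dim(mask@values)
  vox <- which(mask@values)
  out <- array(baseline, c(d, nFrames))
  if (length(vox)) {
    vc <- arrayInd(vox, d)
    vcmm <- sweep(sweep(vc - 0.5, 2, mask@spacing, "*"), 2, mask@origin, "+")
    nn <- FNN::get.knnx(ctr, vcmm, k = 1)$nn.index[, 1]
    pathMm <- ctrDist[nn]
    vel_mm_s <- velocityCmPerMin * 10 / 60
    arrival <- if (vel_mm_s > 0) pathMm / vel_mm_s else
      ifelse(pathMm <= 1e-9, 0, Inf)
    for (k in seq_len(nFrames)) {
      t_k <- (k - 1) * frameIntervalS
      enh <- if (kernel == "step") bolusAmplitude * (t_k >= arrival) else
        bolusAmplitude * gammaVariateKernel(t_k - arrival, gammaPeakS,
                                            gammaShape)
      frame <- array(baseline, d)
      frame[vox] <- baseline + enh
      out[, , , k] <- frame
    }
  }
  if (noiseSd > 0)
    out <- withSeed(seed, out + array(rnorm(length(out), 0, noiseSd), dim(out)))
  ImageVolume(out, spacing = mask@spacing, frameInterval = frameIntervalS,
              origin = mask@origin)
}

#' Reference group means for the histology simulator
#'
#' The per-category mean scores used as the simulator's default stated
#' world: machine-perfused vs static-cold-storage livers at baseline and
#' after 30 minutes, categories neutrophil infiltration, hepatocyte
#' necrosis, sinusoidal congestion and sinusoidal oedema (each 0-3).
#'
#' @return A data.frame with columns `group`, `timepoint`, `neutrophil`,
#'   `necrosis`, `congestion`, `oedema`.
#' @export
histologyReferenceMeans <- function() {
  data.frame(
    group = c("Perfused", "SCS", "Perfused", "SCS"),
    timepoint = c("Baseline", "Baseline", "30 min", "30 min"),
    neutrophil = c(1.0, 1.0, 1.1, 2.9),
    necrosis = c(1.3, 1.6, 2.2, 3.0),
    congestion = c(2.1, 2.0, 2.1, 3.0),
    oedema = c(1.9, 2.0, 3.0, 3.0))
}

#' Simulate biopsy-level histology score tables
#'
#' Integer category scores in 0..3 are drawn around the stated means: the
#' base draw splits between `floor(mean)` and `ceiling(mean)` with
#' probability equal to the fractional part (so the expectation equals the
#' stated mean exactly), then optional integer jitter of standard
#' deviation `dispersion` is added and the result clamped to 0..3. The
#' composite score of each record is the sum of its four categories.
#'
#' @param groupMeans data.frame with columns `group`, `timepoint` and the
#'   four category means in `[0, 3]`; defaults to
#'   [histologyReferenceMeans()].
#' @param dispersion standard deviation of the integer jitter (`>= 0`).
#' @param nBiopsies biopsies per group x timepoint cell (default 3).
#' @param seed integer seed.
#' @return data.frame with columns `group`, `timepoint`, `biopsy_id`,
#'   `neutrophil`, `necrosis`, `congestion`, `oedema`, `composite`.
#' @export
simulateHistology <- function(groupMeans = histologyReferenceMeans(),
                              dispersion = 0.3, nBiopsies = 3L, seed = 1L) {
  cats <- c("neutrophil", "necrosis", "congestion", "oedema")
  stopifnot(all(c("group", "timepoint", cats) %in% names(groupMeans)))
  mm <- as.matrix(groupMeans[, cats])
  if (any(mm < 0) || any(mm > 3))
    stop("category means must lie within [0, 3]")
  if (dispersion < 0) stop("dispersion must be >= 0")
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(nrow(groupMeans))) {
      for (b in seq_len(nBiopsies)) {
        sc <- vapply(cats, function(cn) {
          m <- groupMeans[[cn]][i]
          base <- floor(m) + rbinom(1, 1, m - floor(m))
          if (dispersion > 0) base <- base + round(rnorm(1, 0, dispersion))
          min(3L, max(0L, as.integer(base)))
        }, integer(1))
        rows[[length(rows) + 1L]] <- data.frame(
          group = groupMeans$group[i], timepoint = groupMeans$timepoint[i],
          biopsy_id = b, t(sc), composite = sum(sc))
      }
    }
    do.call(rbind, rows)
  })
}
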