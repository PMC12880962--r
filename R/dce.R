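# Semi-quantitative DCE analysis: voxel-wise time-to-peak maps, ROI
# enhancement curves with a min/max envelope over repeats, bolus-front
# tracking along a centerline path, velocity regression and the volumetric
# flow relation Q = (1/4) * pi * d^2 * v.

#' Voxel-wise time-to-peak map
#'
#' Enhancement is the signal minus the mean over the baseline frames; TTP
#' is the frame interval times the index (from scan start) of the first
#' frame attaining the maximal enhancement — the first-maximum rule makes
#' plateaus deterministic. Voxels whose peak enhancement stays below
#' `noiseFloor` are flagged invalid.
#'
#' @param vol4d a 4D [ImageVolume-class].
#' @param baselineFrames number of leading pre-contrast frames (`>= 1`,
#'   fewer than the total frame count).
#' @param noiseFloor minimal peak enhancement for a voxel to count.
#' @return A [TTPMap-class] in seconds.
#' @export
ttpMap <- function(vol4d, baselineFrames = 1L, noiseFloor = 0) {
  stopifnot(is(vol4d, "ImageVolume"))
  d <- dim(vol4d@values)
  if (length(d) != 4L) stop("ttpMap requires a 4D volume")
  if (baselineFrames < 1L || baselineFrames >= d[4])
    stop("baselineFrames must be >= 1 and < the number of frames")
  nvox <- prod(d[1:3])
  m <- matrix(vol4d@values, nvox, d[4])
  base <- rowMeans(m[, seq_len(baselineFrames), drop = FALSE])
  enh <- m - base
  peak <- do.call(pmax, lapply(seq_len(d[4]), function(t) enh[, t]))
  idx <- max.col(enh, ties.method = "first")
  ttp <- (idx - 1) * vol4d@frameInterval
  valid <- peak > noiseFloor
  ttp[!valid] <- NA_real_
  dim(ttp) <- d[1:3]
  dim(valid) <- d[1:3]
  new("TTPMap", values = ttp, spacing = vol4d@spacing,
      frameInterval = vol4d@frameInterval, origin = vol4d@origin,
      valid = valid)
}

#' ROI enhancement curve with a repeat envelope
#'
#' For each repeat, the curve is the mean signal of a square
#' `roiSize x roiSize` in-plane region (fixed z) per frame; the output
#' reports the mean, minimum and maximum across repeats at every time
#' point. When a vessel mask is supplied, each ROI must lie entirely
#' within it, mirroring the requirement that ROIs sit wholly inside the
#' vessel.
#'
#' @param vol4d a 4D [ImageVolume-class].
#' @param roiCenters matrix of 1-based voxel centers `(x, y, z)`, one row
#'   per repeat (typically 3).
#' @param roiSize in-plane ROI edge length in voxels (default 10).
#' @param vesselMask optional [BinaryMask-class] for the containment check.
#' @return A list of class `EnhancementCurve`: `times_s`, `mean_signal`,
#'   `min_signal`, `max_signal`, `roi` (descriptor).
#' @export
roiEnhancementCurve <- function(vol4d, roiCenters, roiSize = 10L,
                                vesselMask = NULL) {
  stopifnot(is(vol4d, "ImageVolume"))
  d <- dim(vol4d@values)
  if (length(d) != 4L) stop("roiEnhancementCurve requires a 4D volume")
  if (!is.matrix(roiCenters)) roiCenters <- matrix(roiCenters, ncol = 3,
                                                   byrow = TRUE)
  half <- roiSize %/% 2L
  curves <- matrix(NA_real_, nrow(roiCenters), d[4])
  for (r in seq_len(nrow(roiCenters))) {
    cx <- roiCenters[r, 1]; cy <- roiCenters[r, 2]; cz <- roiCenters[r, 3]
    xs <- (cx - half):(cx - half + roiSize - 1L)
    ys <- (cy - half):(cy - half + roiSize - 1L)
    if (min(xs) < 1L || max(xs) > d[1] || min(ys) < 1L || max(ys) > d[2] ||
        cz < 1L || cz > d[3])
      stop(sprintf("ROI repeat %d extends outside the grid", r))
    if (!is.null(vesselMask) && !all(vesselMask@values[xs, ys, cz]))
      stop(sprintf("ROI repeat %d is not entirely within the vessel mask", r))
    curves[r, ] <- apply(vol4d@values[xs, ys, cz, , drop = FALSE], 4, mean)
  }
  times <- (seq_len(d[4]) - 1) * vol4d@frameInterval
  structure(list(times_s = times,
                 mean_signal = colMeans(curves),
                 min_signal = apply(curves, 2, min),
                 max_signal = apply(curves, 2, max),
                 roi = list(centers = roiCenters, size = roiSize)),
            class = "EnhancementCurve")
}

#' Track the bolus front along a centerline path
#'
#' Per frame, the front position is the arc-length coordinate of the
#' farthest path point whose enhancement has reached `thresholdFraction`
#' of that point's eventual maximum enhancement (half-max arrival by
#' default). Front distances are made non-decreasing in time (a front
#' cannot retreat).
#'
#' @param vol4d a 4D [ImageVolume-class].
#' @param path ordered matrix of world-mm points from the inlet outwards
#'   (e.g. a segment polyline).
#' @param thresholdFraction arrival threshold in (0, 1), default 0.5.
#' @param baselineFrames frames used as pre-contrast baseline.
#' @return data.frame with columns `time_s` and `front_distance_cm`.
#' @export
trackBolusFront <- function(vol4d, path, thresholdFraction = 0.5,
                            baselineFrames = 1L) {
  stopifnot(is(vol4d, "ImageVolume"))
  d <- dim(vol4d@values)
  if (length(d) != 4L) stop("trackBolusFront requires a 4D volume")
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie in (0, 1)")
  if (!is.matrix(path) || ncol(path) != 3L || nrow(path) < 2L)
    stop("path must be an n x 3 matrix of world points")
  arc_mm <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  n <- nrow(path)
  sig <- matrix(NA_real_, n, d[4])
  for (i in seq_len(n)) {
    v <- worldToVoxel(vol4d, path[i, ])
    sig[i, ] <- vol4d@values[v[1], v[2], v[3], ]
  }
  base <- rowMeans(sig[, seq_len(baselineFrames), drop = FALSE])
  enh <- sig - base
  peak <- apply(enh, 1, max)
  if (all(peak <= 0))
    stop("no path point ever enhances above baseline")
  arrived <- enh >= thresholdFraction * peak & peak > 0
  front <- numeric(d[4])
  for (t in seq_len(d[4])) {
    idx <- which(arrived[, t])
    front[t] <- if (length(idx)) arc_mm[max(idx)] else 0
  }
  front <- cummax(front) / 10                 # mm -> cm, monotone
  data.frame(time_s = (seq_len(d[4]) - 1) * vol4d@frameInterval,
             front_distance_cm = front)
}

#' Estimate bolus velocity from a front trajectory
#'
#' The velocity is the least-squares slope of front distance versus time,
#' converted to cm/min; the uncertainty is the standard deviation of the
#' per-interval speeds. Only the transit window is used: frames after the
#' front first reaches its final position are a plateau (the bolus has left
#' the path) and would bias the slope towards zero, so they are dropped,
#' along with the attainment frame itself when enough moving samples
#' remain (its true crossing time lies somewhere inside the previous
#' frame interval).
#'
#' @param front data.frame with `time_s` and `front_distance_cm` (from
#'   [trackBolusFront()]), at least two rows.
#' @return A list: `velocity_cm_per_min`, `sd_cm_per_min`.
#' @examples
#' estimateVelocity(data.frame(time_s = c(0, 10, 20),
#'                             front_distance_cm = c(0, 5, 10)))
#' @export
estimateVelocity <- function(front) {
  if (nrow(front) < 2L) stop("at least two front samples are required")
  t <- front$time_s
  x <- front$front_distance_cm
  iAtt <- which(x >= max(x) - 1e-12)[1]
  keep <- seq_len(iAtt)
  if (length(keep) > 3L) keep <- keep[-length(keep)]
  if (length(keep) >= 2L) {
    t <- t[keep]
    x <- x[keep]
  }
  slope <- sum((t - mean(t)) * (x - mean(x))) / sum((t - mean(t))^2)
  dt <- diff(t)
  speeds <- diff(x) / dt * 60               # cm/s -> cm/min
  list(velocity_cm_per_min = slope * 60,
       sd_cm_per_min = if (length(speeds) > 1) stats::sd(speeds) else 0)
}

#' Volumetric flow from diameter and velocity
#'
#' `Q = (1/4) * pi * d^2 * v`: with the diameter in cm and the velocity in
#' cm/min, the flow is in mL/min.
#'
#' @param diameterCm vessel diameter d (cm, `>= 0`).
#' @param velocityCmPerMin fluid velocity v (cm/min, `>= 0`).
#' @return Flow Q in mL/min.
#' @examples
#' volumetricFlow(1, 4 / pi)   # exactly 1 mL/min
#' @export
volumetricFlow <- function(diameterCm, velocityCmPerMin) {
  if (any(diameterCm < 0) || any(velocityCmPerMin < 0))
    stop("diameter and velocity must be >= 0")
  0.25 * pi * diameterCm^2 * velocityCmPerMin
}
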