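# Separable resampling with cubic BC-spline (Mitchell), linear or nearest
# kernels. The Mitchell-Netravali filter is used at its published setting
# B = C = 1/3. Border handling: weights are renormalized to sum to one, so a
# constant image is reproduced exactly everywhere (partition of unity).

mitchellKernel <- function(x, B = 1 / 3, C = 1 / 3) {
  ax <- abs(x)
  out <- numeric(length(x))
  i1 <- ax < 1
  i2 <- ax >= 1 & ax < 2
  out[i1] <- ((12 - 9 * B - 6 * C) * ax[i1]^3 +
              (-18 + 12 * B + 6 * C) * ax[i1]^2 + (6 - 2 * B)) / 6
  out[i2] <- ((-B - 6 * C) * ax[i2]^3 + (6 * B + 30 * C) * ax[i2]^2 +
              (-12 * B - 48 * C) * ax[i2] + (8 * B + 24 * C)) / 6
  out
}

# weight matrix mapping n_in samples at spacing s_in to n_out at s_out;
# both grids share the same mm extent and the half-voxel center convention
resampleWeights <- function(n_in, s_in, n_out, s_out, method) {
  support <- switch(method, mitchell = 2, linear = 1, nearest = 0.5)
  kern <- switch(method,
    mitchell = mitchellKernel,
    linear = function(x) pmax(0, 1 - abs(x)),
    nearest = function(x) as.numeric(abs(x) <= 0.5 + 1e-12))
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    u <- ((i - 0.5) * s_out) / s_in + 0.5      # position in input index units
    j0 <- max(1L, as.integer(ceiling(u - support)))
    j1 <- min(n_in, as.integer(floor(u + support)))
    if (j1 < j0) { j0 <- j1 <- min(n_in, max(1L, as.integer(round(u)))) }
    j <- j0:j1
    w <- kern(u - j)
    if (method == "nearest" && sum(w) > 1) w <- w * cumsum(w == max(w))
    s <- sum(w)
    if (s <= 0) { w <- rep(0, length(j)); w[which.min(abs(u - j))] <- 1; s <- 1 }
    W[i, j] <- w / s
  }
  W
}

applyAlongAxis <- function(vals, axis, W) {
  d <- dim(vals)
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- matrix(aperm(vals, perm), nrow = d[axis])
  m2 <- W %*% m
  out <- array(m2, dim = c(nrow(W), d[-axis]))
  aperm(out, order(perm))
}

#' Resample a volume to isotropic voxels
#'
#' Resamples all spatial axes to a common target spacing, preserving the mm
#' extent of the grid within one voxel. The default kernel is the
#' Mitchell-Netravali cubic at its published "Mitchell" setting
#' (B = C = 1/3); `linear` and `nearest` are also available (`nearest` is
#' what binary masks should use to stay binary). Axes already at the target
#' spacing are passed through untouched, so resampling an isotropic volume
#' to its own spacing is the identity.
#'
#' @param vol an [ImageVolume-class] (3D, or 4D — spatial axes only).
#' @param targetSpacing isotropic target spacing in mm.
#' @param method one of `"mitchell"`, `"linear"`, `"nearest"`.
#' @return An [ImageVolume-class] with `spacing = rep(targetSpacing, 3)`.
#' @examples
#' vol <- ImageVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4)),
#'                    spacing = c(0.83, 0.83, 5))
#' iso <- resampleIsotropic(vol, 0.83)
#' spacingMm(iso)
#' @export
resampleIsotropic <- function(vol, targetSpacing,
                              method = c("mitchell", "linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is(vol, "ImageVolume"))
  if (targetSpacing <= 0) stop("target spacing must be positive")
  d <- dim(vol@values)
  extent <- d[1:3] * vol@spacing
  if (targetSpacing > min(extent))
    stop(sprintf("target spacing (%g mm) exceeds the grid extent (%g mm)",
                 targetSpacing, min(extent)))
  vals <- vol@values
  for (axis in 1:3) {
    if (abs(vol@spacing[axis] - targetSpacing) < 1e-12) next
    n_out <- max(1L, as.integer(round(extent[axis] / targetSpacing)))
    W <- resampleWeights(d[axis], vol@spacing[axis], n_out, targetSpacing,
                         method)
    vals <- applyAlongAxis(vals, axis, W)
  }
  ImageVolume(vals, spacing = rep(targetSpacing, 3),
              frameInterval = vol@frameInterval, origin = vol@origin)
}

#' Maximum intensity projection through time
#'
#' Collapses a 4D volume to 3D by taking, per voxel, the maximum over all
#' frames. Applied to binary per-frame labels this yields the union mask of
#' everything that enhanced at any time.
#'
#' @param vol4d a 4D [ImageVolume-class].
#' @return A 3D [ImageVolume-class].
#' @export
mipOverTime <- function(vol4d) {
  stopifnot(is(vol4d, "ImageVolume"))
  d <- dim(vol4d@values)
  if (length(d) != 4L) stop("mipOverTime requires a 4D volume")
  m <- matrix(vol4d@values, prod(d[1:3]), d[4])
  out <- do.call(pmax, lapply(seq_len(d[4]), function(t) m[, t]))
  dim(out) <- d[1:3]
  ImageVolume(out, spacing = vol4d@spacing, origin = vol4d@origin)
}
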