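# Voxel-wise ADC mapping: log-linear least squares of ln(S) on b per
# direction, direction maps averaged arithmetically. Closed-form and exact
# on noise-free monoexponential input.

#' Fit the monoexponential diffusion model at one voxel
#'
#' Least-squares regression of `ln(S)` on `b` for the model
#' `S = S0 * exp(-D * b)`: `D = -slope`, `S0 = exp(intercept)`. Exact on
#' noise-free input. Voxels with any non-positive signal cannot be
#' log-transformed and are flagged invalid.
#'
#' @param signals signal magnitudes, one per b-value.
#' @param bValues b-values in s/mm^2 (at least two, distinct).
#' @return A list: `S0`, `D` (mm^2/s), `residual` (RMS of log residuals),
#'   `valid`.
#' @examples
#' fitAdcVoxel(100 * exp(-1e-3 * c(90, 500, 1500, 2000)),
#'             c(90, 500, 1500, 2000))$D   # 1e-3
#' @export
fitAdcVoxel <- function(signals, bValues) {
  if (length(unique(bValues)) < 2L)
    stop("at least two distinct b-values are required")
  if (length(signals) != length(bValues))
    stop("one signal per b-value required")
  if (any(signals <= 0))
    return(list(S0 = NA_real_, D = NA_real_, residual = NA_real_,
                valid = FALSE))
  y <- log(signals)
  bbar <- mean(bValues)
  slope <- sum((bValues - bbar) * (y - mean(y))) / sum((bValues - bbar)^2)
  intercept <- mean(y) - slope * bbar
  res <- y - (intercept + slope * bValues)
  list(S0 = exp(intercept), D = -slope,
       residual = sqrt(mean(res^2)), valid = TRUE)
}

# vectorized log-linear fit over all voxels of one direction
fitAdcDirection <- function(volumes, bValues) {
  d <- dim(volumes[[1]]@values)
  nb <- length(bValues)
  Y <- matrix(NA_real_, prod(d), nb)
  for (i in seq_len(nb)) Y[, i] <- as.vector(volumes[[i]]@values)
  valid <- rowSums(Y <= 0) == 0
  D <- rep(NA_real_, nrow(Y))
  if (any(valid)) {
    L <- log(Y[valid, , drop = FALSE])
    bc <- bValues - mean(bValues)
    slope <- (L %*% bc) / sum(bc^2)
    D[valid] <- -slope
  }
  dim(D) <- d
  dim(valid) <- d
  list(D = D, valid = valid)
}

#' Compute an ADC map from a multi-direction DWI series
#'
#' Each direction is fitted independently voxel-wise (log-linear, see
#' [fitAdcVoxel()]); the ADC is the arithmetic mean of the per-direction D
#' maps. Voxels invalid in any direction (non-positive signal) are flagged.
#'
#' @param dwi a `DwiSeries` from [simulateDwi()], or a list of lists of
#'   [ImageVolume-class]: `dwi$volumes[[direction]][[b-index]]`.
#' @param bValues b-values; defaults to `dwi$bValues`.
#' @return An [ADCMap-class] (values in mm^2/s).
#' @export
computeAdcMap <- function(dwi, bValues = dwi$bValues) {
  vols <- if (!is.null(dwi$volumes)) dwi$volumes else dwi
  nb <- length(bValues)
  for (dir in seq_along(vols)) {
    if (length(vols[[dir]]) != nb)
      stop(sprintf("direction %d is missing volumes: %d supplied, %d b-values",
                   dir, length(vols[[dir]]), nb))
    for (v in vols[[dir]])
      stopifnotGeometryMatch(vols[[1]][[1]], v, "DWI volumes")
  }
  fits <- lapply(vols, fitAdcDirection, bValues = bValues)
  valid <- Reduce(`&`, lapply(fits, `[[`, "valid"))
  dmaps <- lapply(fits, `[[`, "D")
  avg <- Reduce(`+`, dmaps) / length(dmaps)
  avg[!valid] <- NA_real_
  ref <- vols[[1]][[1]]
  new("ADCMap", values = avg, spacing = ref@spacing,
      frameInterval = NA_real_, origin = ref@origin,
      directionMaps = dmaps, valid = valid)
}

#' Parenchymal ADC statistics
#'
#' Mean, standard deviation and a histogram of ADC values restricted to
#' parenchyma: voxels whose lowest-b signal exceeds the background
#' threshold AND that lie outside the vessel mask (which must already be on
#' the DWI grid; resample with `method = "nearest"` to preserve binarity).
#' The default background threshold is 10 % of the robust (99th percentile)
#' maximum of the lowest-b volume.
#'
#' @param adc an [ADCMap-class].
#' @param vesselMask a [BinaryMask-class] on the same grid, or `NULL`.
#' @param bMinVolume the lowest-b [ImageVolume-class], used for background
#'   detection; or `NULL` to skip background thresholding.
#' @param backgroundThreshold absolute signal threshold; default as above.
#' @param nBins histogram bin count.
#' @return A list: `mean`, `sd`, `n`, `histogram` (an R `hist` object).
#' @export
parenchymaStats <- function(adc, vesselMask = NULL, bMinVolume = NULL,
                            backgroundThreshold = NULL, nBins = 50L) {
  stopifnot(is(adc, "ADCMap"))
  keep <- adc@valid & !is.na(adc@values)
  if (!is.null(bMinVolume)) {
    stopifnotGeometryMatch(adc, bMinVolume, "ADC map and b-min volume")
    if (is.null(backgroundThreshold))
      backgroundThreshold <-
        0.1 * quantile(bMinVolume@values, 0.99, names = FALSE)
    keep <- keep & (bMinVolume@values > backgroundThreshold)
  }
  if (!is.null(vesselMask)) {
    stopifnotGeometryMatch(adc, vesselMask, "ADC map and vessel mask")
    keep <- keep & !vesselMask@values
  }
  vals <- adc@values[keep]
  if (!length(vals))
    stop("no voxels left after background and vessel masking")
  h <- graphics::hist(vals, breaks = nBins, plot = FALSE)
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals),
       histogram = h)
}
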