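#' Seeded region-growing segmentation
#'
#' Grows a binary mask from seed voxels through all voxels whose intensity
#' lies within `[low, high]`, connected to a seed under the chosen voxel
#' connectivity — the "magic wand" workflow of interactive vessel
#' segmentation, with the tolerance made explicit as an absolute band.
#' Seeds whose own value falls outside the band are skipped with a warning.
#'
#' @param vol a 3D [ImageVolume-class].
#' @param seeds integer matrix (or vector for one seed) of 1-based voxel
#'   indices, one `(x, y, z)` triple per row.
#' @param low,high inclusive intensity band.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners); default 26.
#' @return A [BinaryMask-class]. Every connected component of the mask
#'   contains at least one seed.
#' @examples
#' vol <- ImageVolume(array(100, c(8, 8, 8)))
#' voxelData(regionGrow(vol, c(4, 4, 4), low = 50, high = 150))[4, 4, 4]
#' @export
regionGrow <- function(vol, seeds, low, high, connectivity = 26L) {
  stopifnot(is(vol, "ImageVolume"))
  d <- dim(vol@values)
  if (length(d) != 3L) stop("regionGrow requires a 3D volume")
  if (low > high) stop("low must be <= high")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  if (!is.matrix(seeds)) seeds <- matrix(seeds, ncol = 3, byrow = TRUE)
  if (ncol(seeds) != 3L) stop("seeds must have one (x, y, z) triple per row")
  if (any(seeds < 1L) || any(seeds > matrix(d, nrow(seeds), 3, byrow = TRUE)))
    stop("seed out of volume bounds")
  sv <- vol@values[seeds]
  out_band <- sv < low | sv > high
  if (any(out_band)) {
    warning(sprintf("%d seed(s) with value outside [%g, %g] skipped",
                    sum(out_band), low, high))
    seeds <- seeds[!out_band, , drop = FALSE]
  }
  if (nrow(seeds) == 0L) {
    return(BinaryMask(array(FALSE, d), template = vol))
  }
  m <- cpp_region_grow(vol@values, as.integer(d),
                       matrix(as.integer(seeds - 1L), ncol = 3),
                       low, high, as.integer(connectivity))
  BinaryMask(m, template = vol)
}

#' Union of binary masks
#'
#' Voxel-wise union of per-plane (or otherwise repeated) segmentations, the
#' merge step of segmenting the same vasculature alternately in coronal,
#' sagittal and transverse views.
#'
#' @param masks a list of [BinaryMask-class] objects with identical geometry.
#' @return A [BinaryMask-class].
#' @export
mergeMasks <- function(masks) {
  stopifnot(length(masks) >= 1L)
  out <- masks[[1]]
  stopifnot(is(out, "BinaryMask"))
  if (length(masks) > 1L) for (m in masks[-1]) {
    stopifnot(is(m, "BinaryMask"))
    stopifnotGeometryMatch(out, m, "masks")
    out@values <- out@values | m@values
  }
  out
}

#' Count connected components of a mask
#'
#' @param mask a [BinaryMask-class].
#' @param connectivity 6 or 26.
#' @return Integer component count.
#' @export
countComponents <- function(mask, connectivity = 26L) {
  stopifnot(is(mask, "BinaryMask"))
  lab <- cpp_label(mask@values, as.integer(dim(mask@values)),
                   as.integer(connectivity))
  max(lab)
}
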