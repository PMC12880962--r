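# Minimal NIfTI-1 reader/writer. Only the fields this package relies on are
# interpreted: dim, datatype, pixdim (spacing in mm, frame interval in s),
# vox_offset, scl_slope/inter, qoffset/srow origin. Both endiannesses are
# read; files are written little-endian. Gzipped files (.nii.gz) are
# handled transparently via R's gzfile connection.

NIFTI_TYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),  # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)) # uint16

#' Read a NIfTI-1 volume
#'
#' Reads a 3D or 4D NIfTI-1 file (optionally gzipped) into an
#' [ImageVolume-class]. Voxel spacing comes from `pixdim`, the frame
#' interval (4D) from the time `pixdim` slot, and the world origin from the
#' sform/qform offsets when present.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return An [ImageVolume-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("malformed header: file shorter than 348 bytes")
  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("malformed header: sizeof_hdr is not 348")
  }
  rd <- function(off, what, n, size)
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian)
  dim8 <- rd(40L, "integer", 8L, 2L)
  ndim <- dim8[1]
  if (!ndim %in% c(3L, 4L))
    stop(sprintf("unsupported dimensionality in header field dim: %d", ndim))
  dims <- dim8[2:(1 + ndim)]
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim <- rd(76L, "double", 8L, 4L)
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive voxel spacing in header field pixdim")
  frameInterval <- if (ndim == 4L) pixdim[5] else NA_real_
  if (ndim == 4L && (!is.finite(frameInterval) || frameInterval <= 0))
    stop("4D volume with non-positive frame interval in header field pixdim[4]")
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  qform_code <- rd(252L, "integer", 1L, 2L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    origin <- c(rd(280L + 12L, "double", 1L, 4L),
                rd(296L + 12L, "double", 1L, 4L),
                rd(312L + 12L, "double", 1L, 4L))
  } else if (qform_code > 0L) {
    origin <- rd(268L, "double", 3L, 4L)
  }
  tp <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(tp))
    stop(sprintf("unsupported datatype code in header: %d", datatype))
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, tp$what, n = n, size = tp$size, signed = tp$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated data section")
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  dim(vals) <- dims
  ImageVolume(vals, spacing = spacing, frameInterval = frameInterval,
              origin = origin)
}

#' Write a NIfTI-1 volume
#'
#' Writes an [ImageVolume-class] (or [BinaryMask-class], stored as uint8) as
#' NIfTI-1, gzipped when the path ends in `.gz`. Spacing, frame interval and
#' origin are round-tripped through the header (sform).
#'
#' @param vol an [ImageVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ImageVolume"))
  vals <- vol@values
  dims <- dim(vals)
  ndim <- length(dims)
  isMask <- is.logical(vals)
  datatype <- if (isMask) 2L else 64L
  bitpix <- if (isMask) 8L else 64L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4L)                                    # sizeof_hdr
  w(raw(36L), 1L)                                # unused through dim_info
  dim8 <- integer(8L); dim8[1] <- ndim; dim8[2:(1 + ndim)] <- dims
  dim8[dim8 == 0L] <- 1L
  w(as.integer(dim8), 2L)                        # dim
  w(c(0, 0, 0), 4L)                              # intent_p1..p3 (float)
  w(c(0L, datatype, bitpix, 0L), 2L)             # intent_code..slice_start
  pixdim <- numeric(8L); pixdim[1] <- 1
  pixdim[2:4] <- vol@spacing
  pixdim[5] <- if (ndim == 4L) vol@frameInterval else 0
  w(pixdim, 4L)                                  # pixdim (float)
  w(c(352, 1, 0), 4L)                            # vox_offset, scl_slope, scl_inter
  w(0L, 2L); w(as.raw(0L), 1L)                   # slice_end, slice_code
  w(as.raw(10L), 1L)                             # xyzt_units: mm | sec
  w(c(0, 0, 0, 0), 4L)                           # cal_max..toffset
  w(c(0L, 0L), 4L)                               # glmax, glmin
  w(raw(104L), 1L)                               # descrip + aux_file
  w(c(0L, 1L), 2L)                               # qform_code=0, sform_code=1
  w(c(0, 0, 0), 4L)                              # quatern b, c, d
  w(vol@origin, 4L)                              # qoffset (kept in sync)
  w(c(vol@spacing[1], 0, 0, vol@origin[1]), 4L)  # srow_x
  w(c(0, vol@spacing[2], 0, vol@origin[2]), 4L)  # srow_y
  w(c(0, 0, vol@spacing[3], vol@origin[3]), 4L)  # srow_z
  w(raw(16L), 1L)                                # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL); w(raw(1L), 1L)  # magic
  w(raw(4L), 1L)                                 # extension flag
  if (isMask) w(as.integer(vals), 1L) else w(as.numeric(vals), 8L)
  invisible(path)
}
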