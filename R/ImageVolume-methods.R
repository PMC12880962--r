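#' Construct an ImageVolume
#'
#' @param values numeric or logical array, 3D `(x, y, z)` or 4D `(x, y, z, t)`.
#' @param spacing voxel spacing in mm, per axis (recycled to length 3).
#' @param frameInterval seconds between frames; required for 4D input.
#' @param origin world position (mm) of the corner of the first voxel.
#' @return An [ImageVolume-class].
#' @examples
#' vol <- ImageVolume(array(0, c(8, 8, 4)), spacing = c(0.83, 0.83, 5))
#' spacingMm(vol)
#' @export
ImageVolume <- function(values, spacing = c(1, 1, 1), frameInterval = NA_real_,
                        origin = c(0, 0, 0)) {
  if (is.null(dim(values)))
    stop("values must be an array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  new("ImageVolume", values = values, spacing = spacing,
      frameInterval = as.numeric(frameInterval),
      origin = rep_len(as.numeric(origin), 3L))
}

#' Construct a BinaryMask
#'
#' @param values logical (or coercible) 3D array.
#' @param spacing,origin geometry, as for [ImageVolume()].
#' @param template optional [ImageVolume-class] whose geometry is copied.
#' @return A [BinaryMask-class].
#' @export
BinaryMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       template = NULL) {
  if (!is.logical(values)) {
    d <- dim(values)
    values <- as.logical(values)
    dim(values) <- d
  }
  if (!is.null(template)) {
    spacing <- spacingMm(template)
    origin <- originMm(template)
  }
  new("BinaryMask", values = values, spacing = rep_len(as.numeric(spacing), 3L),
      frameInterval = NA_real_, origin = rep_len(as.numeric(origin), 3L))
}

#' @rdname perfuseMRI-accessors
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@values)

#' @rdname perfuseMRI-accessors
#' @export
setMethod("spacingMm", "ImageVolume", function(x) x@spacing)

#' @rdname perfuseMRI-accessors
#' @export
setMethod("frameIntervalS", "ImageVolume", function(x) x@frameInterval)

#' @rdname perfuseMRI-accessors
#' @export
setMethod("originMm", "ImageVolume", function(x) x@origin)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %s voxels, spacing %s mm%s\n",
              class(object), paste(d, collapse = " x "),
              paste(signif(object@spacing, 4), collapse = " x "),
              if (length(d) == 4L)
                sprintf(", %d frames every %g s", d[4], object@frameInterval)
              else ""))
  invisible(object)
})

#' @rdname perfuseMRI-accessors
#' @export
setMethod("graphNodes", "SpatialGraph", function(x) x@nodes)

#' @rdname perfuseMRI-accessors
#' @export
setMethod("graphSegments", "SpatialGraph", function(x) x@segments)

#' @rdname perfuseMRI-accessors
#' @export
setMethod("inletNode", "SpatialGraph", function(x) x@inlet)

#' @rdname perfuseMRI-accessors
#' @export
setMethod("inletNode<-", "SpatialGraph", function(x, value) {
  x@inlet <- as.integer(value)
  validObject(x)
  x
})

setMethod("show", "SpatialGraph", function(object) {
  deg <- object@nodes$degree
  cat(sprintf(
    "SpatialGraph: %d nodes (%d terminal, %d branching), %d segments\n",
    nrow(object@nodes), sum(deg == 1L), sum(deg >= 3L),
    length(object@segments)))
  invisible(object)
})

# world coordinates of all voxel centers along one axis (1-based indices)
axisCentersMm <- function(vol, axis) {
  n <- dim(vol@values)[axis]
  vol@origin[axis] + (seq_len(n) - 0.5) * vol@spacing[axis]
}

# voxel index (1-based, clamped) containing a world point
worldToVoxel <- function(vol, p) {
  i <- floor((p - vol@origin) / vol@spacing) + 1L
  pmin(pmax(i, 1L), dim(vol@values)[1:3])
}

stopifnotGeometryMatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a@values)[1:3], dim(b@values)[1:3]) ||
      max(abs(a@spacing - b@spacing)) > 1e-9 ||
      max(abs(a@origin - b@origin)) > 1e-9)
    stop(sprintf("%s have mismatched geometry (shape, spacing or origin)", what))
  invisible(TRUE)
}
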