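#' ImageVolume: a 3D or 4D scalar grid with physical geometry
#'
#' The central image container. `values` is a numeric (or logical) array,
#' either 3D `(x, y, z)` or 4D `(x, y, z, t)`. Voxel spacing is in mm per
#' axis; 4D volumes additionally carry the frame interval in seconds.
#' World coordinates follow the half-voxel convention: the center of the
#' 1-based voxel `(i, j, k)` sits at `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @slot values numeric or logical array, 3D or 4D.
#' @slot spacing numeric length-3, voxel spacing in mm (all `> 0`).
#' @slot frameInterval numeric length-1, seconds between frames
#'   (`NA` for 3D volumes).
#' @slot origin numeric length-3, world position (mm) of the corner of the
#'   first voxel.
#'
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(values = "array", spacing = "numeric",
                 frameInterval = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), frameInterval = NA_real_,
            origin = c(0, 0, 0)))

setValidity("ImageVolume", function(object) {
  nd <- length(dim(object@values))
  msg <- character()
  if (!nd %in% c(3L, 4L))
    msg <- c(msg, "values must be a 3D or 4D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite values (mm)")
  if (length(object@frameInterval) != 1L)
    msg <- c(msg, "frameInterval must be length 1")
  if (nd == 4L &&
      (is.na(object@frameInterval) || object@frameInterval <= 0))
    msg <- c(msg, "4D volumes must carry a positive frameInterval (s)")
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a logical voxel grid aligned to an ImageVolume
#'
#' A segmentation result. Inherits the full geometry of [ImageVolume-class];
#' `values` must be logical and 3D.
#'
#' @exportClass BinaryMask
setClass("BinaryMask", contains = "ImageVolume")

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!is.logical(object@values))
    msg <- c(msg, "mask values must be logical")
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "mask must be 3D")
  if (length(msg)) msg else TRUE
})

#' DistanceMap: a chamfer distance transform of a binary mask
#'
#' Values are in chamfer units; divide by `weights[1]` (the face step cost)
#' and multiply by the face voxel size to convert to mm (see
#' [chamferDistanceMap()]). Zero exactly on background, positive on
#' foreground.
#'
#' @slot weights numeric length-3, the 26-neighbourhood step costs
#'   (face, edge, corner).
#'
#' @exportClass DistanceMap
setClass("DistanceMap", contains = "ImageVolume",
  representation(weights = "numeric"),
  prototype(weights = c(3, 4, 5)))

setValidity("DistanceMap", function(object) {
  msg <- character()
  if (length(object@weights) != 3L || any(object@weights <= 0))
    msg <- c(msg, "weights must be three positive step costs (face, edge, corner)")
  if (any(object@values < 0))
    msg <- c(msg, "distances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SpatialGraph: a vessel centerline network with per-point radii
#'
#' Nodes are branch points and terminals; segments are ordered polylines in
#' world mm with one radius per point. A segment's end points coincide with
#' its nodes' positions, and a node's degree equals the number of incident
#' segment ends (both enforced by validity).
#'
#' @slot nodes data.frame with columns `id`, `x`, `y`, `z`, `degree`.
#' @slot segments list; each element a list with fields `a`, `b` (node ids),
#'   `points` (n x 3 matrix, world mm) and `radius` (length-n, mm, `>= 0`).
#' @slot inlet integer, node id of the designated inflow node (may be `NA`).
#'
#' @exportClass SpatialGraph
setClass("SpatialGraph",
  representation(nodes = "data.frame", segments = "list", inlet = "integer"),
  prototype(nodes = data.frame(id = integer(), x = numeric(), y = numeric(),
                               z = numeric(), degree = integer()),
            segments = list(), inlet = NA_integer_))

setValidity("SpatialGraph", function(object) {
  msg <- character()
  nd <- object@nodes
  need <- c("id", "x", "y", "z", "degree")
  if (!all(need %in% names(nd)))
    return(sprintf("nodes must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$id)) msg <- c(msg, "node ids must be unique")
  deg <- stats::setNames(rep(0L, nrow(nd)), nd$id)
  for (i in seq_along(object@segments)) {
    s <- object@segments[[i]]
    if (!all(c("a", "b", "points", "radius") %in% names(s)))
      return(sprintf("segment %d lacks fields a, b, points, radius", i))
    if (!is.matrix(s$points) || ncol(s$points) != 3 || nrow(s$points) < 2)
      return(sprintf("segment %d: points must be an n x 3 matrix, n >= 2", i))
    if (length(s$radius) != nrow(s$points))
      return(sprintf("segment %d: one radius per polyline point required", i))
    if (any(s$radius < 0))
      return(sprintf("segment %d: radii must be >= 0", i))
    for (end in c("a", "b")) {
      nid <- as.character(s[[end]])
      if (!nid %in% names(deg))
        return(sprintf("segment %d references unknown node %s", i, nid))
      deg[nid] <- deg[nid] + 1L
      row <- which(nd$id == s[[end]])
      p <- if (end == "a") s$points[1, ] else s$points[nrow(s$points), ]
      if (max(abs(p - unlist(nd[row, c("x", "y", "z")]))) > 1e-6)
        return(sprintf("segment %d: endpoint %s does not coincide with node %s",
                       i, end, nid))
    }
  }
  if (nrow(nd) && any(deg[as.character(nd$id)] != nd$degree))
    msg <- c(msg, "node degree must equal the number of incident segment ends")
  if (!is.na(object@inlet) && !object@inlet %in% nd$id)
    msg <- c(msg, "inlet must name an existing node")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of the synthetic vascular phantom
#'
#' Describes a binary bifurcating vessel tree to be grown and rasterized:
#' grid geometry, branching depth, root radius with per-generation decay,
#' mean straight segment length and the amplitude of the sinusoidal lateral
#' perturbation that induces tortuosity.
#'
#' @slot gridShape integer length-3 voxel counts.
#' @slot spacing numeric length-3 voxel spacing (mm).
#' @slot treeDepth integer number of branching generations (`>= 1`).
#' @slot rootRadius numeric, radius of the root segment (mm); must be at
#'   least twice the coarsest voxel spacing so the root is resolvable.
#' @slot radiusDecay numeric in (0, 1], radius multiplier per generation.
#' @slot segmentLength numeric, mean straight (chord) length per
#'   generation (mm).
#' @slot tortuosityAmplitude numeric `>= 0`, lateral sinusoidal
#'   perturbation amplitude (mm).
#' @slot seed integer random seed.
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
                 treeDepth = "integer", rootRadius = "numeric",
                 radiusDecay = "numeric", segmentLength = "numeric",
                 tortuosityAmplitude = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1))
    msg <- c(msg, "gridShape must be three positive voxel counts")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive lengths (mm)")
  if (object@treeDepth < 1L)
    msg <- c(msg, "treeDepth must be >= 1")
  if (object@rootRadius < 2 * max(object@spacing))
    msg <- c(msg, "rootRadius must be >= 2 x max(spacing) so the root is resolvable")
  if (object@radiusDecay <= 0 || object@radiusDecay > 1)
    msg <- c(msg, "radiusDecay must lie in (0, 1]")
  if (object@segmentLength <= 0)
    msg <- c(msg, "segmentLength must be positive")
  if (object@tortuosityAmplitude < 0)
    msg <- c(msg, "tortuosityAmplitude must be >= 0")
  if (length(msg)) msg else TRUE
})

#' TTPMap: voxel-wise time to peak contrast enhancement
#'
#' Seconds from scan start to maximal enhancement; voxels whose peak
#' enhancement never clears the noise floor are flagged invalid rather
#' than zero-filled.
#'
#' @slot valid logical array, same shape as `values`.
#'
#' @exportClass TTPMap
setClass("TTPMap", contains = "ImageVolume",
  representation(valid = "array"))

setValidity("TTPMap", function(object) {
  if (!identical(dim(object@valid), dim(object@values)))
    return("valid flags must match the value grid")
  ok <- object@valid & !is.na(object@values)
  if (any(object@values[ok] < 0))
    return("TTP values must be >= 0 where valid")
  TRUE
})

#' ADCMap: voxel-wise apparent diffusion coefficient
#'
#' `values` holds the direction-averaged D in mm^2/s; `directionMaps` the
#' per-direction fits; `valid` flags voxels where the log-linear fit was
#' defined (all signals positive).
#'
#' @slot directionMaps list of numeric arrays, one D map per diffusion
#'   direction.
#' @slot valid logical array of fit validity flags.
#'
#' @exportClass ADCMap
setClass("ADCMap", contains = "ImageVolume",
  representation(directionMaps = "list", valid = "array"))

setValidity("ADCMap", function(object) {
  if (!identical(dim(object@valid), dim(object@values)))
    return("valid flags must match the value grid")
  for (m in object@directionMaps)
    if (!identical(dim(m), dim(object@values)))
      return("direction maps must match the averaged map's shape")
  TRUE
})
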