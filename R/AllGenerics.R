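#' @name perfuseMRI-accessors
#' @title Accessors for perfuseMRI data classes
#'
#' @description Slot accessors. `voxelData()` returns the raw array,
#' `spacingMm()` the per-axis voxel spacing, `frameIntervalS()` the DCE
#' frame interval, `originMm()` the world offset; `graphNodes()`,
#' `graphSegments()` and `inletNode()` expose a [SpatialGraph-class].
#'
#' @param x an object.
#' @param value replacement value.
#' @return The slot contents (see Description).
NULL

#' @rdname perfuseMRI-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname perfuseMRI-accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname perfuseMRI-accessors
#' @export
setGeneric("frameIntervalS", function(x) standardGeneric("frameIntervalS"))

#' @rdname perfuseMRI-accessors
#' @export
setGeneric("originMm", function(x) standardGeneric("originMm"))

#' @rdname perfuseMRI-accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname perfuseMRI-accessors
#' @export
setGeneric("graphSegments", function(x) standardGeneric("graphSegments"))

#' @rdname perfuseMRI-accessors
#' @export
setGeneric("inletNode", function(x) standardGeneric("inletNode"))

#' @rdname perfuseMRI-accessors
#' @export
setGeneric("inletNode<-", function(x, value) standardGeneric("inletNode<-"))
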