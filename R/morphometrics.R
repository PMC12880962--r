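# Vascular morphometrics from a SpatialGraph: per-segment geometry and
# whole-network summaries (totals, node-type counts, coordination numbers,
# segment-length / radius / tortuosity distributions).

curvedLengthMm <- function(points) {
  if (nrow(points) < 2L) return(0)
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Per-segment vessel metrics
#'
#' Curved length is the sum of consecutive polyline point distances;
#' straight length the end-to-end chord; tortuosity their ratio (defined as
#' 1 for a closed loop, whose chord is zero); volume the frustum sum
#' `sum(pi * rbar_i^2 * dl_i)` over polyline intervals with `rbar_i` the
#' interval's mean radius.
#'
#' @param segment one element of `graphSegments(graph)`: a list with
#'   `points` (n x 3 matrix, mm) and `radius` (length n, mm).
#' @return Named list: `curved_length_mm`, `straight_length_mm`,
#'   `tortuosity`, `mean_radius_mm`, `volume_mm3`.
#' @examples
#' seg <- list(points = cbind(seq(0, 10, 1), 0, 0), radius = rep(2, 11))
#' segmentMetrics(seg)$volume_mm3   # 40 * pi, a 10 mm cylinder of radius 2
#' @export
segmentMetrics <- function(segment) {
  P <- segment$points
  if (!is.matrix(P) || nrow(P) < 2L)
    stop("segment polyline must have at least 2 points")
  steps <- sqrt(rowSums(diff(P)^2))
  curved <- sum(steps)
  straight <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
  tort <- if (straight < 1e-12) 1 else curved / straight
  r <- segment$radius
  rbar <- (r[-length(r)] + r[-1]) / 2
  list(curved_length_mm = curved, straight_length_mm = straight,
       tortuosity = tort, mean_radius_mm = mean(r),
       volume_mm3 = sum(pi * rbar^2 * steps))
}

#' Whole-network morphometric summary
#'
#' Totals are sums over segments. Terminal nodes have degree 1, branching
#' nodes degree 3 or more (degree-2 cycle markers are excluded from both
#' counts); `terminal_fraction = terminal / (terminal + branching)`. The
#' coordination number of a branching node is its degree, averaged over
#' branching nodes only. Medians (type-7 interpolation between order
#' statistics) are taken over segments.
#'
#' @param graph a non-empty [SpatialGraph-class].
#' @return A list of class `NetworkSummary`: `total_length_mm`,
#'   `total_volume_mm3`, `n_branching_nodes`, `n_terminal_nodes`,
#'   `terminal_fraction`, `mean_coordination_number`,
#'   `median_segment_length_mm`, `median_radius_mm`, `median_tortuosity`,
#'   and `segments` (the per-segment table).
#' @export
networkSummary <- function(graph) {
  stopifnot(is(graph, "SpatialGraph"))
  if (!length(graph@segments)) stop("empty graph: no segments to summarize")
  tab <- do.call(rbind, lapply(seq_along(graph@segments), function(k) {
    m <- segmentMetrics(graph@segments[[k]])
    data.frame(segment = k, a = graph@segments[[k]]$a,
               b = graph@segments[[k]]$b,
               curved_length_mm = m$curved_length_mm,
               straight_length_mm = m$straight_length_mm,
               tortuosity = m$tortuosity, mean_radius_mm = m$mean_radius_mm,
               volume_mm3 = m$volume_mm3)
  }))
  deg <- graph@nodes$degree
  nTerm <- sum(deg == 1L)
  nBranch <- sum(deg >= 3L)
  out <- list(
    total_length_mm = sum(tab$curved_length_mm),
    total_volume_mm3 = sum(tab$volume_mm3),
    n_branching_nodes = nBranch,
    n_terminal_nodes = nTerm,
    terminal_fraction = if (nTerm + nBranch > 0) nTerm / (nTerm + nBranch)
      else NA_real_,
    mean_coordination_number = if (nBranch > 0) mean(deg[deg >= 3L])
      else NA_real_,
    median_segment_length_mm = median(tab$curved_length_mm),
    median_radius_mm = median(tab$mean_radius_mm),
    median_tortuosity = median(tab$tortuosity),
    segments = tab)
  class(out) <- "NetworkSummary"
  out
}

#' @export
print.NetworkSummary <- function(x, ...) {
  cat("Vascular network summary\n")
  cat(sprintf("  total length  %.1f mm, total volume %.1f mm^3\n",
              x$total_length_mm, x$total_volume_mm3))
  cat(sprintf("  nodes: %d branching, %d terminal (terminal fraction %.2f)\n",
              x$n_branching_nodes, x$n_terminal_nodes, x$terminal_fraction))
  cat(sprintf("  mean coordination number %.2f\n",
              x$mean_coordination_number))
  cat(sprintf("  medians: segment length %.2f mm, radius %.2f mm, tortuosity %.3f\n",
              x$median_segment_length_mm, x$median_radius_mm,
              x$median_tortuosity))
  invisible(x)
}

#' Voxel-count volume of a mask
#'
#' The segmentation-based alternative to the graph frustum volume: number
#' of foreground voxels times the voxel volume.
#'
#' @param mask a [BinaryMask-class].
#' @return Volume in mm^3.
#' @export
maskVolumeMm3 <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  sum(mask@values) * prod(mask@spacing)
}
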