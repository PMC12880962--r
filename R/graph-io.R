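# SpatialGraph serialization: JSON (nodes, segments, per-point radii) and a
# per-segment CSV edge list.

#' Write / read a SpatialGraph as JSON
#'
#' The JSON layout has `nodes` (id, x, y, z, degree), `segments` (node ids
#' `a`, `b`, an n x 3 `points` array in mm and per-point `radius` in mm)
#' and the optional `inlet` node id. Round-trips exactly to numeric
#' precision.
#'
#' @param graph a [SpatialGraph-class].
#' @param path output / input file path.
#' @return `writeSpatialGraph`: `path` invisibly; `readSpatialGraph`: a
#'   [SpatialGraph-class].
#' @export
writeSpatialGraph <- function(graph, path) {
  stopifnot(is(graph, "SpatialGraph"))
  obj <- list(
    nodes = graph@nodes,
    segments = lapply(graph@segments, function(s)
      list(a = s$a, b = s$b, points = unname(s$points), radius = s$radius)),
    inlet = graph@inlet)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname writeSpatialGraph
#' @export
readSpatialGraph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes)
  nodes$id <- as.integer(nodes$id)
  nodes$degree <- as.integer(nodes$degree)
  segs <- lapply(seq_along(obj$segments$a), function(k) {
    P <- obj$segments$points[[k]]
    list(a = as.integer(obj$segments$a[[k]]),
         b = as.integer(obj$segments$b[[k]]),
         points = matrix(as.numeric(P), ncol = 3),
         radius = as.numeric(obj$segments$radius[[k]]))
  })
  inlet <- if (is.null(obj$inlet) || is.na(obj$inlet)) NA_integer_
    else as.integer(obj$inlet)
  new("SpatialGraph", nodes = nodes, segments = segs, inlet = inlet)
}

#' Write the per-segment edge list as CSV
#'
#' Columns: segment id, end-node ids, curved length, mean radius and
#' tortuosity — the tabular export feeding downstream statistics.
#'
#' @param graph a [SpatialGraph-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSegmentCsv <- function(graph, path) {
  s <- networkSummary(graph)$segments
  write.csv(s[, c("segment", "a", "b", "curved_length_mm", "mean_radius_mm",
                  "tortuosity")], path, row.names = FALSE)
  invisible(path)
}

#' Centerline path from the inlet to the farthest terminal
#'
#' Follows the tree from the inlet node to the terminal node with the
#' greatest path distance, concatenating the segment polylines (each
#' oriented away from the inlet). This is the natural path along which to
#' track a contrast bolus front.
#'
#' @param graph a [SpatialGraph-class] with a designated inlet.
#' @return An n x 3 matrix of world-mm points ordered from the inlet.
#' @export
inletPath <- function(graph) {
  if (is.na(graph@inlet)) stop("graph has no designated inlet node")
  nn <- nrow(graph@nodes)
  pd <- graphPathDistances(graph)
  # parent pointers via repeated relaxation (graphs are small trees)
  segLen <- vapply(graph@segments, function(s) curvedLengthMm(s$points),
                   numeric(1))
  parentSeg <- rep(NA_integer_, nn)
  for (k in seq_along(graph@segments)) {
    s <- graph@segments[[k]]
    if (abs(pd$nodeDist[s$a] + segLen[k] - pd$nodeDist[s$b]) < 1e-6)
      parentSeg[s$b] <- k
    if (abs(pd$nodeDist[s$b] + segLen[k] - pd$nodeDist[s$a]) < 1e-6)
      parentSeg[s$a] <- k
  }
  term <- which(graph@nodes$degree == 1L & graph@nodes$id != graph@inlet)
  if (!length(term)) term <- seq_len(nn)[-graph@inlet]
  target <- term[which.max(pd$nodeDist[term])]
  chain <- list()
  cur <- target
  while (cur != graph@inlet) {
    k <- parentSeg[cur]
    if (is.na(k)) stop("no path from inlet to the farthest terminal")
    s <- graph@segments[[k]]
    P <- s$points
    if (s$b == cur) { nxt <- s$a } else { nxt <- s$b; P <- P[nrow(P):1, ] }
    chain[[length(chain) + 1L]] <- P
    cur <- nxt
  }
  chain <- rev(chain)
  out <- chain[[1]]
  if (length(chain) > 1L)
    for (j in 2:length(chain)) out <- rbind(out, chain[[j]][-1, , drop = FALSE])
  out
}

# path distance (mm) of every polyline point of every segment from the
# inlet node, following the graph; used by the DCE simulator and the
# bolus-front tracker. Returns list(segments = list of per-point distances,
# nodeDist = per-node distance).
graphPathDistances <- function(graph) {
  if (is.na(graph@inlet)) stop("graph has no designated inlet node")
  nn <- nrow(graph@nodes)
  segLen <- vapply(graph@segments, function(s) curvedLengthMm(s$points),
                   numeric(1))
  # Dijkstra over nodes with segment curved lengths as edge weights
  dist <- rep(Inf, nn)
  dist[graph@inlet] <- 0
  done <- rep(FALSE, nn)
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    for (k in seq_along(graph@segments)) {
      s <- graph@segments[[k]]
      if (s$a == u && dist[u] + segLen[k] < dist[s$b])
        dist[s$b] <- dist[u] + segLen[k]
      if (s$b == u && dist[u] + segLen[k] < dist[s$a])
        dist[s$a] <- dist[u] + segLen[k]
    }
  }
  perSeg <- lapply(seq_along(graph@segments), function(k) {
    s <- graph@segments[[k]]
    P <- s$points
    arc <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
    fromA <- dist[s$a] + arc
    fromB <- dist[s$b] + (arc[length(arc)] - arc)
    pmin(fromA, fromB)
  })
  list(segments = perSeg, nodeDist = dist)
}
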