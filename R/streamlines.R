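#' @include AllClasses.R utils.R
NULL

#' Streamline geometry: length and maximum turning angle
#'
#' `streamlineLengths` sums segment lengths per streamline (mm);
#' `maxTurningAngles` takes, per streamline, the maximum over interior
#' points of the angle (degrees) between consecutive segment directions.
#' A 2-point streamline has turning angle 0.
#'
#' @param x A [StreamlineSet-class].
#' @return Numeric vector, one value per streamline.
#' @export
streamlineLengths <- function(x) {
  vapply(x@points, function(p) {
    d <- diff(p)
    sum(sqrt(rowSums(d * d)))
  }, numeric(1))
}

#' @rdname streamlineLengths
#' @export
maxTurningAngles <- function(x) {
  vapply(x@points, function(p) {
    if (nrow(p) < 3L) return(0)
    d <- diff(p)
    len <- sqrt(rowSums(d * d))
    keep <- len > .Machine$double.eps
    d <- d[keep, , drop = FALSE]
    if (nrow(d) < 2L) return(0)
    u <- d / sqrt(rowSums(d * d))
    cosang <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
    max(acos(pmin(1, pmax(-1, cosang)))) * 180 / pi
  }, numeric(1))
}

#' Filter streamlines by length, turning angle and grey-matter masks
#'
#' Applies the standard tractography exclusion rules: a streamline is kept
#' iff `minLength <= length <= maxLength`, its maximum per-step turning
#' angle is `<= maxAngle`, and (when `gmMask` is supplied) both endpoints
#' are flagged in-grey-matter. Rejections are attributed to the *first*
#' failing rule in the fixed order length-short, length-long, angle, mask,
#' so the accounting is deterministic and sums to the input count.
#'
#' @param x A [StreamlineSet-class].
#' @param minLength,maxLength Length window in mm (defaults 10 and 300).
#' @param maxAngle Maximum per-step turning angle in degrees (default 60).
#' @param gmMask Optional logical matrix (nStreamlines x 2): endpoint
#'   in-grey-matter flags.
#' @return List with `kept` (a StreamlineSet), `keptIndex` (indices into
#'   the input), `status` (per-streamline: `kept`, `length-short`,
#'   `length-long`, `angle`, `mask`) and `counts` (named rejection tally).
#' @export
filterStreamlines <- function(x, minLength = 10, maxLength = 300,
                              maxAngle = 60, gmMask = NULL) {
  for (i in seq_along(x@points)) {
    if (nrow(x@points[[i]]) < 2L)
      stop(sprintf("malformed streamline at index %d: fewer than 2 points", i),
           call. = FALSE)
  }
  n <- length(x@points)
  len <- streamlineLengths(x)
  ang <- maxTurningAngles(x)
  status <- rep("kept", n)
  status[ang > maxAngle] <- "angle"
  status[len > maxLength] <- "length-long"
  status[len < minLength] <- "length-short"
  if (!is.null(gmMask)) {
    stopIfNot(is.logical(gmMask) && nrow(gmMask) == n && ncol(gmMask) == 2,
              "gmMask must be a logical nStreamlines x 2 matrix")
    failMask <- !(gmMask[, 1] & gmMask[, 2])
    status[status == "kept" & failMask] <- "mask"
  }
  keptIdx <- which(status == "kept")
  kept <- new("StreamlineSet", points = x@points[keptIdx],
              labels = if (length(x@labels)) x@labels[keptIdx] else character(0))
  counts <- c(`kept` = length(keptIdx),
              `length-short` = sum(status == "length-short"),
              `length-long` = sum(status == "length-long"),
              `angle` = sum(status == "angle"),
              `mask` = sum(status == "mask"))
  list(kept = kept, keptIndex = keptIdx, status = status, counts = counts)
}

#' Snap streamline endpoints to nearest triangle centers
#'
#' Each endpoint of each (already filtered) streamline is snapped to the
#' closest triangle centroid by Euclidean distance (ties broken by lowest
#' triangle id). Streamlines whose two endpoints snap to the same triangle
#' yield a self-loop and are dropped from the edge list but counted.
#'
#' @param x A [StreamlineSet-class] of kept streamlines.
#' @param centers Numeric matrix (nTriangles x 3) of triangle centroids.
#' @param maxSnapDistance Maximum snap distance in mm (`Inf` = unlimited,
#'   the default; endpoints farther than this leave the streamline
#'   unsnapped and counted).
#' @return List with `edges` (data.frame `from`, `to`, `count`; `from <
#'   to`, multiplicities aggregated), `endpointTriangles` (n x 2 integer
#'   matrix, NA when unsnapped), `nSelfLoops`, `nUnsnapped`.
#' @export
mapEndpoints <- function(x, centers, maxSnapDistance = Inf) {
  stopIfNot(nrow(centers) >= 1, "at least one triangle center required")
  n <- length(x@points)
  ep <- matrix(0, 2L * n, 3L)
  for (i in seq_len(n)) {
    p <- x@points[[i]]
    ep[2L * i - 1L, ] <- p[1L, ]
    ep[2L * i, ] <- p[nrow(p), ]
  }
  if (any(!is.finite(ep)))
    stop("non-finite endpoint coordinates", call. = FALSE)
  # exhaustive nearest neighbor, chunked; ties to lowest triangle id
  # (max.col with ties.method = "first" on negated distances)
  cN2 <- rowSums(centers * centers)
  nearest <- integer(nrow(ep))
  nearestD2 <- numeric(nrow(ep))
  chunk <- max(1L, floor(5e6 / nrow(centers)))
  for (s in seq(1L, nrow(ep), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(ep))
    d2 <- outer(rowSums(ep[idx, , drop = FALSE]^2), cN2, "+") -
      2 * ep[idx, , drop = FALSE] %*% t(centers)
    j <- max.col(-d2, ties.method = "first")
    nearest[idx] <- j
    nearestD2[idx] <- d2[cbind(seq_along(idx), j)]
  }
  if (is.finite(maxSnapDistance))
    nearest[nearestD2 > maxSnapDistance^2] <- NA_integer_
  epTri <- matrix(nearest, ncol = 2L, byrow = TRUE)
  unsnapped <- is.na(epTri[, 1]) | is.na(epTri[, 2])
  self <- !unsnapped & epTri[, 1] == epTri[, 2]
  ok <- !unsnapped & !self
  a <- pmin(epTri[ok, 1], epTri[ok, 2])
  b <- pmax(epTri[ok, 1], epTri[ok, 2])
  if (length(a)) {
    key <- paste(a, b)
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    edges <- data.frame(from = as.integer(parts[, 1]),
                        to = as.integer(parts[, 2]),
                        count = as.integer(tab))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(0), to = integer(0),
                        count = integer(0))
  }
  list(edges = edges, endpointTriangles = epTri,
       nSelfLoops = sum(self), nUnsnapped = sum(unsnapped))
}

#' Assemble the binary combined network
#'
#' Sums the local lateral adjacency (mesh triangle adjacency) and the
#' long-range streamline edge list, then binarises: an edge is present
#' wherever either a local or a long-range connection exists. The result
#' is a simple undirected graph over triangle nodes with area labels and
#' centroid coordinates as node metadata.
#'
#' @param localAdjacency Integer matrix (nPairs x 2) from
#'   [triangleAdjacency()].
#' @param longRangeEdges data.frame with `from`, `to` columns (triangle
#'   ids) as returned by [mapEndpoints()]; may have repeated rows.
#' @param nNodes Number of triangles (nodes).
#' @param area Character vector of area labels (length nNodes) or NULL.
#' @param centers Optional numeric matrix (nNodes x 3) of centroids.
#' @return List with `network` (a [ConnectomeNetwork-class]) and
#'   `nOverlap`, the number of edges both local and long-range.
#' @export
assembleNetwork <- function(localAdjacency, longRangeEdges, nNodes,
                            area = NULL, centers = NULL) {
  le <- as.matrix(localAdjacency)
  lr <- cbind(longRangeEdges$from, longRangeEdges$to)
  allIds <- c(le, lr)
  if (length(allIds) && (min(allIds) < 1L || max(allIds) > nNodes))
    stop("edge endpoint id out of range 1..nNodes", call. = FALSE)
  norm <- function(m) {
    if (!nrow(m)) return(matrix(integer(0), 0, 2))
    unique(cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  }
  leU <- norm(le); lrU <- norm(lr)
  keyOf <- function(m) m[, 1] * (nNodes + 1) + m[, 2]
  nOverlap <- sum(keyOf(lrU) %in% keyOf(leU))
  both <- rbind(leU, lrU)
  both <- both[!duplicated(keyOf(both)), , drop = FALSE]
  g <- igraph::graph_from_edgelist(both, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nNodes - igraph::vcount(g)))
  nodes <- data.frame(
    area = if (is.null(area)) rep(NA_character_, nNodes) else area,
    x = if (is.null(centers)) NA_real_ else centers[, 1],
    y = if (is.null(centers)) NA_real_ else centers[, 2],
    z = if (is.null(centers)) NA_real_ else centers[, 3],
    stringsAsFactors = FALSE)
  list(network = new("ConnectomeNetwork", graph = g, nodes = nodes),
       nOverlap = nOverlap)
}
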