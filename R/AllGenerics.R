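#' @include AllClasses.R
NULL

#' Number of triangles in a mesh
#' @param x A TriangleMesh.
#' @return Integer triangle count.
#' @export
setGeneric("nTriangles", function(x) standardGeneric("nTriangles"))

#' @rdname nTriangles
#' @export
setMethod("nTriangles", "TriangleMesh", function(x) nrow(x@triangles))

#' Number of vertices in a mesh
#' @param x A TriangleMesh.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname nVertices
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))

#' Per-triangle area labels
#' @param x A TriangleMesh or ConnectomeNetwork.
#' @return Character vector of area names.
#' @export
setGeneric("areaLabels", function(x) standardGeneric("areaLabels"))

#' @rdname areaLabels
#' @export
setMethod("areaLabels", "TriangleMesh", function(x) x@areaLabels)

#' @rdname areaLabels
#' @export
setMethod("areaLabels", "ConnectomeNetwork", function(x) x@nodes$area)

#' Number of network nodes
#' @param x A ConnectomeNetwork.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "ConnectomeNetwork", function(x) igraph::vcount(x@graph))

#' Number of network edges
#' @param x A ConnectomeNetwork.
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname nEdges
#' @export
setMethod("nEdges", "ConnectomeNetwork", function(x) igraph::ecount(x@graph))

#' Underlying igraph graph
#' @param x A ConnectomeNetwork or BenchmarkGraph.
#' @return The igraph object.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "ConnectomeNetwork", function(x) x@graph)

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "BenchmarkGraph", function(x) x@graph)

#' Node metadata table
#' @param x A ConnectomeNetwork.
#' @return data.frame with area, centroid coordinates and optional module.
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname nodeTable
#' @export
setMethod("nodeTable", "ConnectomeNetwork", function(x) x@nodes)

#' Number of streamlines
#' @param x A StreamlineSet.
#' @export
setGeneric("nStreamlines", function(x) standardGeneric("nStreamlines"))

#' @rdname nStreamlines
#' @export
setMethod("nStreamlines", "StreamlineSet", function(x) length(x@points))

#' Generator validity labels of a StreamlineSet
#' @param x A StreamlineSet.
#' @return Character vector (`valid`, `too-short`, `too-long`,
#'   `sharp-angle`) or length 0 if unlabelled.
#' @export
setGeneric("streamlineLabels", function(x) standardGeneric("streamlineLabels"))

#' @rdname streamlineLabels
#' @export
setMethod("streamlineLabels", "StreamlineSet", function(x) x@labels)

#' Module membership of a Partition
#' @param x A Partition or GammaScanResult (its consensus).
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))

#' @rdname moduleMembership
#' @export
setMethod("moduleMembership", "Partition", function(x) x@membership)

#' @rdname moduleMembership
#' @export
setMethod("moduleMembership", "GammaScanResult",
          function(x) x@consensus@membership)

setMethod("show", "TriangleMesh", function(object) {
  cat("TriangleMesh:", nVertices(object), "vertices,",
      nTriangles(object), "triangles")
  if (length(object@areaLabels))
    cat(",", length(unique(object@areaLabels)), "areas")
  cat("\n")
})

setMethod("show", "StreamlineSet", function(object) {
  cat("StreamlineSet:", nStreamlines(object), "streamlines")
  if (length(object@labels)) {
    tab <- table(object@labels)
    cat(" (", paste(names(tab), tab, sep = ":", collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
})

setMethod("show", "ConnectomeNetwork", function(object) {
  cat("ConnectomeNetwork:", nNodes(object), "nodes,",
      nEdges(object), "edges,",
      length(unique(object@nodes$area)), "areas\n")
})

setMethod("show", "BoxCover", function(object) {
  cat("BoxCover: ellB =", object@ellB, "(rB =", object@rB, "),",
      object@nBoxes, "boxes over", length(object@boxOfNode), "nodes\n")
})

setMethod("show", "FractalFit", function(object) {
  cat(sprintf("FractalFit: d_B = %.4f (se %.4f, R^2 %.4f) over ell_B {%s}\n",
              object@dB, object@stderr, object@rSquared,
              paste(object@fitRange, collapse = ",")))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: %d nodes, %d modules, Q = %.6f (gamma %.2f)\n",
              length(object@membership),
              length(unique(object@membership)),
              object@Q, object@gamma))
})

setMethod("show", "GammaScanResult", function(object) {
  cat(sprintf(
    "GammaScanResult: %d gammas x %d runs; gamma* = %.2f, QMax* = %.4f; %d consensus modules\n",
    length(object@gammaGrid), object@nRuns, object@gammaStar,
    max(object@QMax), length(unique(object@consensus@membership))))
})

setMethod("show", "ModulePairStats", function(object) {
  cat(sprintf(
    "ModulePairStats %s~%s: %d module pairs, %d nonzero (zero fraction %.3f)\n",
    object@areaPair[1], object@areaPair[2], object@nPairsTotal,
    object@nNonzero, object@zeroFraction))
})

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene: ")
  show(object@mesh)
  cat("  ", nStreamlines(object@streamlines), "streamlines,",
      length(unique(object@plantedModules)), "planted modules, fidelity",
      object@targetingFidelity, "\n")
})

setMethod("show", "BenchmarkGraph", function(object) {
  cat(sprintf("BenchmarkGraph (%s): %d nodes, %d edges",
              object@family, igraph::vcount(object@graph),
              igraph::ecount(object@graph)))
  if (!is.na(object@knownDimension))
    cat(sprintf(", known dimension %.4f", object@knownDimension))
  cat("\n")
})
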