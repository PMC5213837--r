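#' @import methods
#' @importFrom igraph vcount ecount gorder gsize
NULL

#' TriangleMesh: a triangulated surface with per-triangle area labels
#'
#' The spatial substrate of the analysis. Triangles (not vertices) are the
#' nodes of the connectome network; each triangle carries the name of the
#' cortical "area" (atlas parcel) it belongs to.
#'
#' Vertices and triangle indices are stored 1-based in memory; all on-disk
#' formats (OFF, PLY, TSV tables) use 0-based indices per their conventions.
#'
#' @slot vertices Numeric matrix (nVertices x 3), coordinates in mm.
#' @slot triangles Integer matrix (nTriangles x 3), 1-based vertex indices.
#' @slot areaLabels Character vector of length nTriangles; area name per
#'   triangle (may be length 0 when unlabelled).
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 areaLabels = "character"),
  validity = function(object) {
    v <- object@vertices; tr <- object@triangles
    if (ncol(v) != 3L) return("vertices must have 3 columns")
    if (ncol(tr) != 3L) return("triangles must have 3 columns")
    if (!is.numeric(v)) return("vertices must be numeric")
    if (any(!is.finite(v))) return("vertices contain non-finite coordinates")
    if (nrow(tr) > 0) {
      if (min(tr) < 1L || max(tr) > nrow(v))
        return("triangle vertex indices out of range")
    }
    if (length(object@areaLabels) > 0 &&
        length(object@areaLabels) != nrow(tr))
      return("areaLabels length must equal triangle count")
    TRUE
  })

#' StreamlineSet: a collection of 3D polylines
#'
#' Each streamline is an ordered polyline of 3D points (mm). The set may
#' carry per-streamline validity labels assigned by the synthetic generator
#' (`valid`, `too-short`, `too-long`, `sharp-angle`), which the filtering
#' step can be audited against.
#'
#' @slot points List of numeric matrices (nPoints x 3), one per streamline.
#' @slot labels Character vector (possibly length 0) of generator labels.
#' @export
setClass("StreamlineSet",
  representation(points = "list", labels = "character"),
  validity = function(object) {
    for (i in seq_along(object@points)) {
      p <- object@points[[i]]
      if (!is.matrix(p) || ncol(p) != 3L)
        return(sprintf("streamline %d is not an n x 3 matrix", i))
      if (nrow(p) < 2L)
        return(sprintf("streamline %d has fewer than 2 points", i))
    }
    if (length(object@labels) > 0 &&
        length(object@labels) != length(object@points))
      return("labels length must equal streamline count")
    TRUE
  })

#' ConnectomeNetwork: binary undirected network over mesh triangles
#'
#' Wraps an igraph graph (simple, undirected, unweighted) together with a
#' per-node metadata table: area label, centroid coordinates and, once
#' modules have been detected, a module id.
#'
#' @slot graph An igraph object; nodes are triangles.
#' @slot nodes data.frame with one row per node; columns at least
#'   `area`, `x`, `y`, `z` (module added later).
#' @export
setClass("ConnectomeNetwork",
  representation(graph = "ANY", nodes = "data.frame"),
  validity = function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
    if (igraph::is_directed(g)) return("graph must be undirected")
    if (any(igraph::which_loop(g))) return("graph must have no self-loops")
    if (igraph::any_multiple(g)) return("graph must be simple (binary)")
    if (nrow(object@nodes) != igraph::vcount(g))
      return("nodes table must have one row per graph vertex")
    TRUE
  })

#' BoxCover: one MEMB box covering at a fixed box size
#'
#' @slot ellB Integer box size (maximum chemical path length criterion).
#' @slot rB Integer covering radius, `floor((ellB - 1) / 2)`.
#' @slot boxOfNode Integer vector: box id (1..nBoxes) per node.
#' @slot centers Integer vector of center node ids in burning order
#'   (for `ellB == 2`, one representative per pair/singleton box).
#' @slot nBoxes Integer number of boxes.
#' @export
setClass("BoxCover",
  representation(ellB = "integer", rB = "integer", boxOfNode = "integer",
                 centers = "integer", nBoxes = "integer"),
  validity = function(object) {
    if (any(is.na(object@boxOfNode))) return("every node must be in a box")
    if (object@nBoxes != max(object@boxOfNode))
      return("nBoxes inconsistent with box assignments")
    if (length(object@centers) != object@nBoxes)
      return("one center per box required")
    TRUE
  })

#' FractalFit: box-counting curve and fitted fractal dimension
#'
#' @slot ell Integer vector of box sizes.
#' @slot nB Integer vector of box counts N_B(ell_B).
#' @slot nNodes Integer network size N.
#' @slot dB Fitted fractal dimension (negative log-log slope).
#' @slot rSquared Fit R-squared.
#' @slot stderr Standard error of the slope.
#' @slot fitRange Integer vector of ell values used in the fit.
#' @export
setClass("FractalFit",
  representation(ell = "integer", nB = "integer", nNodes = "integer",
                 dB = "numeric", rSquared = "numeric", stderr = "numeric",
                 fitRange = "integer"))

#' Partition: one modularity partition of a graph
#'
#' @slot membership Integer vector: module id per node.
#' @slot Q Modularity at the stated resolution, recomputable from the
#'   graph and membership by direct summation.
#' @slot gamma Resolution parameter used.
#' @slot seed Seed of the run that produced it.
#' @export
setClass("Partition",
  representation(membership = "integer", Q = "numeric", gamma = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (any(is.na(object@membership))) return("every node must be assigned")
    TRUE
  })

#' GammaScanResult: resolution scan with random-graph null
#'
#' For each resolution gamma, the mean modularity of repeated Louvain runs
#' on the data network and on a same-size random network; their difference
#' QMax selects the analysis resolution gammaStar, at which a consensus
#' partition is computed.
#'
#' @slot gammaGrid Numeric vector of resolutions.
#' @slot QNet,QRand Mean modularity per gamma (data / null).
#' @slot QMax Per-gamma difference `QNet - QRand`.
#' @slot gammaStar Resolution maximizing QMax (ties: smallest gamma).
#' @slot nRuns Louvain runs per gamma per network.
#' @slot consensus Partition at gammaStar.
#' @slot runsAtStar Integer matrix (nodes x runs) of memberships at
#'   gammaStar (kept for consensus audits).
#' @export
setClass("GammaScanResult",
  representation(gammaGrid = "numeric", QNet = "numeric", QRand = "numeric",
                 QMax = "numeric", gammaStar = "numeric", nRuns = "integer",
                 consensus = "Partition", runsAtStar = "matrix"),
  validity = function(object) {
    n <- length(object@gammaGrid)
    if (length(object@QNet) != n || length(object@QRand) != n ||
        length(object@QMax) != n)
      return("Q vectors must match gamma grid length")
    if (!object@gammaStar %in% object@gammaGrid)
      return("gammaStar must be on the grid")
    TRUE
  })

#' ModulePairStats: module-to-module edge densities between two areas
#'
#' For every pair (module i of area A, module j of area B), the edge
#' density is the number of inter-area edges between their node sets
#' divided by the number of possible node pairs |i| * |j| - the
#' "quadrilateral" statistic for long-range targeting.
#'
#' @slot areaPair Character vector of the two area names.
#' @slot density Numeric matrix (modules of A x modules of B).
#' @slot sizesA,sizesB Integer module sizes (named by module id).
#' @slot nPairsTotal,nNonzero Counts of module pairs / nonzero pairs.
#' @slot zeroFraction `1 - nNonzero / nPairsTotal`.
#' @export
setClass("ModulePairStats",
  representation(areaPair = "character", density = "matrix",
                 sizesA = "integer", sizesB = "integer",
                 nPairsTotal = "integer", nNonzero = "integer",
                 zeroFraction = "numeric"),
  validity = function(object) {
    d <- object@density
    if (any(d < 0 | d > 1)) return("densities must lie in [0, 1]")
    if (object@nPairsTotal != length(d))
      return("nPairsTotal inconsistent with density matrix")
    if (object@nNonzero != sum(d > 0))
      return("nNonzero inconsistent with density matrix")
    ok <- isTRUE(all.equal(object@zeroFraction,
                           1 - object@nNonzero / object@nPairsTotal))
    if (!ok) return("zeroFraction inconsistent")
    TRUE
  })

#' SyntheticScene: a full synthetic input bundle
#'
#' @slot mesh TriangleMesh with area labels.
#' @slot streamlines StreamlineSet with validity labels.
#' @slot plantedModules Integer vector: planted module id per triangle.
#' @slot pairMap data.frame with columns `source`, `target` (module ids).
#' @slot targetingFidelity Probability that a streamline joins a planted
#'   module pair rather than random triangles of the two areas.
#' @slot seed Master seed of the scene.
#' @export
setClass("SyntheticScene",
  representation(mesh = "TriangleMesh", streamlines = "StreamlineSet",
                 plantedModules = "integer", pairMap = "data.frame",
                 targetingFidelity = "numeric", seed = "integer"))

#' BenchmarkGraph: a graph with known dimension or planted partition
#'
#' @slot graph igraph object (connected).
#' @slot knownDimension Numeric fractal dimension, or `NA` when the family
#'   has none.
#' @slot plantedPartition Integer block id per node, or length 0.
#' @slot family Family name (`uv_flower`, `lattice2d`, `sbm`, ...).
#' @slot params Named list of family parameters.
#' @slot seed Integer seed (0 for deterministic families).
#' @export
setClass("BenchmarkGraph",
  representation(graph = "ANY", knownDimension = "numeric",
                 plantedPartition = "integer", family = "character",
                 params = "list", seed = "integer"),
  validity = function(object) {
    if (!igraph::is_igraph(object@graph)) return("graph must be igraph")
    if (!igraph::is_connected(object@graph))
      return("benchmark graph must be connected")
    TRUE
  })
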