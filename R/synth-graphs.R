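#' @include AllClasses.R utils.R
NULL

#' Deterministic (u,v)-flower fractal benchmark graph
#'
#' Starts from a cycle of `u + v` edges and, at each generation, replaces
#' every edge by two parallel paths of `u` and `v` edges. For `u > 1` the
#' family is a fractal with box dimension `log(u + v) / log(u)`, making it
#' the standard oracle for box-covering estimators. Edge count multiplies
#' by `u + v` each generation.
#'
#' @param u,v Path lengths, `1 < u <= v`.
#' @param generations Number of replacement generations (>= 1; generation
#'   1 is the base cycle).
#' @return A [BenchmarkGraph-class] with `knownDimension = log(u+v)/log(u)`.
#' @examples
#' fl <- makeUVFlower(2, 2, 3)
#' igraph::ecount(networkGraph(fl))  # 64
#' @export
makeUVFlower <- function(u, v, generations) {
  stopIfNot(u > 1, "u must exceed 1 (dimension ln(u+v)/ln(u) undefined)")
  stopIfNot(v >= u, "require u <= v")
  stopIfNot(generations >= 1, "generations must be >= 1")
  w <- u + v
  # generation 1: cycle of u+v edges
  edges <- cbind(seq_len(w), c(seq_len(w)[-1], 1L))
  nNodes <- w
  if (generations > 1) {
    for (g in seq_len(generations - 1L)) {
      newEdges <- matrix(0L, nrow(edges) * w, 2L)
      r <- 1L
      for (i in seq_len(nrow(edges))) {
        a <- edges[i, 1]; b <- edges[i, 2]
        for (len in c(u, v)) {
          inner <- if (len > 1) nNodes + seq_len(len - 1L) else integer(0)
          nNodes <- nNodes + len - 1L
          chain <- c(a, inner, b)
          for (s in seq_len(len)) {
            newEdges[r, ] <- c(chain[s], chain[s + 1L])
            r <- r + 1L
          }
        }
      }
      edges <- newEdges
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  new("BenchmarkGraph", graph = g, knownDimension = log(w) / log(u),
      plantedPartition = integer(0), family = "uv_flower",
      params = list(u = u, v = v, generations = generations), seed = 0L)
}

#' Periodic 2D lattice benchmark graph
#'
#' A toroidal (periodic) square lattice; box dimension 2.
#'
#' @param side Number of nodes per side.
#' @return A [BenchmarkGraph-class] with `knownDimension = 2`.
#' @export
makeLattice2D <- function(side) {
  stopIfNot(side >= 3, "side must be >= 3")
  g <- igraph::make_lattice(c(side, side), periodic = TRUE)
  new("BenchmarkGraph", graph = g, knownDimension = 2,
      plantedPartition = integer(0), family = "lattice2d",
      params = list(side = side), seed = 0L)
}

#' Connected planted-partition (stochastic block model) graph
#'
#' Standard SBM with `nBlocks` equal blocks, within-block edge probability
#' `pIn` and between-block probability `pOut`. Connectivity (needed by both
#' box covering and the modularity scan) is enforced by resampling up to
#' 100 times and, failing that, adding one minimal bridging edge between
#' consecutive components (lowest node ids); the method used is recorded in
#' `params$connectivity`.
#'
#' @param nBlocks Number of blocks.
#' @param blockSize Nodes per block.
#' @param pIn,pOut Edge probabilities, `pIn > pOut`.
#' @param seed Integer seed.
#' @return A [BenchmarkGraph-class] carrying the planted block labels.
#' @export
makePlantedPartitionGraph <- function(nBlocks, blockSize, pIn, pOut, seed) {
  stopIfNot(pIn > pOut, "pIn must exceed pOut")
  if ((blockSize - 1) * pIn < 1)
    warning("expected within-block degree < 1; block recovery not guaranteed")
  pref <- matrix(pOut, nBlocks, nBlocks)
  diag(pref) <- pIn
  sizes <- rep(blockSize, nBlocks)
  set.seed(seed)
  connectivity <- "resampled"
  g <- NULL
  for (try in seq_len(100L)) {
    cand <- igraph::sample_sbm(nBlocks * blockSize, pref.matrix = pref,
                               block.sizes = sizes)
    if (igraph::is_connected(cand)) { g <- cand; break }
  }
  if (is.null(g)) {
    g <- cand
    comp <- igraph::components(g)$membership
    reps <- vapply(seq_len(max(comp)), function(ci) min(which(comp == ci)),
                   integer(1))
    bridges <- cbind(reps[-length(reps)], reps[-1])
    g <- igraph::add_edges(g, t(bridges))
    connectivity <- "bridged"
  }
  planted <- rep(seq_len(nBlocks), each = blockSize)
  new("BenchmarkGraph", graph = g, knownDimension = NA_real_,
      plantedPartition = as.integer(planted), family = "sbm",
      params = list(nBlocks = nBlocks, blockSize = blockSize, pIn = pIn,
                    pOut = pOut, connectivity = connectivity),
      seed = as.integer(seed))
}
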