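#' @include AllClasses.R boxcover.R utils.R
NULL

#' Modularity by direct summation
#'
#' Computes `Q(gamma) = sum_c [ w_in(c)/m - gamma * (d_c / (2m))^2 ]`,
#' equivalently `(1/2m) sum_ij [A_ij - gamma k_i k_j / (2m)] delta(c_i,c_j)`,
#' directly from the edge list - independently of any optimizer, so the
#' optimizer's reported Q can always be audited against this routine.
#'
#' @param graph igraph graph (optionally weighted via `weights`).
#' @param membership Integer module id per node.
#' @param gamma Resolution parameter.
#' @param weights Optional edge weights (defaults to 1).
#' @return Numeric modularity value.
#' @export
computeModularity <- function(graph, membership, gamma = 1,
                              weights = NULL) {
  g <- asGraph(graph)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (is.null(weights)) rep(1, nrow(el)) else weights
  m <- sum(w)
  if (m == 0) return(0)
  deg <- rep(0, igraph::vcount(g))
  for (k in 1:2) {
    s <- rowsum(w, el[, k])
    deg[as.integer(rownames(s))] <- deg[as.integer(rownames(s))] + s[, 1]
  }
  same <- membership[el[, 1]] == membership[el[, 2]]
  win <- tapply(w[same], membership[el[same, 1]], sum)
  dc <- tapply(deg, membership, sum)
  sum(win[match(names(dc), names(win))] / m, na.rm = TRUE) -
    gamma * sum((dc / (2 * m))^2)
}

#' One seeded Louvain run at resolution gamma
#'
#' Runs the Louvain algorithm (two-phase greedy modularity maximization
#' with the resolution parameter scaling the degree-product null term).
#' The run seed controls the randomized optimization order, so repeated
#' runs explore different local optima. The reported Q is recomputed from
#' the final membership by direct summation ([computeModularity()]).
#'
#' @param network Connected graph (ConnectomeNetwork, BenchmarkGraph or
#'   igraph); may carry edge weights via `weights`.
#' @param gamma Resolution parameter (> 0).
#' @param seed Integer run seed.
#' @param weights Optional edge weights.
#' @return A [Partition-class].
#' @export
louvainPartition <- function(network, gamma = 1, seed = 1L,
                             weights = NULL) {
  g <- asGraph(network)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  stopIfNot(gamma > 0, "gamma must be positive")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = weights, resolution = gamma)
  mem <- as.integer(igraph::membership(cl))
  new("Partition", membership = mem,
      Q = computeModularity(g, mem, gamma, weights = weights),
      gamma = gamma, seed = as.integer(seed))
}

#' Same-size random-graph null
#'
#' Uniform G(n, m) random graph with the same number of nodes and edges
#' as the input network. Connectivity is deliberately not enforced (the
#' modularity comparison runs on it regardless; box covering is never
#' applied to nulls).
#'
#' @param network Graph whose N and k to match.
#' @param seed Integer seed.
#' @return An igraph graph.
#' @export
randomNull <- function(network, seed) {
  g <- asGraph(network)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  stopIfNot(n >= 2, "need at least 2 nodes")
  if (m > choose(n, 2))
    stop("more edges than a simple graph allows", call. = FALSE)
  set.seed(seed)
  igraph::sample_gnm(n, m)
}

#' Resolution scan with random-graph null (Q_MAX) and consensus
#'
#' For each gamma on the grid, runs `nRuns` Louvain partitions on the
#' data network and `nRuns` on one same-N,k random-graph realization, and
#' records the mean modularities. `QMax(gamma) = Qbar_net - Qbar_rand`;
#' the analysis resolution `gammaStar` is the grid point maximizing QMax
#' (ties: smallest gamma). A consensus partition over the data runs at
#' `gammaStar` summarizes the scan.
#'
#' All run seeds derive from `seed` via [deriveSeed()], so a single master
#' seed reproduces the whole scan.
#'
#' @param network Connected graph.
#' @param gammaGrid Numeric grid (default `seq(0.6, 1.4, by = 0.02)`,
#'   41 values).
#' @param nRuns Runs per gamma per network (default 25).
#' @param seed Master seed for the scan.
#' @param tau Consensus co-classification threshold (default 0.5).
#' @param nullGraph Optional: supply the null graph explicitly (used by
#'   self-comparison tests); default generates one G(n, m) realization.
#' @return A [GammaScanResult-class].
#' @export
gammaScan <- function(network, gammaGrid = seq(0.6, 1.4, by = 0.02),
                      nRuns = 25L, seed = 1L, tau = 0.5,
                      nullGraph = NULL) {
  g <- asGraph(network)
  stopIfNot(length(gammaGrid) >= 1, "gamma grid must be non-empty")
  nullG <- if (is.null(nullGraph)) {
    randomNull(g, deriveSeed(seed, "null"))
  } else asGraph(nullGraph)
  nG <- length(gammaGrid)
  QNet <- QRand <- numeric(nG)
  memNet <- vector("list", nG)
  for (gi in seq_len(nG)) {
    gamma <- gammaGrid[gi]
    runsN <- matrix(0L, igraph::vcount(g), nRuns)
    qn <- qr_ <- numeric(nRuns)
    for (r in seq_len(nRuns)) {
      pn <- louvainPartition(g, gamma, deriveSeed(seed, "net", gi, r))
      runsN[, r] <- pn@membership
      qn[r] <- pn@Q
      pr <- louvainPartition(nullG, gamma, deriveSeed(seed, "rand", gi, r))
      qr_[r] <- pr@Q
    }
    QNet[gi] <- mean(qn)
    QRand[gi] <- mean(qr_)
    memNet[[gi]] <- runsN
  }
  QMax <- QNet - QRand
  starIdx <- which.max(QMax)       # first max = smallest gamma on ties
  gammaStar <- gammaGrid[starIdx]
  runsAtStar <- memNet[[starIdx]]
  consensus <- consensusPartition(runsAtStar, tau = tau,
                                  seed = deriveSeed(seed, "consensus"),
                                  graph = g, gamma = gammaStar)
  new("GammaScanResult", gammaGrid = gammaGrid, QNet = QNet,
      QRand = QRand, QMax = QMax, gammaStar = gammaStar,
      nRuns = as.integer(nRuns), consensus = consensus,
      runsAtStar = runsAtStar)
}

#' Consensus partition over repeated clustering runs
#'
#' Consensus clustering: build the co-classification
#' matrix D (fraction of runs in which each node pair shares a module),
#' zero entries below `tau`, re-cluster D as a weighted graph with Louvain
#' at resolution 1 (as many runs as input columns), and repeat until all
#' re-clustering runs agree, up to `maxIter` iterations. Module labels
#' from different runs are never compared directly - only co-classification
#' is used - so the procedure is label-permutation invariant.
#'
#' @param runs Integer matrix (nodes x runs) of module memberships.
#' @param tau Co-classification threshold in [0, 1].
#' @param seed Integer seed for the re-clustering runs.
#' @param graph Optional original graph: when given, the returned
#'   Partition's Q is evaluated on it at `gamma`.
#' @param gamma Resolution for the reported Q (default 1).
#' @param maxIter Maximum consensus iterations (default 20).
#' @return A [Partition-class].
#' @export
consensusPartition <- function(runs, tau = 0.5, seed = 1L, graph = NULL,
                               gamma = 1, maxIter = 20L) {
  stopIfNot(is.matrix(runs) && ncol(runs) >= 2,
            "need a nodes x runs matrix with >= 2 runs")
  n <- nrow(runs)
  R <- ncol(runs)
  agree <- function(m) all(apply(m, 2, function(col)
    identical(canonicalLabels(col), canonicalLabels(m[, 1]))))
  cur <- runs
  for (iter in seq_len(maxIter)) {
    if (agree(cur)) break
    D <- matrix(0, n, n)
    for (r in seq_len(ncol(cur))) {
      mm <- cur[, r]
      D <- D + outer(mm, mm, "==")
    }
    D <- D / ncol(cur)
    D[D < tau] <- 0
    diag(D) <- 0
    gD <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                              weighted = TRUE)
    nxt <- matrix(0L, n, R)
    for (r in seq_len(R)) {
      p <- louvainPartition(gD, gamma = 1,
                            seed = deriveSeed(seed, "consensus", iter, r),
                            weights = igraph::E(gD)$weight)
      nxt[, r] <- p@membership
    }
    cur <- nxt
  }
  mem <- canonicalLabels(cur[, 1])
  q <- if (!is.null(graph)) computeModularity(graph, mem, gamma) else NA_real_
  new("Partition", membership = mem, Q = q, gamma = gamma,
      seed = as.integer(seed))
}

# relabel modules 1,2,... in order of first appearance
canonicalLabels <- function(mem) {
  as.integer(match(mem, unique(mem)))
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Integer membership vectors over the same nodes.
#' @return Numeric ARI in [-1, 1].
#' @export
adjustedRandIndex <- function(a, b) {
  stopIfNot(length(a) == length(b), "partitions must cover the same nodes")
  tab <- table(a, b)
  sumIJ <- sum(choose(tab, 2))
  sumI <- sum(choose(rowSums(tab), 2))
  sumJ <- sum(choose(colSums(tab), 2))
  nPairs <- choose(length(a), 2)
  expected <- sumI * sumJ / nPairs
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(ifelse(sumIJ == expected, 1, 0))
  (sumIJ - expected) / (maxIdx - expected)
}

#' Within-area module detection
#'
#' Runs an independent resolution scan ([gammaScan()]) on the induced
#' subgraph of every area of the network. If an area's induced subgraph is
#' disconnected, its largest connected component is analyzed and the
#' remaining nodes are reported unassigned (module NA). Areas with fewer
#' than 3 nodes are skipped with a warning. Module ids are namespaced by
#' area (`"<area>.<k>"`).
#'
#' @param network A [ConnectomeNetwork-class] with area labels.
#' @param gammaGrid,nRuns,tau Scan parameters (see [gammaScan()]).
#' @param seed Master seed; per-area seeds derive from it.
#' @return List with `scans` (named list of GammaScanResult), `modules`
#'   (data.frame: node, area, module) and `unassigned` (integer node ids
#'   outside the analyzed components).
#' @export
withinAreaModules <- function(network, gammaGrid = seq(0.6, 1.4, by = 0.02),
                              nRuns = 25L, seed = 1L, tau = 0.5) {
  stopIfNot(is(network, "ConnectomeNetwork"),
            "network must be a ConnectomeNetwork")
  g <- network@graph
  areas <- sort(unique(network@nodes$area))
  scans <- list()
  moduleOf <- rep(NA_character_, igraph::vcount(g))
  unassigned <- integer(0)
  for (a in areas) {
    nodes <- which(network@nodes$area == a)
    if (length(nodes) < 3L) {
      warning(sprintf("area %s has fewer than 3 nodes; skipped", a))
      unassigned <- c(unassigned, nodes)
      next
    }
    sub <- igraph::induced_subgraph(g, nodes)
    comp <- igraph::components(sub)
    keepLocal <- seq_along(nodes)
    if (comp$no > 1) {
      big <- which.max(comp$csize)
      keepLocal <- which(comp$membership == big)
      unassigned <- c(unassigned, nodes[comp$membership != big])
      sub <- igraph::induced_subgraph(sub, keepLocal)
    }
    scan <- gammaScan(sub, gammaGrid = gammaGrid, nRuns = nRuns,
                      seed = deriveSeed(seed, "area", a), tau = tau)
    scans[[a]] <- scan
    moduleOf[nodes[keepLocal]] <-
      paste0(a, ".", scan@consensus@membership)
  }
  modules <- data.frame(node = seq_len(igraph::vcount(g)),
                        area = network@nodes$area,
                        module = moduleOf, stringsAsFactors = FALSE)
  list(scans = scans, modules = modules, unassigned = unassigned)
}
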