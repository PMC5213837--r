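#' @include AllClasses.R utils.R
NULL

# coerce ConnectomeNetwork / BenchmarkGraph / igraph to igraph
asGraph <- function(network) {
  if (is(network, "ConnectomeNetwork")) return(network@graph)
  if (is(network, "BenchmarkGraph")) return(network@graph)
  if (igraph::is_igraph(network)) return(network)
  stop("expected a ConnectomeNetwork, BenchmarkGraph or igraph object",
       call. = FALSE)
}

requireConnected <- function(g) {
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop(sprintf("network is disconnected (%d components); box covering requires a connected graph",
                 comp$no), call. = FALSE)
  invisible(g)
}

# balls of chemical radius r around every node (list of integer vectors)
chemicalBalls <- function(g, r) {
  lapply(igraph::ego(g, order = r, mindist = 0), as.integer)
}

#' Maximum excluded mass burning (MEMB) box covering
#'
#' Covers a connected unweighted graph with boxes of size `ellB` under the
#' radius criterion `rB = floor((ellB - 1) / 2)`: repeatedly select the
#' node of maximum excluded mass (number of not-yet-covered nodes within
#' chemical distance `rB`; ties broken by lowest node id) as a center and
#' mark its ball covered, until all nodes are covered. Every non-center
#' node is then assigned to a center at minimal chemical distance, ties
#' broken by burning order via a level-synchronous multi-source BFS, so
#' each box induces a connected subgraph. Since boxes have radius `rB`
#' around their center, pairwise in-box distances are at most
#' `2 rB <= ellB - 1`, i.e. strictly below `ellB`.
#'
#' For `ellB = 2` (`rB = 0`) the radius criterion degenerates to
#' singletons, so a greedy pairing on the diameter-1 criterion is used
#' instead: nodes in order of increasing degree (ties: lowest id) are
#' paired with their lowest-degree uncovered neighbor, or form a
#' singleton box; leaf-first pairing is optimal on trees and on the
#' structured benchmark families.
#'
#' Because the target quantity is the *minimum* number of boxes, the
#' greedy covering is run `nRestarts` times - one deterministic pass
#' breaking ties by lowest node id, the rest breaking ties uniformly at
#' random from seeds derived from `seed` - and the smallest cover is
#' kept (earliest pass on ties). Centers whose entire ball is also
#' covered by other centers are then pruned. Excluded masses are updated
#' incrementally (only nodes whose balls contain newly covered nodes are
#' recomputed); the result is identical to full recomputation.
#'
#' @param network A connected [ConnectomeNetwork-class],
#'   [BenchmarkGraph-class] or igraph graph.
#' @param ellB Integer box size >= 2.
#' @param seed Integer seed for the randomized tie-breaking restarts.
#' @param nRestarts Total greedy passes (default 4; 1 = deterministic
#'   lowest-id pass only).
#' @return A [BoxCover-class].
#' @export
membCover <- function(network, ellB, seed = 1L, nRestarts = 4L) {
  g <- asGraph(network)
  requireConnected(g)
  stopIfNot(ellB >= 2, "ellB must be >= 2")
  n <- igraph::vcount(g)
  if (ellB == 2L) return(membPairCover(g))
  rB <- as.integer((ellB - 1) %/% 2)
  balls <- chemicalBalls(g, rB)
  bi <- rep(seq_len(n), lengths(balls))
  bv <- unlist(balls, use.names = FALSE)
  inBallOf <- split(bi, bv)
  best <- NULL
  for (pass in seq_len(max(1L, nRestarts))) {
    tieSeed <- if (pass == 1L) NULL else deriveSeed(seed, "restart", pass)
    centers <- membGreedyCenters(balls, inBallOf, n, tieSeed)
    centers <- pruneRedundantCenters(balls, centers, n)
    if (is.null(best) || length(centers) < length(best))
      best <- centers
  }
  boxOf <- assignBoxesBFS(g, best)
  new("BoxCover", ellB = as.integer(ellB), rB = rB,
      boxOfNode = boxOf, centers = as.integer(best),
      nBoxes = length(best))
}

# one greedy maximum-excluded-mass pass; ties by lowest id (tieSeed
# NULL) or uniformly at random under the given seed
membGreedyCenters <- function(balls, inBallOf, n, tieSeed = NULL) {
  if (!is.null(tieSeed)) set.seed(tieSeed)
  covered <- logical(n)
  mass <- lengths(balls)
  centers <- integer(0)
  while (!all(covered)) {
    if (is.null(tieSeed)) {
      c0 <- which.max(mass)  # lowest index on ties
    } else {
      mx <- which(mass == max(mass))
      c0 <- if (length(mx) == 1L) mx else mx[sample.int(length(mx), 1L)]
    }
    centers <- c(centers, c0)
    newly <- balls[[c0]][!covered[balls[[c0]]]]
    covered[newly] <- TRUE
    affected <- unique(unlist(inBallOf[as.character(newly)],
                              use.names = FALSE))
    for (a in affected) mass[a] <- sum(!covered[balls[[a]]])
  }
  centers
}

# drop centers (latest first) whose ball is entirely covered by others
pruneRedundantCenters <- function(balls, centers, n) {
  coverCount <- integer(n)
  for (c0 in centers) {
    b <- balls[[c0]]
    coverCount[b] <- coverCount[b] + 1L
  }
  keep <- rep(TRUE, length(centers))
  for (i in rev(seq_along(centers))) {
    b <- balls[[centers[i]]]
    if (all(coverCount[b] >= 2L)) {
      keep[i] <- FALSE
      coverCount[b] <- coverCount[b] - 1L
    }
  }
  centers[keep]
}

# level-synchronous multi-source BFS assignment: nodes join the box of the
# first center (in burning order) to reach them at their minimal distance.
assignBoxesBFS <- function(g, centers) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  boxOf <- rep(NA_integer_, n)
  boxOf[centers] <- seq_along(centers)
  frontier <- centers  # already ordered by burning order
  while (any(is.na(boxOf)) && length(frontier)) {
    nxt <- integer(0)
    for (f in frontier) {
      nb <- as.integer(adj[[f]])
      nb <- nb[is.na(boxOf[nb])]
      if (length(nb)) {
        boxOf[nb] <- boxOf[f]
        nxt <- c(nxt, nb)
      }
    }
    # keep next frontier ordered by box burning order, then node id
    nxt <- unique(nxt)
    frontier <- nxt[order(boxOf[nxt], nxt)]
  }
  boxOf
}

# ellB = 2: greedy matching on the diameter-1 criterion. Leaf-first
# (ascending-degree) pairing, partner of minimum degree: optimal on
# trees, hence on paths and stars, and on cycles and cliques.
membPairCover <- function(g) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  ord <- order(deg, seq_len(n))
  boxOf <- rep(NA_integer_, n)
  centers <- integer(0)
  b <- 0L
  for (u in ord) {
    if (!is.na(boxOf[u])) next
    b <- b + 1L
    boxOf[u] <- b
    centers <- c(centers, u)
    nb <- as.integer(adj[[u]])
    nb <- nb[is.na(boxOf[nb])]
    if (length(nb)) {
      v <- nb[order(deg[nb], nb)][1]
      boxOf[v] <- b
    }
  }
  new("BoxCover", ellB = 2L, rB = 0L, boxOfNode = boxOf,
      centers = as.integer(centers), nBoxes = b)
}

#' Verify the radius criterion of a box cover
#'
#' Checks that every node lies within `rB` of its box center (`ellB >= 3`)
#' or that every box is a single node or an adjacent pair (`ellB = 2`),
#' and that each box induces a connected subgraph.
#'
#' @param network The covered graph.
#' @param cover A [BoxCover-class].
#' @return TRUE (invisibly) or an error describing the violated box.
#' @export
validateCover <- function(network, cover) {
  g <- asGraph(network)
  for (b in seq_len(cover@nBoxes)) {
    members <- which(cover@boxOfNode == b)
    sub <- igraph::induced_subgraph(g, members)
    if (igraph::components(sub)$no != 1)
      stop(sprintf("box %d induces a disconnected subgraph", b),
           call. = FALSE)
    if (cover@ellB == 2L) {
      if (length(members) > 2L)
        stop(sprintf("box %d has %d members under ellB = 2", b,
                     length(members)), call. = FALSE)
    } else {
      d <- igraph::distances(g, v = cover@centers[b], to = members)
      if (any(d > cover@rB))
        stop(sprintf("box %d violates the radius criterion", b),
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Exact minimum box cover by exhaustive search (test oracle)
#'
#' Enumerates all partitions of the node set into connected boxes
#' satisfying the radius criterion (adjacent pairs / singletons for
#' `ellB = 2`) via a bitmask dynamic program, returning the true minimum
#' box count. Refuses graphs with more than 12 nodes.
#'
#' @param network Connected graph with at most 12 nodes.
#' @param ellB Integer box size >= 2.
#' @return Integer: the minimum number of boxes.
#' @export
bruteForceMinCover <- function(network, ellB) {
  g <- asGraph(network)
  requireConnected(g)
  n <- igraph::vcount(g)
  if (n > 12L)
    stop("bruteForceMinCover refuses graphs with more than 12 nodes",
         call. = FALSE)
  rB <- as.integer((ellB - 1) %/% 2)
  D <- igraph::distances(g)
  adjM <- as.matrix(igraph::as_adjacency_matrix(g))
  nodesOf <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
  valid <- logical(2^n)
  for (mask in seq_len(2^n - 1L)) {
    s <- nodesOf(mask)
    if (ellB == 2L) {
      valid[mask + 1L] <- length(s) == 1L ||
        (length(s) == 2L && adjM[s[1], s[2]] == 1)
    } else {
      if (any(vapply(s, function(c0) all(D[c0, s] <= rB), logical(1)))) {
        sub <- igraph::induced_subgraph(g, s)
        valid[mask + 1L] <- igraph::components(sub)$no == 1L
      }
    }
  }
  validMasks <- which(valid) - 1L
  lowBit <- bitwAnd(validMasks, -validMasks)
  byLow <- split(validMasks, lowBit)
  f <- rep(Inf, 2^n)
  f[1] <- 0
  for (mask in seq_len(2^n - 1L)) {
    b <- bitwAnd(mask, -mask)
    cand <- byLow[[as.character(b)]]
    cand <- cand[bitwAnd(cand, mask) == cand]
    if (length(cand))
      f[mask + 1L] <- 1 + min(f[mask - cand + 1L])
  }
  as.integer(f[2^n])
}

#' Box-counting curve N_B(ell_B)
#'
#' Runs [membCover()] over a range of box sizes and returns the counts.
#'
#' @param network Connected graph.
#' @param ellRange Integer vector of box sizes (default 2:10, the
#'   conventional `1 < ell_B < 11` range).
#' @param seed Seed passed through to [membCover()].
#' @return data.frame with columns `ell`, `nB`, `nBOverN`.
#' @export
boxcountCurve <- function(network, ellRange = 2:10, seed = 1L) {
  g <- asGraph(network)
  n <- igraph::vcount(g)
  nB <- vapply(ellRange, function(l) membCover(g, l, seed)@nBoxes, integer(1))
  data.frame(ell = as.integer(ellRange), nB = nB, nBOverN = nB / n)
}

#' Fit the fractal dimension from a box-counting curve
#'
#' Ordinary least squares of `log(N_B / N)` on `log(ell_B)`; the fractal
#' dimension `d_B` is the negative slope. Because the radius criterion
#' makes `N_B` depend on `ell_B` only through `floor((ell_B - 1)/2)`,
#' even box sizes duplicate the preceding odd size; the default fit range
#' therefore uses the odd sizes {3, 5, 7, 9} to avoid duplicated points
#' biasing the slope.
#'
#' @param curve data.frame from [boxcountCurve()].
#' @param nNodes Network size N.
#' @param fitRange Integer vector of ell values to fit (default: odd
#'   values >= 3 present in the curve).
#' @return A [FractalFit-class].
#' @export
fitFractalDimension <- function(curve, nNodes, fitRange = NULL) {
  if (is.null(fitRange))
    fitRange <- curve$ell[curve$ell >= 3 & curve$ell %% 2 == 1]
  use <- curve$ell %in% fitRange & curve$nB > 1
  if (sum(use) < 3)
    stop("need at least 3 fit points with N_B > 1", call. = FALSE)
  x <- log(curve$ell[use])
  y <- log(curve$nB[use] / nNodes)
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact power-law input ("essentially perfect fit")
  sm <- suppressWarnings(summary(fit))
  new("FractalFit", ell = curve$ell, nB = curve$nB,
      nNodes = as.integer(nNodes),
      dB = -unname(stats::coef(fit)[2]),
      rSquared = sm$r.squared,
      stderr = unname(sm$coefficients[2, 2]),
      fitRange = as.integer(curve$ell[use]))
}
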