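#' @include modularity.R
NULL

#' Module-to-module edge densities between two areas
#'
#' For every pair (module i of area A, module j of area B) the edge
#' density is the number of inter-area edges joining their node sets
#' divided by all possible node pairs `|i| * |j|` - the per-"quadrilateral"
#' statistic quantifying whether long-range connections target specific
#' modules. Only edges with one endpoint in A and one in B are counted.
#'
#' @param network A [ConnectomeNetwork-class].
#' @param moduleOf Character vector (length nNodes): module id per node
#'   (NA allowed outside the two areas).
#' @param areaA,areaB Distinct area names.
#' @return A [ModulePairStats-class].
#' @export
modulePairDensities <- function(network, moduleOf, areaA, areaB) {
  stopIfNot(areaA != areaB, "areas must differ")
  area <- network@nodes$area
  inA <- which(area == areaA & !is.na(moduleOf))
  inB <- which(area == areaB & !is.na(moduleOf))
  stopIfNot(length(inA) > 0 && length(inB) > 0,
            "both areas must contain module-assigned nodes")
  modsA <- sort(unique(moduleOf[inA]))
  modsB <- sort(unique(moduleOf[inB]))
  sizesA <- vapply(modsA, function(m) sum(moduleOf[inA] == m), integer(1))
  sizesB <- vapply(modsB, function(m) sum(moduleOf[inB] == m), integer(1))
  if (any(sizesA == 0) || any(sizesB == 0))
    stop("empty module (division by zero)", call. = FALSE)
  el <- igraph::as_edgelist(network@graph, names = FALSE)
  aSide <- area[el[, 1]]; bSide <- area[el[, 2]]
  cross <- (aSide == areaA & bSide == areaB) |
    (aSide == areaB & bSide == areaA)
  el <- el[cross, , drop = FALSE]
  counts <- matrix(0, length(modsA), length(modsB),
                   dimnames = list(modsA, modsB))
  if (nrow(el)) {
    # orient rows as (node in A, node in B)
    swap <- area[el[, 1]] == areaB
    el[swap, ] <- el[swap, c(2, 1)]
    mA <- moduleOf[el[, 1]]; mB <- moduleOf[el[, 2]]
    ok <- !is.na(mA) & !is.na(mB)
    if (any(ok)) {
      tab <- table(factor(mA[ok], levels = modsA),
                   factor(mB[ok], levels = modsB))
      counts <- counts + unclass(tab)
    }
  }
  density <- counts / outer(sizesA, sizesB)
  nTot <- length(density)
  nNz <- sum(density > 0)
  new("ModulePairStats", areaPair = c(areaA, areaB), density = density,
      sizesA = sizesA, sizesB = sizesB,
      nPairsTotal = as.integer(nTot), nNonzero = as.integer(nNz),
      zeroFraction = 1 - nNz / nTot)
}

#' Flatten ModulePairStats into a module-pair table
#'
#' @param stats A [ModulePairStats-class] or list of them.
#' @return data.frame with columns `areaA`, `areaB`, `moduleA`, `moduleB`,
#'   `density`, `sizeA`, `sizeB`.
#' @export
modulePairTable <- function(stats) {
  if (is(stats, "ModulePairStats")) stats <- list(stats)
  do.call(rbind, lapply(stats, function(s) {
    grid <- expand.grid(moduleA = rownames(s@density),
                        moduleB = colnames(s@density),
                        stringsAsFactors = FALSE)
    data.frame(areaA = s@areaPair[1], areaB = s@areaPair[2],
               grid,
               density = as.vector(s@density),
               sizeA = s@sizesA[grid$moduleA],
               sizeB = s@sizesB[grid$moduleB],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

# all unordered area pairs of a network
areaPairs <- function(network) {
  areas <- sort(unique(network@nodes$area))
  if (length(areas) < 2) stop("need at least two areas", call. = FALSE)
  t(utils::combn(areas, 2))
}

# pooled targeting summary over a list of ModulePairStats
poolPairStats <- function(statsList) {
  tab <- modulePairTable(statsList)
  nz <- tab$density[tab$density > 0]
  list(nPairsTotal = nrow(tab),
       nNonzero = length(nz),
       zeroFraction = 1 - length(nz) / nrow(tab),
       medianNonzero = if (length(nz)) stats::median(nz) else NA_real_,
       nonzeroDensities = nz)
}

#' Compare module-targeting statistics against random networks
#'
#' Computes module-pair edge densities for every area pair of the data
#' network, then for `nRandom` same-N,k random networks (G(n, m) nulls)
#' on which modules are re-detected with the same within-area resolution
#' scan (null partitions are re-derived on each null, never transplanted).
#' If long-range connections target specific modules, the data network
#' shows a *larger* fraction of zero-density module pairs but *higher*
#' nonzero densities than the nulls.
#'
#' @param network A [ConnectomeNetwork-class].
#' @param dataModules Optional result of [withinAreaModules()] for the
#'   data network (computed if NULL).
#' @param gammaGrid,nRuns,tau Scan parameters reused for data and nulls.
#' @param nRandom Number of random networks (default 5).
#' @param seed Master seed.
#' @param nullGraphs Optional list of explicit null graphs (igraph),
#'   overriding G(n, m) generation; used for self-comparison checks.
#' @return List with `data` (pooled summary), `nulls` (list of pooled
#'   summaries), `dataStats`/`nullStats` (ModulePairStats lists), and
#'   `summary`: zeroFraction data vs mean null, median nonzero density
#'   data vs mean null, and their ratios.
#' @export
compareToRandom <- function(network, dataModules = NULL,
                            gammaGrid = seq(0.6, 1.4, by = 0.02),
                            nRuns = 25L, tau = 0.5, nRandom = 5L,
                            seed = 1L, nullGraphs = NULL) {
  if (!is.null(nullGraphs)) nRandom <- length(nullGraphs)
  if (is.null(dataModules))
    dataModules <- withinAreaModules(network, gammaGrid, nRuns,
                                     deriveSeed(seed, "data"), tau)
  pairs <- areaPairs(network)
  statsOf <- function(net, moduleOf) {
    lapply(seq_len(nrow(pairs)), function(i)
      modulePairDensities(net, moduleOf, pairs[i, 1], pairs[i, 2]))
  }
  dataStats <- statsOf(network, dataModules$modules$module)
  dataPool <- poolPairStats(dataStats)
  nullStats <- list(); nullPool <- list()
  for (r in seq_len(nRandom)) {
    gNull <- if (is.null(nullGraphs)) {
      randomNull(network, deriveSeed(seed, "nullgraph", r))
    } else asGraph(nullGraphs[[r]])
    nullNet <- new("ConnectomeNetwork", graph = gNull,
                   nodes = network@nodes)
    nm <- withinAreaModules(nullNet, gammaGrid, nRuns,
                            deriveSeed(seed, "nullscan", r), tau)
    nullStats[[r]] <- statsOf(nullNet, nm$modules$module)
    nullPool[[r]] <- poolPairStats(nullStats[[r]])
  }
  zfNull <- mean(vapply(nullPool, `[[`, numeric(1), "zeroFraction"))
  mdNull <- mean(vapply(nullPool, `[[`, numeric(1), "medianNonzero"),
                 na.rm = TRUE)
  summary <- list(
    zeroFractionData = dataPool$zeroFraction,
    zeroFractionNull = zfNull,
    zeroFractionRatio = dataPool$zeroFraction / zfNull,
    medianNonzeroData = dataPool$medianNonzero,
    medianNonzeroNull = mdNull,
    medianNonzeroRatio = dataPool$medianNonzero / mdNull)
  list(data = dataPool, nulls = nullPool, dataStats = dataStats,
       nullStats = nullStats, summary = summary)
}

#' Log-spaced histogram of nonzero module-pair densities
#'
#' @param densities Numeric vector of nonzero densities.
#' @param nBins Number of log-spaced bins.
#' @return data.frame with `binLow`, `binHigh`, `count`.
#' @export
densityHistogram <- function(densities, nBins = 20L) {
  densities <- densities[densities > 0]
  stopIfNot(length(densities) > 0, "no nonzero densities")
  rng <- range(densities)
  if (rng[1] == rng[2]) rng <- rng * c(0.5, 2)
  breaks <- exp(seq(log(rng[1]), log(rng[2]), length.out = nBins + 1L))
  breaks[1] <- breaks[1] * (1 - 1e-12)
  h <- hist(densities, breaks = breaks, plot = FALSE)
  data.frame(binLow = h$breaks[-length(h$breaks)],
             binHigh = h$breaks[-1], count = h$counts)
}

#' Module centroids
#'
#' Mean coordinates of the member triangles of each module.
#'
#' @param network A [ConnectomeNetwork-class] with centroid coordinates.
#' @param moduleOf Character module id per node (NA skipped).
#' @return Numeric matrix (modules x 3), rownames = module ids.
#' @export
moduleCentroids <- function(network, moduleOf) {
  keep <- !is.na(moduleOf)
  xyz <- as.matrix(network@nodes[keep, c("x", "y", "z")])
  mods <- moduleOf[keep]
  out <- rowsum(xyz, mods) / as.vector(table(mods)[sort(unique(mods))])
  out[sort(unique(mods)), , drop = FALSE]
}

#' Distance association of connected vs unconnected module pairs
#'
#' Splits between-area module pairs into connected (density > 0) and
#' unconnected, and measures whether connected pairs are spatially closer
#' using the rank-biserial correlation between group and inter-centroid
#' distance (positive = connected pairs closer), with a permutation test
#' on the group labels.
#'
#' @param pairTable data.frame from [modulePairTable()].
#' @param centroids Module centroid matrix ([moduleCentroids()]).
#' @param nPermutations Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return List with `effectSize` (rank-biserial, in [-1, 1]), `pValue`,
#'   `connectedDistances`, `unconnectedDistances`, `nPermutations`.
#' @export
distanceAssociation <- function(pairTable, centroids,
                                nPermutations = 10000L, seed = 1L) {
  d <- sqrt(rowSums((centroids[pairTable$moduleA, , drop = FALSE] -
                       centroids[pairTable$moduleB, , drop = FALSE])^2))
  connected <- pairTable$density > 0
  if (!any(connected)) stop("no connected module pairs", call. = FALSE)
  if (all(connected)) stop("no unconnected module pairs", call. = FALSE)
  rb <- function(conn) {
    # AUC = P(distance of unconnected > distance of connected)
    r <- rank(d)
    n1 <- sum(conn); n0 <- sum(!conn)
    auc <- (sum(r[!conn]) - n0 * (n0 + 1) / 2) / (n0 * n1)
    2 * auc - 1
  }
  obs <- rb(connected)
  set.seed(seed)
  perm <- replicate(nPermutations, rb(sample(connected)))
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (nPermutations + 1)
  list(effectSize = obs, pValue = p,
       connectedDistances = d[connected],
       unconnectedDistances = d[!connected],
       nPermutations = as.integer(nPermutations))
}

#' Curvature-class preference of targeted modules
#'
#' Labels each module by the majority curvature class (gyrus / sulcus /
#' saddle) of its member triangles (ties fall to saddle) and each module
#' as targeted when it participates in at least one nonzero-density
#' between-area module pair. The association between targeting and class
#' is summarized by Cramer's V (no bias correction) on the 2 x 3
#' contingency table.
#'
#' @param pairTable data.frame from [modulePairTable()].
#' @param classOfTriangle Character class per node/triangle.
#' @param moduleOf Character module id per node.
#' @return List with `table` (targeted x class contingency), `effectSize`
#'   (Cramer's V) and `moduleClass`.
#' @export
gyralPreference <- function(pairTable, classOfTriangle, moduleOf) {
  keep <- !is.na(moduleOf)
  classLevels <- c("gyrus", "sulcus", "saddle")
  byMod <- split(classOfTriangle[keep], moduleOf[keep])
  moduleClass <- vapply(byMod, function(cl) {
    tab <- table(factor(cl, levels = classLevels))
    mx <- which(tab == max(tab))
    if (length(mx) > 1) "saddle" else classLevels[mx]
  }, character(1))
  targeted <- unique(c(pairTable$moduleA[pairTable$density > 0],
                       pairTable$moduleB[pairTable$density > 0]))
  inPairs <- unique(c(pairTable$moduleA, pairTable$moduleB))
  isTargeted <- factor(ifelse(inPairs %in% targeted, "targeted",
                              "non-targeted"),
                       levels = c("targeted", "non-targeted"))
  cls <- factor(moduleClass[inPairs], levels = classLevels)
  tab <- table(isTargeted, cls)
  v <- cramersV(tab)
  list(table = tab, effectSize = v, moduleClass = moduleClass)
}

# Cramer's V without bias correction; 0 (with warning) when degenerate
cramersV <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("contingency table degenerate (single class); V undefined, returning 0")
    return(0)
  }
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  n <- sum(tab)
  as.numeric(sqrt(chi / (n * (min(dim(tab)) - 1))))
}
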