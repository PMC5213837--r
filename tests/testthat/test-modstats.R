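# Module-pair densities, null comparison, spatial statistics.

# small two-area network with hand-placed modules and cross edges
handNetwork <- function() {
  # area A: modules a1 (nodes 1-4), a2 (nodes 5-8)
  # area B: modules b1 (nodes 9-13), b2 (nodes 14-18)
  g <- igraph::make_ring(18)
  # complete bipartite a1 x b1 (4 x 5 = 20 edges)
  for (i in 1:4) for (j in 9:13) g <- igraph::add_edges(g, c(i, j))
  # exactly 3 edges between a2 (4 nodes) and b2 (5 nodes)
  g <- igraph::add_edges(g, c(5, 14, 6, 15, 7, 16))
  g <- igraph::simplify(g)
  nodes <- data.frame(area = rep(c("A", "B"), c(8, 10)),
                      x = c(rep(0, 8), rep(10, 10)),
                      y = seq_len(18), z = 0)
  moduleOf <- c(rep("a1", 4), rep("a2", 4), rep("b1", 5), rep("b2", 5))
  list(net = new("ConnectomeNetwork", graph = g, nodes = nodes),
       moduleOf = moduleOf)
}

test_that("module-pair densities match direct counts and identities", {
  h <- handNetwork()
  st <- modulePairDensities(h$net, h$moduleOf, "A", "B")
  expect_equal(st@density["a1", "b1"], 1.0)         # complete bipartite
  expect_equal(st@density["a2", "b2"], 3 / 20)      # 3 of 4*5
  expect_equal(st@nPairsTotal, 4L)

  # ring edges crossing the area boundary (8-9 and 18-1) are inter-area
  # and must be counted in their module pair
  oracle <- bruteForcePairCounts(h$net, h$moduleOf, "A", "B")
  for (key in names(oracle)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    expected <- oracle[[key]] /
      (st@sizesA[parts[1]] * st@sizesB[parts[2]])
    expect_equal(unname(st@density[parts[1], parts[2]]), unname(expected))
  }

  # conservation: sum density * |i||j| = inter-area edge count (exact)
  el <- igraph::as_edgelist(networkGraph(h$net), names = FALSE)
  area <- nodeTable(h$net)$area
  nCross <- sum(area[el[, 1]] != area[el[, 2]])
  expect_identical(sum(st@density * outer(st@sizesA, st@sizesB)),
                   as.double(nCross))

  # zero_fraction + nNonzero / nPairsTotal = 1 exactly
  expect_identical(st@zeroFraction + st@nNonzero / st@nPairsTotal, 1)

  # no inter-area edges: all densities zero
  gIso <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  nodesIso <- data.frame(area = rep(c("A", "B"), each = 4),
                         x = 0, y = 0, z = 0)
  netIso <- new("ConnectomeNetwork", graph = gIso, nodes = nodesIso)
  stIso <- modulePairDensities(netIso, rep(c("a", "b"), each = 4),
                               "A", "B")
  expect_true(all(stIso@density == 0))
  expect_equal(stIso@zeroFraction, 1)

  expect_error(modulePairDensities(h$net, h$moduleOf, "A", "A"), "differ")
})

test_that("self-comparison against the data network gives unit ratios", {
  scene <- smallSceneNetwork()
  net <- scene$network

  # identical module-pair statistics give ratios of exactly 1
  wam <- withinAreaModules(net, gammaGrid = testGammaGrid, nRuns = 4L,
                           seed = 31L)
  pairs <- t(combn(sort(unique(nodeTable(net)$area)), 2))
  stats <- lapply(seq_len(nrow(pairs)), function(i)
    modulePairDensities(net, wam$modules$module, pairs[i, 1],
                        pairs[i, 2]))
  poolA <- triconnectome:::poolPairStats(stats)
  poolB <- triconnectome:::poolPairStats(stats)
  expect_identical(poolA$zeroFraction / poolB$zeroFraction, 1)
  expect_identical(poolA$medianNonzero / poolB$medianNonzero, 1)

  # full re-derivation on the same graph (fresh scan seeds): ratios stay
  # near 1 because the consensus procedure is stable on a fixed graph
  cmp <- compareToRandom(net, gammaGrid = testGammaGrid, nRuns = 4L,
                         seed = 31L,
                         nullGraphs = list(networkGraph(net)))
  expect_equal(cmp$summary$zeroFractionRatio, 1, tolerance = 0.3)
  expect_equal(cmp$summary$medianNonzeroRatio, 1, tolerance = 0.3)
})

test_that("distance association detects separation and null cases", {
  # complete separation: connected pairs at 1 mm, unconnected at 100 mm
  pt <- data.frame(areaA = "A", areaB = "B",
                   moduleA = paste0("m", 1:10),
                   moduleB = paste0("n", 1:10),
                   density = rep(c(1, 0), each = 5))
  cent <- rbind(matrix(0, 10, 3), matrix(0, 10, 3))
  rownames(cent) <- c(paste0("m", 1:10), paste0("n", 1:10))
  cent[paste0("n", 1:5), 1] <- 1     # connected pairs: distance 1
  cent[paste0("n", 6:10), 1] <- 100  # unconnected: distance 100
  da <- distanceAssociation(pt, cent, nPermutations = 500L, seed = 1L)
  expect_equal(da$effectSize, 1)
  expect_lt(da$pValue, 0.05)

  # identical distances in both groups: zero effect, p ~ 1
  cent2 <- cent
  cent2[paste0("n", 1:10), 1] <- 7
  da2 <- distanceAssociation(pt, cent2, nPermutations = 500L, seed = 1L)
  expect_equal(da2$effectSize, 0)
  expect_equal(da2$pValue, 1)

  ptAll <- pt; ptAll$density <- 1
  expect_error(distanceAssociation(ptAll, cent), "unconnected")

  # planted nearest-centroid pair map: connected pairs are closer
  scene <- makeSyntheticScene(nSubdivisions = 2L, nStreamlines = 1500L,
                              targetingFidelity = 1,
                              invalidFraction = 0,
                              pairRule = "nearest",
                              withinModulePairs = FALSE, seed = 23L)
  filt <- filterStreamlines(scene@streamlines)
  snap <- mapEndpoints(filt$kept, triangleCenters(scene@mesh))
  asm <- assembleNetwork(triangleAdjacency(scene@mesh), snap$edges,
                         nTriangles(scene@mesh),
                         area = areaLabels(scene@mesh),
                         centers = triangleCenters(scene@mesh))
  moduleOf <- paste0(areaLabels(scene@mesh), ".", scene@plantedModules)
  pairs <- t(combn(sort(unique(areaLabels(scene@mesh))), 2))
  stats <- lapply(seq_len(nrow(pairs)), function(i)
    modulePairDensities(asm$network, moduleOf, pairs[i, 1], pairs[i, 2]))
  tab <- modulePairTable(stats)
  centMod <- moduleCentroids(asm$network, moduleOf)
  daScene <- distanceAssociation(tab, centMod, nPermutations = 2000L,
                                 seed = 7L)
  expect_gt(daScene$effectSize, 0.5)
  expect_lt(daScene$pValue, 0.01)
})

test_that("curvature-class preference yields bounded effect sizes", {
  # perfect association: all targeted modules gyral, non-targeted sulcal
  pt <- data.frame(areaA = "A", areaB = "B",
                   moduleA = paste0("m", 1:6),
                   moduleB = paste0("n", 1:6),
                   density = rep(c(1, 0), each = 3))
  moduleOf <- c(paste0("m", rep(1:6, each = 2)),
                paste0("n", rep(1:6, each = 2)))
  classOf <- c(rep(c("gyrus", "sulcus"), c(6, 6)),
               rep(c("gyrus", "sulcus"), c(6, 6)))
  gp <- gyralPreference(pt, classOf, moduleOf)
  expect_equal(gp$effectSize, 1)

  # a uniform contingency table has V = 0
  expect_equal(triconnectome:::cramersV(matrix(5, 2, 3)), 0)

  # a single surface class present: V undefined, returns 0 with warning
  expect_warning(
    gp0 <- gyralPreference(pt, rep("gyrus", length(moduleOf)), moduleOf),
    "degenerate")
  expect_equal(gp0$effectSize, 0)

  # targeting independent of class: V small in expectation over seeds
  # (subdivision-3 mesh so module majority classes actually vary)
  mesh <- makeAreaLabeledSphereMesh(3, radius = 50, bumpAmplitude = 5,
                                    bumpFrequency = 6, nAreas = 4)
  cls <- classifySurface(mesh)
  planted <- plantModules(mesh, 5L, seed = 2L)
  moduleOfScene <- paste0(areaLabels(mesh), ".", planted)
  vs <- vapply(1:10, function(s) {
    set.seed(s)
    mods <- sort(unique(moduleOfScene))
    dens <- runif(length(mods)) < 0.5   # random targeting
    ptS <- data.frame(areaA = "A", areaB = "B",
                      moduleA = mods, moduleB = mods,
                      density = as.numeric(dens))
    gyralPreference(ptS, cls$classOfTriangle, moduleOfScene)$effectSize
  }, numeric(1))
  expect_lt(mean(vs), 0.35)
})

test_that("histogram bins cover all nonzero densities", {
  d <- c(0.001, 0.01, 0.02, 0.3, 0, 0)
  h <- densityHistogram(d, nBins = 8L)
  expect_equal(sum(h$count), 4L)
  expect_error(densityHistogram(c(0, 0)), "nonzero")
})
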