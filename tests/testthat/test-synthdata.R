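# Synthetic generators: flowers, SBMs, planted modules, streamlines.

test_that("(u,v)-flower matches closed-form recurrences for g <= 6", {
  # E_g = (u+v)^g; N_g = ((w-2) w^g + w) / (w-1), w = u + v
  for (uv in list(c(2, 2), c(2, 3))) {
    u <- uv[1]; v <- uv[2]; w <- u + v
    for (g in 1:6) {
      if (w^g > 5000) next
      fl <- makeUVFlower(u, v, g)
      expect_equal(igraph::ecount(networkGraph(fl)), w^g)
      expect_equal(igraph::vcount(networkGraph(fl)),
                   ((w - 2) * w^g + w) / (w - 1))
      expect_true(igraph::is_connected(networkGraph(fl)))
    }
  }
  expect_equal(makeUVFlower(2, 2, 1)@knownDimension, 2)
  expect_equal(igraph::vcount(networkGraph(makeUVFlower(2, 2, 1))), 4L)
  expect_equal(makeUVFlower(2, 3, 2)@knownDimension, log(5) / log(2))
  expect_error(makeUVFlower(1, 3, 2), "u")
})

test_that("planted-partition graphs have the declared size and moments", {
  bg <- makePlantedPartitionGraph(4, 40, 0.25, 0.02, seed = 1)
  g <- networkGraph(bg)
  expect_equal(igraph::vcount(g), 160L)
  expect_true(igraph::is_connected(g))
  expect_equal(bg@plantedPartition, rep(1:4, each = 40L))

  # expected edges 4*C(40,2)*0.25 + C(4,2)*1600*0.02 = 780 + 192 = 972
  mu <- 972
  sigma <- sqrt(4 * choose(40, 2) * 0.25 * 0.75 +
                  6 * 1600 * 0.02 * 0.98)
  expect_lt(abs(igraph::ecount(g) - mu), 3 * sigma)

  # degenerate SBM: two cliques forced together by one bridge
  two <- makePlantedPartitionGraph(2, 30, 1.0, 0.0, seed = 3)
  g2 <- networkGraph(two)
  expect_equal(igraph::ecount(g2), 2L * choose(30L, 2L) + 1L)
  expect_equal(two@params$connectivity, "bridged")

  expect_error(makePlantedPartitionGraph(2, 30, 0.01, 0.02, seed = 1),
               "pIn")
  expect_warning(makePlantedPartitionGraph(2, 10, 0.05, 0.01, seed = 1),
                 "degree")
})

test_that("planted modules are contiguous, exhaustive and seed-stable", {
  mesh <- smallScene()@mesh
  planted <- plantModules(mesh, 5L, seed = 1L)
  expect_false(any(is.na(planted)))
  expect_equal(length(unique(planted)), 20L)  # 4 areas x 5

  # modulesPerArea = 1 reproduces the area partition
  one <- plantModules(mesh, 1L, seed = 2L)
  expect_equal(length(unique(one)), 4L)
  expect_true(all(tapply(areaLabels(mesh), one,
                         function(z) length(unique(z))) == 1L))

  # each module induces a connected subgraph of the triangle adjacency
  adj <- triangleAdjacency(mesh)
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  for (m in unique(planted)) {
    sub <- igraph::induced_subgraph(g, which(planted == m))
    expect_equal(igraph::components(sub)$no, 1L)
  }

  # modules never straddle areas
  expect_true(all(tapply(areaLabels(mesh), planted,
                         function(z) length(unique(z))) == 1L))

  expect_identical(planted, plantModules(mesh, 5L, seed = 1L))
  expect_error(plantModules(mesh, 10000L, seed = 1L), "fewer")
})

test_that("planted streamlines honor fidelity, contamination and labels", {
  scene <- smallScene()
  sl <- scene@streamlines
  # floor(600 * 0.1) = 60 invalid, rules cycling at the tail
  expect_equal(sum(streamlineLabels(sl) != "valid"), 60L)
  expect_equal(as.integer(table(streamlineLabels(sl))[c("too-short",
                                                        "too-long",
                                                        "sharp-angle")]),
               c(20L, 20L, 20L))

  # labels consistent with recomputed geometry
  len <- streamlineLengths(sl)
  ang <- maxTurningAngles(sl)
  lab <- streamlineLabels(sl)
  expect_true(all(len[lab == "too-short"] < 10))
  expect_true(all(len[lab == "too-long"] > 300))
  expect_true(all(ang[lab == "sharp-angle"] > 60))
  expect_true(all(len[lab == "valid"] >= 10 & len[lab == "valid"] <= 300))
  expect_true(all(ang[lab == "valid"] <= 60))

  # fidelity 1, zero noise: endpoint triangles recover planted pairs
  pure <- makePlantedStreamlines(scene@mesh, scene@plantedModules,
                                 scene@pairMap, 150L, 1,
                                 endpointNoiseSd = 0, invalidFraction = 0,
                                 seed = 5L)
  snap <- mapEndpoints(pure, triangleCenters(scene@mesh))
  mods <- scene@plantedModules
  ep <- snap$endpointTriangles
  pairKeys <- paste(scene@pairMap$source, scene@pairMap$target)
  got <- paste(mods[ep[, 1]], mods[ep[, 2]])
  rev <- paste(mods[ep[, 2]], mods[ep[, 1]])
  expect_true(all(got %in% pairKeys | rev %in% pairKeys))

  expect_error(makePlantedStreamlines(scene@mesh, scene@plantedModules,
                                      scene@pairMap[0, ], 10L, 0.5,
                                      seed = 1L),
               "pairMap")

  # bit-reproducibility
  again <- makePlantedStreamlines(scene@mesh, scene@plantedModules,
                                  scene@pairMap, 150L, 1,
                                  endpointNoiseSd = 0,
                                  invalidFraction = 0, seed = 5L)
  expect_identical(pure@points, again@points)
})

test_that("at fidelity 0 endpoint modules follow the size-proportional null", {
  scene <- smallScene()
  # cross-area rows only: at fidelity 0 endpoints are uniform over the
  # two areas, so module pairs occur proportional to size products
  crossMap <- scene@pairMap[scene@pairMap$source != scene@pairMap$target, ]
  sl <- makePlantedStreamlines(scene@mesh, scene@plantedModules, crossMap,
                               5000L, 0, endpointNoiseSd = 0,
                               invalidFraction = 0, seed = 9L)
  snap <- mapEndpoints(sl, triangleCenters(scene@mesh))
  mods <- scene@plantedModules
  area <- areaLabels(scene@mesh)
  areaOfMod <- vapply(split(area, mods), `[[`, character(1), 1)
  ep <- snap$endpointTriangles
  key <- paste(mods[ep[, 1]], mods[ep[, 2]])

  # expected: row of crossMap uniform, then triangles uniform in areas
  sizes <- table(mods)
  areaSizes <- table(area)
  expected <- numeric(0)
  for (r in seq_len(nrow(crossMap))) {
    sa <- areaOfMod[[as.character(crossMap$source[r])]]
    ta <- areaOfMod[[as.character(crossMap$target[r])]]
    for (mi in names(sizes)[areaOfMod == sa])
      for (mj in names(sizes)[areaOfMod == ta]) {
        k <- paste(mi, mj)
        p <- (1 / nrow(crossMap)) *
          (sizes[[mi]] / areaSizes[[sa]]) * (sizes[[mj]] / areaSizes[[ta]])
        expected[k] <- (if (k %in% names(expected)) expected[[k]] else 0) + p
      }
  }
  obs <- table(factor(key, levels = names(expected)))
  keep <- expected * length(key) >= 5  # chi-square validity
  chi <- sum((obs[keep] - expected[keep] * length(key))^2 /
               (expected[keep] * length(key)))
  p <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})
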