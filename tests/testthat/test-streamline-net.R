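# Streamline filtering, endpoint mapping, network assembly.

test_that("filter applies the length/angle/mask exclusion rules", {
  s <- streamlineSet(
    straightStreamline(50),                              # kept
    straightStreamline(9.9),                             # length-short
    straightStreamline(300.1),                           # length-long
    rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0)),        # 90 deg angle
    straightStreamline(10),                              # boundary: kept
    straightStreamline(300))                             # boundary: kept
  f <- filterStreamlines(s)
  expect_equal(f$status,
               c("kept", "length-short", "length-long", "angle",
                 "kept", "kept"))
  expect_equal(unname(f$counts["kept"]), 3L)

  # a streamline failing several rules is counted once, first rule wins
  shortAndBent <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0))
  f2 <- filterStreamlines(streamlineSet(shortAndBent))
  expect_equal(f2$status, "length-short")
  expect_equal(sum(f2$counts), 1L)

  # grey-matter mask rejects streamlines with an out-of-mask endpoint
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2, byrow = TRUE)
  f3 <- filterStreamlines(streamlineSet(straightStreamline(50),
                                        straightStreamline(60)),
                          gmMask = mask)
  expect_equal(f3$status, c("kept", "mask"))

  # malformed input is rejected at construction, naming the index
  expect_error(new("StreamlineSet",
                   points = list(straightStreamline(50),
                                 matrix(0, 1, 3)),
                   labels = character(0)),
               "2")
})

test_that("turning angles are per-interior-vertex maxima", {
  expect_equal(maxTurningAngles(streamlineSet(straightStreamline(50))), 0)
  bent <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0))
  expect_equal(maxTurningAngles(streamlineSet(bent)), 90)
  gentle <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 1, 0), c(30, 0, 0))
  expect_lt(maxTurningAngles(streamlineSet(gentle)), 12)
  expect_equal(streamlineLengths(streamlineSet(bent)), 20)
})

test_that("every input streamline is accounted for exactly once", {
  scene <- smallScene()
  f <- filterStreamlines(scene@streamlines)
  snap <- mapEndpoints(f$kept, triangleCenters(scene@mesh))
  nWithEdge <- sum(snap$edges$count)
  expect_equal(nWithEdge + snap$nSelfLoops + snap$nUnsnapped +
                 sum(f$counts[c("length-short", "length-long", "angle",
                                "mask")]),
               nStreamlines(scene@streamlines))
})

test_that("endpoint snapping is exact nearest-neighbor with id ties", {
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  # endpoint exactly at a centroid snaps there
  s <- streamlineSet(rbind(c(10, 0, 0), c(0.4, 0, 0)))
  snap <- mapEndpoints(s, centers)
  expect_equal(snap$endpointTriangles[1, ], c(2L, 1L))

  # equidistant endpoint: tie broken to the lowest triangle id
  tie <- streamlineSet(rbind(c(5, 3, 0), c(20, 0.1, 0)))
  expect_equal(mapEndpoints(tie, centers)$endpointTriangles[1, 1], 1L)

  # both endpoints nearest the same triangle: self-loop counted, no edge
  loop <- streamlineSet(rbind(c(0.1, 0, 0), c(-0.1, 0, 0)))
  snapLoop <- mapEndpoints(loop, centers)
  expect_equal(nrow(snapLoop$edges), 0L)
  expect_equal(snapLoop$nSelfLoops, 1L)

  # snapping result equals exhaustive nearest-neighbor on a real scene
  scene <- smallScene()
  f <- filterStreamlines(scene@streamlines)
  cent <- triangleCenters(scene@mesh)
  snapAll <- mapEndpoints(f$kept, cent)
  idx <- c(3L, 17L, 101L)
  for (i in idx) {
    p <- f$kept@points[[i]]
    for (side in 1:2) {
      ep <- if (side == 1) p[1, ] else p[nrow(p), ]
      d <- sqrt(colSums((t(cent) - ep)^2))
      expect_equal(snapAll$endpointTriangles[i, side],
                   unname(which.min(d)))
    }
  }

  expect_error(mapEndpoints(streamlineSet(rbind(c(NA, 0, 0), c(1, 1, 1))),
                            centers), "finite")

  # finite snap cutoff drops distant endpoints
  far <- streamlineSet(rbind(c(500, 0, 0), c(0.3, 0, 0)))
  snapFar <- mapEndpoints(far, centers, maxSnapDistance = 50)
  expect_equal(snapFar$nUnsnapped, 1L)
})

test_that("network assembly binarises the local + long-range union", {
  mesh <- makeAreaLabeledSphereMesh(3, radius = 50, nAreas = 4)
  adj <- triangleAdjacency(mesh)
  nT <- nTriangles(mesh)

  # empty long-range list: pure local lattice with k = 3F/2
  empty <- data.frame(from = integer(0), to = integer(0),
                      count = integer(0))
  net0 <- assembleNetwork(adj, empty, nT)$network
  expect_equal(nEdges(net0), 3L * nT / 2L)

  # duplicated long-range edge contributes exactly once
  dup <- data.frame(from = rep(1L, 100), to = rep(640L, 100),
                    count = 1L)
  net1 <- assembleNetwork(adj, dup, nT)$network
  expect_equal(nEdges(net1), 3L * nT / 2L + 1L)

  # disjoint long-range edges add exactly; overlaps counted
  adjKey <- adj[, 1] * (nT + 1) + adj[, 2]
  set.seed(4)
  cand <- cbind(sample(nT, 2000, replace = TRUE),
                sample(nT, 2000, replace = TRUE))
  cand <- cand[cand[, 1] != cand[, 2], ]
  cand <- cbind(pmin(cand[, 1], cand[, 2]), pmax(cand[, 1], cand[, 2]))
  cand <- cand[!(cand[, 1] * (nT + 1) + cand[, 2]) %in% adjKey, ]
  cand <- unique(cand)[1:500, ]
  lr <- data.frame(from = cand[, 1], to = cand[, 2], count = 1L)
  asm <- assembleNetwork(adj, lr, nT)
  expect_equal(nEdges(asm$network), 1920L + 500L)
  expect_equal(asm$nOverlap, 0L)

  # a long-range edge duplicating a local one is reported as overlap
  asm2 <- assembleNetwork(adj, data.frame(from = adj[1, 1],
                                          to = adj[1, 2], count = 1L), nT)
  expect_equal(asm2$nOverlap, 1L)
  expect_equal(nEdges(asm2$network), 1920L)

  expect_error(assembleNetwork(adj, data.frame(from = 0L, to = 5L,
                                               count = 1L), nT),
               "range")

  # assembled networks over closed manifolds are connected
  scene <- smallSceneNetwork()
  expect_true(igraph::is_connected(networkGraph(scene$network)))
})

test_that("identical inputs give identical networks (no randomness)", {
  scene <- smallScene()
  run <- function() {
    f <- filterStreamlines(scene@streamlines)
    snap <- mapEndpoints(f$kept, triangleCenters(scene@mesh))
    asm <- assembleNetwork(triangleAdjacency(scene@mesh), snap$edges,
                           nTriangles(scene@mesh))
    igraph::as_edgelist(networkGraph(asm$network))
  }
  expect_identical(run(), run())
})
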