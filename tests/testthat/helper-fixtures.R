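# Shared fixtures, built in code. Heavier objects are created lazily and
# cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# closed tetrahedron surface (outward-wound)
tetrahedronMesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1L, 2L, 3L), c(1L, 4L, 2L), c(1L, 3L, 4L), c(2L, 4L, 3L))
  new("TriangleMesh", vertices = v, triangles = f,
      areaLabels = character(0))
}

# one flat triangle
singleTriangleMesh <- function() {
  new("TriangleMesh",
      vertices = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
      triangles = matrix(c(1L, 2L, 3L), 1L, 3L),
      areaLabels = character(0))
}

# straight 2-point streamline of a given length along +x from origin
straightStreamline <- function(len, from = c(0, 0, 0)) {
  rbind(from, from + c(len, 0, 0))
}

streamlineSet <- function(...) {
  new("StreamlineSet", points = list(...), labels = character(0))
}

# small standard synthetic scene for unit tests (subdivision 2, fast)
smallScene <- function() {
  fixture("smallScene", function()
    makeSyntheticScene(nSubdivisions = 2L, nStreamlines = 600L,
                       invalidFraction = 0.1, seed = 11L))
}

# network assembled from the small scene
smallSceneNetwork <- function() {
  fixture("smallSceneNetwork", function() {
    scene <- smallScene()
    filt <- filterStreamlines(scene@streamlines)
    centers <- triangleCenters(scene@mesh)
    snap <- mapEndpoints(filt$kept, centers)
    asm <- assembleNetwork(triangleAdjacency(scene@mesh), snap$edges,
                           nTriangles(scene@mesh),
                           area = areaLabels(scene@mesh),
                           centers = centers)
    list(scene = scene, filt = filt, snap = snap, network = asm$network,
         nOverlap = asm$nOverlap)
  })
}

# reduced gamma grid for fast scans in unit tests
testGammaGrid <- seq(0.6, 1.4, by = 0.2)

# independent brute-force recount of inter-area module-pair edges from
# the raw edge list (oracle for ModulePairStats)
bruteForcePairCounts <- function(network, moduleOf, areaA, areaB) {
  el <- igraph::as_edgelist(networkGraph(network), names = FALSE)
  area <- nodeTable(network)$area
  counts <- list()
  for (r in seq_len(nrow(el))) {
    i <- el[r, 1]; j <- el[r, 2]
    pair <- NULL
    if (!is.na(moduleOf[i]) && !is.na(moduleOf[j])) {
      if (area[i] == areaA && area[j] == areaB)
        pair <- c(moduleOf[i], moduleOf[j])
      if (area[i] == areaB && area[j] == areaA)
        pair <- c(moduleOf[j], moduleOf[i])
    }
    if (!is.null(pair)) {
      key <- paste(pair, collapse = "|")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
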