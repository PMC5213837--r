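#' @include mesh.R streamlines.R synth-graphs.R
NULL

#' Plant spatially contiguous modules within each mesh area
#'
#' Partitions the triangles of every area into `modulesPerArea` spatially
#' contiguous patches, grown from random seed triangles by breadth-first
#' region growing with random tie-breaking over the triangle-adjacency
#' graph (restricted to the area). Module ids are global (area 1 holds
#' modules 1..modulesPerArea, area 2 the next block, ...).
#'
#' @param mesh An area-labelled [TriangleMesh-class].
#' @param modulesPerArea Modules to plant per area (>= 1).
#' @param seed Integer seed.
#' @return Integer vector: planted module id per triangle.
#' @export
plantModules <- function(mesh, modulesPerArea, seed) {
  stopIfNot(modulesPerArea >= 1, "modulesPerArea must be >= 1")
  stopIfNot(length(mesh@areaLabels) == nTriangles(mesh),
            "mesh must carry area labels")
  adj <- triangleAdjacency(mesh)
  nT <- nTriangles(mesh)
  nbr <- vector("list", nT)
  for (r in seq_len(nrow(adj))) {
    nbr[[adj[r, 1]]] <- c(nbr[[adj[r, 1]]], adj[r, 2])
    nbr[[adj[r, 2]]] <- c(nbr[[adj[r, 2]]], adj[r, 1])
  }
  set.seed(seed)
  assignment <- rep(NA_integer_, nT)
  moduleBase <- 0L
  for (a in sort(unique(mesh@areaLabels))) {
    tris <- which(mesh@areaLabels == a)
    if (modulesPerArea > length(tris))
      stop(sprintf("area %s has %d triangles, fewer than modulesPerArea = %d",
                   a, length(tris), modulesPerArea), call. = FALSE)
    seeds <- sample(tris, modulesPerArea)
    assignment[seeds] <- moduleBase + seq_len(modulesPerArea)
    inArea <- logical(nT); inArea[tris] <- TRUE
    repeat {
      unass <- tris[is.na(assignment[tris])]
      if (!length(unass)) break
      frontier <- unass[vapply(unass, function(t)
        any(!is.na(assignment[nbr[[t]]]) & inArea[nbr[[t]]]), logical(1))]
      if (!length(frontier))
        stop(sprintf("area %s induces a disconnected triangle subgraph", a),
             call. = FALSE)
      # note: index-based sampling avoids R's single-element sample() trap
      for (t in frontier[sample.int(length(frontier))]) {
        cand <- nbr[[t]]
        cand <- cand[inArea[cand] & !is.na(assignment[cand])]
        if (length(cand))
          assignment[t] <- assignment[cand[sample.int(length(cand), 1L)]]
      }
    }
    moduleBase <- moduleBase + modulesPerArea
  }
  assignment
}

# circular-arc polyline from p to q bulging along outDir, sampled at step.
# Arc length is max(minLen, 1.015 * chord); the arc radius is always
# >= minLen / (2*pi), bounding per-step turning by step / radius.
makeArcPolyline <- function(p, q, outDir, step = 0.625, minLen = 10.5) {
  chord <- sqrt(sum((q - p)^2))
  stopIfNot(chord > 1e-9, "arc endpoints must be distinct")
  L <- max(minLen, 1.015 * chord)
  ratio <- L / chord
  # solve (x / sin x) = ratio for x = half arc angle
  f <- function(x) x / sin(x) - ratio
  x <- stats::uniroot(f, c(1e-9, pi - 1e-9), tol = 1e-12)$root
  R <- chord / (2 * sin(x))
  u <- (q - p) / chord
  w <- outDir - sum(outDir * u) * u
  if (sqrt(sum(w^2)) < 1e-9) {            # outDir parallel to chord
    w <- c(-u[2], u[1], 0)
    if (sqrt(sum(w^2)) < 1e-9) w <- c(0, -u[3], u[2])
  }
  w <- w / sqrt(sum(w^2))
  m <- (p + q) / 2
  d <- R * cos(x)
  center <- m - d * w
  beta <- atan2(d, chord / 2)
  aP <- pi - beta
  theta <- 2 * x
  nSeg <- max(2L, as.integer(ceiling(L / step)))
  tt <- seq(0, 1, length.out = nSeg + 1L)
  ang <- aP - tt * theta
  pts <- cbind(center[1] + R * (cos(ang) * u[1] + sin(ang) * w[1]),
               center[2] + R * (cos(ang) * u[2] + sin(ang) * w[2]),
               center[3] + R * (cos(ang) * u[3] + sin(ang) * w[3]))
  pts[1, ] <- p
  pts[nSeg + 1L, ] <- q
  pts
}

#' Generate streamlines with planted module-to-module targeting
#'
#' Valid streamlines join two triangles: with probability
#' `targetingFidelity` the triangles are drawn from a planted (source
#' module, target module) pair, otherwise uniformly from the two areas of
#' a sampled pair. Endpoints sit at the triangle centers plus isotropic
#' Gaussian noise; the interior is a smooth circular arc sampled at
#' `step` mm, constructed so that every valid streamline passes the
#' standard exclusion rules (length in [10, 300] mm, per-step turning
#' <= 60 degrees). A fraction `invalidFraction` (floor(n * fraction),
#' placed deterministically at the tail, rule types cycling) violates
#' exactly one rule and is labelled accordingly.
#'
#' @param mesh Area-labelled [TriangleMesh-class].
#' @param plantedModules Integer module id per triangle ([plantModules()]).
#' @param pairMap data.frame with `source`, `target` module id columns.
#' @param nStreamlines Number of streamlines.
#' @param targetingFidelity Probability in [0, 1].
#' @param endpointNoiseSd Gaussian endpoint perturbation sd (mm).
#' @param step Sampling step along the arc (mm; default 0.625).
#' @param invalidFraction Fraction of deliberately invalid streamlines.
#' @param seed Integer seed.
#' @return A labelled [StreamlineSet-class] (labels `valid`, `too-short`,
#'   `too-long`, `sharp-angle`).
#' @export
makePlantedStreamlines <- function(mesh, plantedModules, pairMap,
                                   nStreamlines, targetingFidelity,
                                   endpointNoiseSd = 0.5, step = 0.625,
                                   invalidFraction = 0, seed = 1L) {
  stopIfNot(targetingFidelity >= 0 && targetingFidelity <= 1,
            "targetingFidelity must lie in [0, 1]")
  stopIfNot(step > 0, "step must be positive")
  if (nrow(pairMap) == 0 && targetingFidelity > 0)
    stop("empty pairMap with positive targetingFidelity", call. = FALSE)
  centers <- triangleCenters(mesh)
  areaOfModule <- vapply(split(mesh@areaLabels, plantedModules),
                         function(z) z[[1]], character(1))
  trisOfModule <- split(seq_len(nTriangles(mesh)), plantedModules)
  trisOfArea <- split(seq_len(nTriangles(mesh)), mesh@areaLabels)

  n <- as.integer(nStreamlines)
  nInvalid <- as.integer(floor(n * invalidFraction))
  invalidRules <- if (nInvalid > 0)
    rep(c("too-short", "too-long", "sharp-angle"), length.out = nInvalid)
  else character(0)
  labels <- c(rep("valid", n - nInvalid), invalidRules)

  set.seed(seed)
  pts <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (lab == "valid") {
      row <- if (nrow(pairMap)) sample.int(nrow(pairMap), 1L) else NA_integer_
      planted <- stats::runif(1) < targetingFidelity
      if (planted) {
        srcPool <- trisOfModule[[as.character(pairMap$source[row])]]
        tgtPool <- trisOfModule[[as.character(pairMap$target[row])]]
      } else {
        srcPool <- trisOfArea[[areaOfModule[[as.character(pairMap$source[row])]]]]
        tgtPool <- trisOfArea[[areaOfModule[[as.character(pairMap$target[row])]]]]
      }
      t1 <- srcPool[sample.int(length(srcPool), 1L)]
      repeat {
        t2 <- tgtPool[sample.int(length(tgtPool), 1L)]
        if (t2 != t1) break
      }
      p <- centers[t1, ] + stats::rnorm(3, 0, endpointNoiseSd)
      q <- centers[t2, ] + stats::rnorm(3, 0, endpointNoiseSd)
      m <- (p + q) / 2
      outDir <- if (sqrt(sum(m^2)) > 1e-6) m / sqrt(sum(m^2)) else c(0, 0, 1)
      pts[[i]] <- makeArcPolyline(p, q, outDir, step = step)
    } else if (lab == "too-short") {
      t1 <- sample.int(nTriangles(mesh), 1L)
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      p <- centers[t1, ]
      pts[[i]] <- rbind(p, p + 5 * dir)
    } else if (lab == "too-long") {
      t1 <- sample.int(nTriangles(mesh), 1L)
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      p <- centers[t1, ]
      pts[[i]] <- rbind(p, p + 155 * dir, p + 310 * dir)
    } else { # sharp-angle: 90 degree bend, valid length
      t1 <- sample.int(nTriangles(mesh), 1L)
      d1 <- stats::rnorm(3); d1 <- d1 / sqrt(sum(d1^2))
      d2 <- stats::rnorm(3); d2 <- d2 - sum(d2 * d1) * d1
      d2 <- d2 / sqrt(sum(d2^2))
      p <- centers[t1, ]
      pts[[i]] <- rbind(p, p + 20 * d1, p + 20 * d1 + 20 * d2)
    }
    dimnames(pts[[i]]) <- NULL
  }
  new("StreamlineSet", points = pts, labels = labels)
}

#' Build a planted module-to-module pair map
#'
#' Assigns every planted module a target module in a different area,
#' either uniformly at random (`rule = "random"`) or the module with the
#' nearest centroid among other areas (`rule = "nearest"`, which plants a
#' distance-connectivity association). With `includeSelfPairs = TRUE`
#' every module additionally maps to itself, emulating the short
#' within-module association fibers that dominate connectivity inside
#' cortical areas; since streamline generation samples pair rows
#' uniformly, half of the planted streamlines are then within-module.
#'
#' @param mesh Area-labelled [TriangleMesh-class].
#' @param plantedModules Integer module id per triangle.
#' @param rule `"random"` or `"nearest"`.
#' @param includeSelfPairs Also add (module, module) rows.
#' @param seed Integer seed (used by `"random"`).
#' @return data.frame with columns `source`, `target`.
#' @export
makePairMap <- function(mesh, plantedModules, rule = c("random", "nearest"),
                        includeSelfPairs = FALSE, seed = 1L) {
  rule <- match.arg(rule)
  centers <- triangleCenters(mesh)
  mods <- sort(unique(plantedModules))
  areaOfModule <- vapply(split(mesh@areaLabels, plantedModules),
                         function(z) z[[1]], character(1))[as.character(mods)]
  cent <- t(vapply(mods, function(m)
    colMeans(centers[plantedModules == m, , drop = FALSE]), numeric(3)))
  set.seed(seed)
  target <- integer(length(mods))
  for (k in seq_along(mods)) {
    other <- which(areaOfModule != areaOfModule[k])
    if (!length(other)) stop("need at least two areas for a pair map")
    target[k] <- if (rule == "random") {
      mods[other[sample.int(length(other), 1L)]]
    } else {
      d2 <- rowSums((cent[other, , drop = FALSE] -
                       matrix(cent[k, ], length(other), 3, byrow = TRUE))^2)
      mods[other[which.min(d2)]]
    }
  }
  out <- data.frame(source = mods, target = target)
  if (includeSelfPairs)
    out <- rbind(data.frame(source = mods, target = mods), out)
  out
}

#' Generate a complete synthetic scene
#'
#' Bundles a bumpy area-labelled icosphere, planted contiguous modules, a
#' module pair map and planted-targeted streamlines with controllable
#' fidelity and contamination. Defaults define the standard synthetic
#' study conditions used throughout the test suite: a subdivision-3
#' icosphere (1280 triangles) of radius 50 mm with 4 areas and 5 planted
#' modules per area, 5000 streamlines at targeting fidelity 0.9 with
#' 0.5 mm endpoint noise and 5% invalid contamination. With
#' `withinModulePairs = TRUE` (default) the pair map includes
#' self-pairs, so half of the planted streamlines are short
#' within-module connections (the association fibers dominating
#' within-area connectivity) and half are long-range between-area
#' module-to-module connections; within-area module detection then has
#' planted structure to recover. With `FALSE`, all streamlines are
#' between-area, leaving the within-area subgraphs (hence the detected
#' module granularity) identical across targeting fidelities - the
#' configuration used to isolate long-range targeting effects.
#'
#' @param nSubdivisions,radius,bumpAmplitude,bumpFrequency,nAreas Mesh
#'   parameters (see [makeAreaLabeledSphereMesh()]).
#' @param modulesPerArea Planted modules per area.
#' @param nStreamlines,targetingFidelity,endpointNoiseSd,step,invalidFraction
#'   Streamline parameters (see [makePlantedStreamlines()]).
#' @param pairRule Pair-map rule ([makePairMap()]).
#' @param withinModulePairs Include within-module self-pairs (see above).
#' @param seed Master seed for the scene.
#' @return A [SyntheticScene-class].
#' @export
makeSyntheticScene <- function(nSubdivisions = 3L, radius = 50,
                               bumpAmplitude = 5, bumpFrequency = 6,
                               nAreas = 4L, modulesPerArea = 5L,
                               nStreamlines = 5000L,
                               targetingFidelity = 0.9,
                               endpointNoiseSd = 0.5, step = 0.625,
                               invalidFraction = 0.05,
                               pairRule = "random",
                               withinModulePairs = TRUE, seed = 1L) {
  mesh <- makeAreaLabeledSphereMesh(nSubdivisions, radius, bumpAmplitude,
                                    bumpFrequency, nAreas,
                                    seed = deriveSeed(seed, "mesh"))
  planted <- plantModules(mesh, modulesPerArea,
                          seed = deriveSeed(seed, "modules"))
  pairMap <- makePairMap(mesh, planted, rule = pairRule,
                         includeSelfPairs = withinModulePairs,
                         seed = deriveSeed(seed, "pairs"))
  streamlines <- makePlantedStreamlines(
    mesh, planted, pairMap, nStreamlines, targetingFidelity,
    endpointNoiseSd = endpointNoiseSd, step = step,
    invalidFraction = invalidFraction, seed = deriveSeed(seed, "streamlines"))
  new("SyntheticScene", mesh = mesh, streamlines = streamlines,
      plantedModules = as.integer(planted), pairMap = pairMap,
      targetingFidelity = targetingFidelity, seed = as.integer(seed))
}
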