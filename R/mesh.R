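#' @include AllClasses.R
NULL

# Base icosahedron (unit circumradius), outward-wound faces.
icosahedronBase <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(1 + t^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivideOnce <- function(vertices, faces) {
  nv <- nrow(vertices)
  edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  midIndex <- new.env(hash = TRUE)
  verts <- vertices
  getMid <- function(a, b) {
    k <- edgeKey(a, b)
    idx <- midIndex[[k]]
    if (is.null(idx)) {
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      midIndex[[k]] <- idx
    }
    idx
  }
  newFaces <- matrix(0L, nrow(faces) * 4L, 3L)
  r <- 1L
  for (i in seq_len(nrow(faces))) {
    a <- faces[i, 1]; b <- faces[i, 2]; c <- faces[i, 3]
    ab <- getMid(a, b); bc <- getMid(b, c); ca <- getMid(c, a)
    newFaces[r, ] <- c(a, ab, ca)
    newFaces[r + 1L, ] <- c(b, bc, ab)
    newFaces[r + 2L, ] <- c(c, ca, bc)
    newFaces[r + 3L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(vertices = verts, faces = newFaces)
}

#' Generate an area-labelled bumpy icosphere mesh
#'
#' Builds a closed 2-manifold mesh emulating a downsampled cortical
#' surface: an icosphere of `20 * 4^nSubdivisions` triangles, optionally
#' deformed by radial sinusoidal bumps that create convex ("gyral") caps,
#' concave ("sulcal") pits and intervening saddle bands, and partitioned
#' into `nAreas` contiguous areas by angular (longitude) sectors, mimicking
#' atlas parcels.
#'
#' The radial displacement is
#' `r(theta, phi) = radius + bumpAmplitude * sin(bumpFrequency * theta) *
#' cos(bumpFrequency * phi)` with `theta` the polar and `phi` the azimuth
#' angle; the `sin(f * theta)` factor vanishes at the poles so the
#' deformation is smooth there.
#'
#' @param nSubdivisions Number of icosahedron subdivisions (>= 1).
#' @param radius Sphere radius in mm (> 0).
#' @param bumpAmplitude Bump height in mm (0 disables bumps).
#' @param bumpFrequency Integer angular frequency of the bumps.
#' @param nAreas Number of contiguous areas (>= 2).
#' @param seed Integer seed (kept for interface uniformity; the
#'   construction is deterministic).
#' @return A [TriangleMesh-class] with `nAreas` area labels.
#' @examples
#' mesh <- makeAreaLabeledSphereMesh(2, radius = 50, nAreas = 4)
#' nTriangles(mesh)  # 320
#' @export
makeAreaLabeledSphereMesh <- function(nSubdivisions, radius = 50,
                                      bumpAmplitude = 0, bumpFrequency = 6,
                                      nAreas = 4, seed = 1L) {
  stopIfNot(radius > 0, "radius must be positive")
  stopIfNot(nSubdivisions >= 1, "nSubdivisions must be >= 1")
  stopIfNot(nAreas >= 2, "nAreas must be >= 2")
  ico <- icosahedronBase()
  for (i in seq_len(nSubdivisions)) ico <- subdivideOnce(ico$vertices, ico$faces)
  v <- ico$vertices
  # spherical angles of each (unit) vertex
  theta <- acos(pmin(1, pmax(-1, v[, 3])))       # polar, [0, pi]
  phi <- atan2(v[, 2], v[, 1])                   # azimuth, (-pi, pi]
  r <- radius + bumpAmplitude * sin(bumpFrequency * theta) *
    cos(bumpFrequency * phi)
  verts <- v * r
  dimnames(verts) <- NULL
  faces <- ico$faces
  storage.mode(faces) <- "integer"
  # area labels by azimuth sector of the triangle centroid
  cent <- (verts[faces[, 1], ] + verts[faces[, 2], ] + verts[faces[, 3], ]) / 3
  cphi <- atan2(cent[, 2], cent[, 1])            # (-pi, pi]
  sector <- floor((cphi + pi) / (2 * pi) * nAreas)
  sector[sector >= nAreas] <- nAreas - 1L
  labels <- paste0("area", sector + 1L)
  new("TriangleMesh", vertices = verts, triangles = faces,
      areaLabels = labels)
}

# internal fixture: parametric torus mesh (closed, outward-wound)
torusMesh <- function(nU = 24L, nV = 12L, R = 3, r = 1) {
  iu <- rep(seq_len(nU) - 1L, each = nV)
  iv <- rep(seq_len(nV) - 1L, times = nU)
  u <- 2 * pi * iu / nU
  vv <- 2 * pi * iv / nV
  verts <- cbind((R + r * cos(vv)) * cos(u),
                 (R + r * cos(vv)) * sin(u),
                 r * sin(vv))
  idx <- function(i, j) ((i %% nU) * nV + (j %% nV)) + 1L
  faces <- matrix(0L, 2L * nU * nV, 3L)
  k <- 1L
  for (i in 0:(nU - 1L)) for (j in 0:(nV - 1L)) {
    a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    faces[k, ] <- c(a, b, c); faces[k + 1L, ] <- c(a, c, d)
    k <- k + 2L
  }
  new("TriangleMesh", vertices = verts, triangles = faces,
      areaLabels = character(0))
}

# internal: map each undirected vertex-pair edge to the triangles using it
meshEdgeTable <- function(mesh) {
  tr <- mesh@triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  triOf <- rep(seq_len(nrow(tr)), times = 3L)
  key <- e[, 1] * (nrow(mesh@vertices) + 1) + e[, 2]
  list(key = key, tri = triOf)
}

#' Triangle adjacency of a mesh
#'
#' Two triangles are adjacent iff they share an edge (two vertices). On a
#' closed manifold every triangle has exactly 3 neighbors; boundary edges
#' (one incident triangle) are permitted for open cortical patches.
#'
#' @param mesh A [TriangleMesh-class].
#' @return Integer matrix (nPairs x 2) of adjacent triangle id pairs
#'   (1-based, first column < second).
#' @export
triangleAdjacency <- function(mesh) {
  et <- meshEdgeTable(mesh)
  o <- order(et$key)
  key <- et$key[o]; tri <- et$tri[o]
  runs <- rle(key)
  if (any(runs$lengths > 2L))
    stop("non-manifold mesh: an edge is shared by more than 2 triangles",
         call. = FALSE)
  ends <- cumsum(runs$lengths)
  shared <- runs$lengths == 2L
  a <- tri[ends[shared] - 1L]
  b <- tri[ends[shared]]
  if (!length(a)) return(matrix(integer(0), 0, 2))
  cbind(pmin(a, b), pmax(a, b))
}

#' Triangle centroids
#'
#' @param mesh A [TriangleMesh-class].
#' @return Numeric matrix (nTriangles x 3) of centroid coordinates (mm),
#'   the arithmetic mean of the three vertices.
#' @export
triangleCenters <- function(mesh) {
  v <- mesh@vertices; tr <- mesh@triangles
  (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
     v[tr[, 3], , drop = FALSE]) / 3
}

#' Triangle areas
#'
#' @param mesh A [TriangleMesh-class].
#' @return List with `areas` (numeric vector, mm^2; half cross-product
#'   magnitudes) and `meanArea`.
#' @export
triangleAreas <- function(mesh) {
  v <- mesh@vertices; tr <- mesh@triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a <- rowNorms(cr) / 2
  if (any(a <= .Machine$double.eps * 100))
    stop("degenerate mesh: zero-area triangle present", call. = FALSE)
  list(areas = a, meanArea = mean(a))
}
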