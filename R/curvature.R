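#' @include mesh.R
NULL

# Directed-edge orientation check: a consistently oriented triangle mesh
# never repeats a directed edge. Returns TRUE/FALSE.
isConsistentlyOriented <- function(mesh) {
  tr <- mesh@triangles
  nv <- nrow(mesh@vertices)
  de <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- de[, 1] * (nv + 1) + de[, 2]
  !anyDuplicated(key)
}

# Signed volume of a closed mesh (positive when faces are outward-wound).
signedMeshVolume <- function(mesh) {
  v <- mesh@vertices; tr <- mesh@triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c <- v[tr[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(a * cr) / 6
}

# Per-vertex angle deficit 2*pi - sum of incident triangle angles
# (closed meshes). Exposed internally for the Gauss-Bonnet check.
angleDeficits <- function(mesh) {
  v <- mesh@vertices; tr <- mesh@triangles
  ang <- matrix(0, nrow(tr), 3)
  for (k in 1:3) {
    i <- tr[, k]; j <- tr[, (k %% 3) + 1]; l <- tr[, ((k + 1) %% 3) + 1]
    e1 <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    e2 <- v[l, , drop = FALSE] - v[i, , drop = FALSE]
    cosang <- rowSums(e1 * e2) / (rowNorms(e1) * rowNorms(e2))
    ang[, k] <- acos(pmin(1, pmax(-1, cosang)))
  }
  sums <- rep(0, nrow(v))
  for (k in 1:3) {
    s <- rowsum(ang[, k], tr[, k])
    sums[as.integer(rownames(s))] <- sums[as.integer(rownames(s))] + s[, 1]
  }
  2 * pi - sums
}

#' Classify mesh triangles as gyrus, sulcus or saddle
#'
#' Computes discrete curvature per vertex and classifies each triangle from
#' the curvature signs, emulating the gyral/sulcal/saddle partition of a
#' cortical surface:
#' \itemize{
#'   \item Gaussian curvature `K`: angle deficit divided by the barycentric
#'     vertex area (one third of incident triangle areas), units 1/mm^2.
#'   \item Mean curvature `H`: cotangent-Laplacian mean-curvature vector,
#'     signed by the outward vertex normal, units 1/mm. The sign convention
#'     makes a sphere (convex, "gyral") have `H < 0`.
#' }
#' Per-triangle values are the means over the triangle's three vertices.
#' Classification: `K > tol, H < 0` gyrus (convex cap/ridge);
#' `K > tol, H > 0` sulcus (concave pit); `K < -tol` saddle; `|K| <= tol`
#' by the sign of `H` alone (zero `H` falls to saddle).
#'
#' @param mesh A closed (or near-closed), consistently outward-oriented
#'   [TriangleMesh-class].
#' @param neighborhoodRings Retained for interface stability; curvature is
#'   evaluated on the 1-ring (the only ring used).
#' @param tol Flatness tolerance on `|K|` (1/mm^2).
#' @return List with `classOfTriangle` (character), `meanCurvature` and
#'   `gaussianCurvature` (per-triangle numerics), and the per-vertex
#'   `vertexH`, `vertexK`.
#' @export
classifySurface <- function(mesh, neighborhoodRings = 1L, tol = 1e-8) {
  if (!isConsistentlyOriented(mesh))
    stop("mesh is not consistently oriented; fix the triangle winding ",
         "(all faces must wind the same way, outward normals)",
         call. = FALSE)
  et <- meshEdgeTable(mesh)
  closed <- all(rle(sort(et$key))$lengths == 2L)
  if (closed && signedMeshVolume(mesh) < 0)
    stop("mesh faces are wound inward; flip the triangle orientation ",
         "so normals point outward", call. = FALSE)

  v <- mesh@vertices; tr <- mesh@triangles
  nv <- nrow(v)
  areas <- triangleAreas(mesh)$areas

  # face normals (outward by winding), area-weighted vertex normals
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- matrix(0, nv, 3)
  for (k in 1:3) {
    for (d in 1:3) {
      s <- rowsum(fn[, d], tr[, k])
      vn[as.integer(rownames(s)), d] <- vn[as.integer(rownames(s)), d] + s[, 1]
    }
  }
  vn <- vn / pmax(rowNorms(vn), .Machine$double.eps)

  # barycentric mixed vertex areas
  va <- rep(0, nv)
  for (k in 1:3) {
    s <- rowsum(areas / 3, tr[, k])
    va[as.integer(rownames(s))] <- va[as.integer(rownames(s))] + s[, 1]
  }

  # Gaussian curvature: angle deficit / vertex area
  K <- angleDeficits(mesh) / va

  # cotangent weights: angle at vertex l is opposite edge (i, j)
  wi <- integer(0); wj <- integer(0); wv <- numeric(0)
  for (k in 1:3) {
    i <- tr[, k]; j <- tr[, (k %% 3) + 1]; l <- tr[, ((k + 1) %% 3) + 1]
    a1 <- v[i, , drop = FALSE] - v[l, , drop = FALSE]
    a2 <- v[j, , drop = FALSE] - v[l, , drop = FALSE]
    cosang <- rowSums(a1 * a2)
    cr <- cbind(a1[, 2] * a2[, 3] - a1[, 3] * a2[, 2],
                a1[, 3] * a2[, 1] - a1[, 1] * a2[, 3],
                a1[, 1] * a2[, 2] - a1[, 2] * a2[, 1])
    cotl <- cosang / pmax(rowNorms(cr), .Machine$double.eps)
    wi <- c(wi, i, j); wj <- c(wj, j, i); wv <- c(wv, cotl, cotl)
  }
  # mean-curvature vector (1 / (2 A_i)) * sum_j w_ij (x_i - x_j)
  Hvec <- matrix(0, nv, 3)
  diff <- v[wi, , drop = FALSE] - v[wj, , drop = FALSE]
  for (d in 1:3) {
    s <- rowsum(wv * diff[, d], wi)
    Hvec[as.integer(rownames(s)), d] <- s[, 1]
  }
  Hvec <- Hvec / (2 * va)
  # signed so a convex (spherical) surface has H < 0
  H <- -rowSums(Hvec * vn) / 2

  triK <- (K[tr[, 1]] + K[tr[, 2]] + K[tr[, 3]]) / 3
  triH <- (H[tr[, 1]] + H[tr[, 2]] + H[tr[, 3]]) / 3
  cls <- ifelse(triK > tol,
                ifelse(triH < 0, "gyrus", "sulcus"),
                ifelse(triK < -tol, "saddle",
                       ifelse(triH < 0, "gyrus",
                              ifelse(triH > 0, "sulcus", "saddle"))))
  list(classOfTriangle = cls, meanCurvature = triH,
       gaussianCurvature = triK, vertexH = H, vertexK = K)
}
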