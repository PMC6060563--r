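#' Triangle mesh container
#'
#' A `spine_mesh` is a plain indexed triangle surface: an `n x 3` numeric
#' matrix of vertex positions (micrometres) and an `m x 3` integer matrix of
#' 1-based vertex indices, one row per triangular face. An optional
#' per-vertex scalar channel (e.g. a geodesic distance field) can be
#' attached.
#'
#' @param vertices numeric matrix `n x 3`.
#' @param faces integer matrix `m x 3`, 1-based vertex indices.
#' @param scalar optional numeric vector of length `n`.
#' @return an object of class `spine_mesh`.
#' @export
spine_mesh <- function(vertices, faces, scalar = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (nrow(faces) > 0L) {
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("degenerate face: repeated vertex index")
  }
  if (!is.null(scalar) && length(scalar) != nrow(vertices))
    stop("scalar channel length must match vertex count")
  structure(list(vertices = vertices, faces = faces, scalar = scalar),
            class = "spine_mesh")
}

#' @export
print.spine_mesh <- function(x, ...) {
  cat(sprintf("spine_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox (um): x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

## Undirected edge keys: one integer per (sorted) vertex pair.  Vertex counts
## stay far below 2^26 so the product fits exactly in a double.
edge_keys <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  lo * 2^26 + hi
}

## All face edges (3 per face) as keys, in face order:
## (v1,v2), (v2,v3), (v3,v1).
mesh_edge_keys <- function(mesh) {
  f <- mesh$faces
  c(edge_keys(f[, 1], f[, 2]), edge_keys(f[, 2], f[, 3]),
    edge_keys(f[, 3], f[, 1]))
}

## Unique undirected edges as a 2-column matrix (lo, hi).
mesh_edges <- function(mesh) {
  ek <- unique(mesh_edge_keys(mesh))
  cbind(floor(ek / 2^26), ek %% 2^26)
}

## Occurrence count of each element of a numeric key vector (exact double
## matching; avoids the string coercion of table()).
key_counts <- function(keys) {
  u <- unique(keys)
  tabulate(match(keys, u), nbins = length(u))[match(keys, u)]
}

#' Validate a triangle mesh
#'
#' Reports edge-connected face components, watertightness (every edge shared
#' by exactly two faces) and the count of boundary/non-manifold edges, plus
#' the bounding-box extents. A mesh is considered fragmented when the faces
#' fall into more than one edge-connected component.
#'
#' @param mesh a [spine_mesh].
#' @return a list with `n_components`, `watertight`, `n_nonmanifold_edges`
#'   (edges not shared by exactly two faces) and `bbox` (3-vector of
#'   extents, micrometres).
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "spine_mesh"))
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("empty mesh: nothing to validate")
  m <- nrow(mesh$faces)
  ek <- mesh_edge_keys(mesh)
  face_of <- rep.int(seq_len(m), 3L)
  u <- unique(ek)
  per_edge <- tabulate(match(ek, u), nbins = length(u))
  n_bad <- sum(per_edge != 2L)
  ## Face adjacency: faces sharing an edge key.
  ord <- order(ek)
  eks <- ek[ord]; fo <- face_of[ord]
  same <- which(eks[-1] == eks[-length(eks)])
  g <- igraph::graph_from_edgelist(
    cbind(fo[same], fo[same + 1L]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, m - length(igraph::V(g))))
  comp <- igraph::components(g)
  list(n_components = comp$no,
       watertight = n_bad == 0L,
       n_nonmanifold_edges = as.integer(n_bad),
       bbox = apply(mesh$vertices, 2, function(v) diff(range(v))),
       face_component = comp$membership)
}

#' Enclosed volume of a closed mesh
#'
#' Signed tetrahedron (divergence-theorem) volume, returned as an absolute
#' value so the result does not depend on the global face orientation.
#'
#' @param mesh a watertight [spine_mesh].
#' @return volume in cubic micrometres.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det6)) / 6
}

## Per-face areas.
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

## Flip all faces if the signed volume is negative, so outward orientation
## gives positive volume.  Only meaningful for closed single-shell meshes.
orient_outward <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  if (sum(det6) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Merge coincident vertices
#'
#' Welds vertices closer than `tol` (snapping to a grid of that pitch) and
#' drops faces that become degenerate. Off by default everywhere in the
#' package; useful for triangle-soup inputs such as STL.
#'
#' @param mesh a [spine_mesh].
#' @param tol welding tolerance in micrometres.
#' @return a [spine_mesh].
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  idx <- match(key, unique(key))
  keep <- !duplicated(idx)
  f <- matrix(idx[mesh$faces], ncol = 3L)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  spine_mesh(v[keep, , drop = FALSE], f[ok, , drop = FALSE])
}

## Apply a rigid transform x -> R x + t (R: 3x3, t: length-3).
transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  mesh$vertices <- sweep(mesh$vertices %*% t(R), 2, -t)
  mesh
}

## Rotation taking unit vector a to unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    ## 180 degrees: rotate about any axis orthogonal to a.
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a; ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

## Split a multi-component mesh into a list of single-component meshes.
split_components <- function(mesh) {
  rep_ <- validate_mesh(mesh)
  lapply(seq_len(rep_$n_components), function(k) {
    f <- mesh$faces[rep_$face_component == k, , drop = FALSE]
    vid <- sort(unique(as.vector(f)))
    spine_mesh(mesh$vertices[vid, , drop = FALSE],
               matrix(match(f, vid), ncol = 3L))
  })
}

#' Icosphere primitive
#'
#' Geodesic sphere obtained by repeated midpoint subdivision of an
#' icosahedron with re-projection onto the sphere. Used throughout the test
#' fixtures because its geodesics and volume have closed forms.
#'
#' @param subdiv number of subdivision rounds (0 = icosahedron).
#' @param radius sphere radius (micrometres).
#' @param center sphere centre.
#' @return a watertight [spine_mesh].
#' @export
mesh_icosphere <- function(subdiv = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    ek <- unique(edge_keys(c(f[, 1], f[, 2], f[, 3]),
                           c(f[, 2], f[, 3], f[, 1])))
    lo <- floor(ek / 2^26); hi <- ek %% 2^26
    mid <- (v[lo, , drop = FALSE] + v[hi, , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    midx <- nrow(v) + seq_along(ek)
    v <- rbind(v, mid)
    m12 <- midx[match(edge_keys(f[, 1], f[, 2]), ek)]
    m23 <- midx[match(edge_keys(f[, 2], f[, 3]), ek)]
    m31 <- midx[match(edge_keys(f[, 3], f[, 1]), ek)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  spine_mesh(sweep(v * radius, 2, -center), f)
}
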