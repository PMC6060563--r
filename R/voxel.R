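## Voxel-domain machinery behind the repair stage: solid voxelization of a
## closed mesh, binary morphology with (approximately) spherical structuring
## elements, and isosurface re-extraction on a conforming tetrahedral
## decomposition of the voxel lattice.
##
## The voxel grid is aligned to the absolute lattice (origin a multiple of
## the spacing) so that voxelize -> extract -> voxelize round-trips see the
## same sample points, which keeps the repair operator near-idempotent.

#' Voxelize a closed triangle mesh
#'
#' Solid (parity-fill) voxelization: for every lattice column the z
#' crossings with the surface are paired up and the voxel centres between
#' odd/even crossings are marked occupied. Vertices are perturbed by a
#' deterministic sub-nanometre hash jitter so rays never hit edges exactly.
#'
#' @param mesh a watertight [spine_mesh] (multiple closed components are
#'   fine; each is filled independently by parity).
#' @param spacing voxel edge length (micrometres).
#' @param pad number of empty voxels of padding around the bounding box.
#' @return a `voxel_grid`: list with `origin_index` (integer 3-vector, the
#'   lattice index of voxel `[1,1,1]`), `spacing`, and logical array `occ`.
#' @export
voxelize_mesh <- function(mesh, spacing = 0.075, pad = 3L) {
  stopifnot(spacing > 0)
  v <- mesh$vertices
  ## Deterministic per-vertex jitter, ~1e-5 voxel: breaks ray/edge ties.
  h <- function(i, s) {
    x <- sin(i * 12.9898 + s * 78.233) * 43758.5453
    (x - floor(x) - 0.5) * 2e-5 * spacing
  }
  i <- seq_len(nrow(v))
  v <- v + cbind(h(i, 1), h(i, 2), h(i, 3))
  lo <- floor(apply(v, 2, min) / spacing) - pad
  hi <- ceiling(apply(v, 2, max) / spacing) + pad
  dims <- as.integer(hi - lo + 1)
  center1 <- function(ax, idx) (lo[ax] + idx - 1) * spacing  # voxel centres
  f <- mesh$faces
  cols <- integer(0); zs <- numeric(0)
  for (t in seq_len(nrow(f))) {
    p <- v[f[t, ], , drop = FALSE]
    area2 <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
             (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1])
    if (abs(area2) < 1e-14) next
    if (area2 < 0) { p <- p[c(1, 3, 2), ]; area2 <- -area2 }
    ix <- max(1, ceiling(min(p[, 1]) / spacing - lo[1] + 1)):
          min(dims[1], floor(max(p[, 1]) / spacing - lo[1] + 1))
    iy <- max(1, ceiling(min(p[, 2]) / spacing - lo[2] + 1)):
          min(dims[2], floor(max(p[, 2]) / spacing - lo[2] + 1))
    if (ix[1] > ix[length(ix)] || iy[1] > iy[length(iy)]) next
    cx <- center1(1, ix); cy <- center1(2, iy)
    X <- rep(cx, times = length(cy)); Y <- rep(cy, each = length(cx))
    e1 <- (p[2, 1] - p[1, 1]) * (Y - p[1, 2]) -
          (p[2, 2] - p[1, 2]) * (X - p[1, 1])
    e2 <- (p[3, 1] - p[2, 1]) * (Y - p[2, 2]) -
          (p[3, 2] - p[2, 2]) * (X - p[2, 1])
    e3 <- (p[1, 1] - p[3, 1]) * (Y - p[3, 2]) -
          (p[1, 2] - p[3, 2]) * (X - p[3, 1])
    ins <- e1 > 0 & e2 > 0 & e3 > 0
    if (!any(ins)) next
    ## Barycentric interpolation of z at the inside centres.
    w1 <- e2[ins] / area2; w2 <- e3[ins] / area2; w3 <- e1[ins] / area2
    zc <- w1 * p[1, 3] + w2 * p[2, 3] + w3 * p[3, 3]
    ii <- rep(ix, times = length(iy))[ins]
    jj <- rep(iy, each = length(ix))[ins]
    cols <- c(cols, ii + (jj - 1L) * dims[1])
    zs <- c(zs, zc)
  }
  occ <- array(FALSE, dim = dims)
  if (length(cols)) {
    byc <- split(zs, cols)
    colid <- as.integer(names(byc))
    for (k in seq_along(byc)) {
      z <- sort(byc[[k]])
      np <- length(z) %/% 2
      if (np == 0) next
      for (q in seq_len(np)) {
        za <- z[2 * q - 1]; zb <- z[2 * q]
        izlo <- ceiling(za / spacing - lo[3] + 1)
        izhi <- floor(zb / spacing - lo[3] + 1)
        if (izlo > izhi) next
        izlo <- max(1L, izlo); izhi <- min(dims[3], izhi)
        occ[colid[k] + (seq.int(izlo, izhi) - 1L) * (dims[1] * dims[2])] <- TRUE
      }
    }
  }
  structure(list(origin_index = as.integer(lo), spacing = spacing, occ = occ),
            class = "voxel_grid")
}

## Voxel-centre coordinates for a grid.
voxel_axis <- function(grid, ax) {
  (grid$origin_index[ax] + seq_len(dim(grid$occ)[ax]) - 1) * grid$spacing
}

## Integer offsets inside a Euclidean ball of the given radius (voxels).
ball_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2 + 1e-9, ]
}

## Squared Euclidean distance to the TRUE set, exact up to `rmax` (larger
## distances are reported as > rmax^2).  Separable 1D transforms with the
## offset range clamped to rmax, vectorized per offset.
squared_distance_to_set <- function(occ, rmax) {
  d <- dim(occ)
  big <- (rmax + 2)^2
  A <- array(ifelse(occ, 0, big), d)
  R <- as.integer(ceiling(rmax)) + 1L
  for (ax in 1:3) {
    B <- A
    for (j in c(-(R:1), 1:R)) {
      xs <- max(1, 1 + j):min(d[ax], d[ax] + j)
      src <- xs - j
      idx_dst <- switch(ax, list(xs, TRUE, TRUE), list(TRUE, xs, TRUE),
                        list(TRUE, TRUE, xs))
      idx_src <- switch(ax, list(src, TRUE, TRUE), list(TRUE, src, TRUE),
                        list(TRUE, TRUE, src))
      shifted <- do.call(`[`, c(list(A), idx_src, list(drop = FALSE))) + j^2
      cur <- do.call(`[`, c(list(B), idx_dst, list(drop = FALSE)))
      B <- do.call(`[<-`, c(list(B), idx_dst, list(pmin(cur, shifted))))
    }
    A <- B
  }
  A
}

## Exact Euclidean-ball dilation and erosion (radius in voxels).
binary_dilate <- function(occ, radius) {
  if (!any(occ)) return(occ)
  squared_distance_to_set(occ, radius) <= radius^2 + 1e-9
}

binary_erode <- function(occ, radius)
  squared_distance_to_set(!occ, radius) > radius^2 + 1e-9

## Morphological closing with a spherical structuring element (radius in
## voxels).  The grid must carry at least `radius + 1` voxels of padding.
binary_close <- function(occ, radius) binary_erode(binary_dilate(occ, radius),
                                                   radius)

## 6-connected components of an occupancy array; returns an integer array
## (0 = background) and the component count.
voxel_components <- function(occ) {
  d <- dim(occ)
  idx <- which(occ)
  if (length(idx) == 0) return(list(labels = array(0L, d), n = 0L))
  pos <- arrayInd(idx, d)
  id <- seq_along(idx)
  key <- (pos[, 1]) + (pos[, 2] - 1) * d[1] + (pos[, 3] - 1) * d[1] * d[2]
  lookup <- integer(prod(d)); lookup[key] <- id
  edges <- NULL
  for (sh in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    np <- sweep(pos, 2, -sh)
    ok <- np[, 1] <= d[1] & np[, 2] <= d[2] & np[, 3] <= d[3]
    nkey <- np[ok, 1] + (np[ok, 2] - 1) * d[1] + (np[ok, 3] - 1) * d[1] * d[2]
    nid <- lookup[nkey]
    hit <- nid > 0L
    if (any(hit)) edges <- rbind(edges, cbind(id[ok][hit], nid[hit]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  labels <- array(0L, d)
  labels[idx] <- comp$membership
  list(labels = labels, n = comp$no)
}

## Freudenthal 6-tet decomposition of the unit cube; all tets share the
## main diagonal 0-7, which makes the decomposition conforming across cells.
.tet_types <- list(c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
                   c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))

## Per-pattern triangle assembly for one tetrahedron: pattern bit k set
## means local corner k (1..4) is occupied.  Triangles are listed as pairs
## of local corner indices (the crossing edges); orientation is fixed
## numerically afterwards.
.tet_case <- local({
  cases <- vector("list", 16L)
  for (p in 0:15) {
    inside <- which(bitwAnd(p, c(1L, 2L, 4L, 8L)) != 0L)
    outside <- setdiff(1:4, inside)
    tri <- NULL
    if (length(inside) %in% c(1L, 3L)) {
      s <- if (length(inside) == 1L) inside else outside
      o <- setdiff(1:4, s)
      tri <- list(rbind(c(s, o[1]), c(s, o[2]), c(s, o[3])))
    } else if (length(inside) == 2L) {
      i1 <- inside[1]; i2 <- inside[2]; o1 <- outside[1]; o2 <- outside[2]
      ring <- rbind(c(i1, o1), c(i1, o2), c(i2, o2), c(i2, o1))
      tri <- list(ring[c(1, 2, 3), ], ring[c(1, 3, 4), ])
    }
    cases[[p + 1L]] <- tri
  }
  cases
})

#' Extract the occupancy isosurface of a voxel grid
#'
#' Re-creates a watertight triangle mesh from a binary voxel grid by
#' marching over a conforming tetrahedral decomposition of the lattice
#' cells at iso-level 0.5 (surface vertices sit midway between occupied and
#' empty voxel centres). The output is manifold, closed and consistently
#' oriented outward; one surface component is produced per solid component.
#'
#' @param grid a `voxel_grid` from [voxelize_mesh()] (or built directly).
#' @return a [spine_mesh].
#' @export
extract_isosurface <- function(grid) {
  occ <- grid$occ
  d <- dim(occ)
  if (!any(occ)) stop("empty voxel grid: no occupied voxels")
  ## Cells (cubes between 8 voxel centres) with mixed occupancy.
  n1 <- d[1] - 1L; n2 <- d[2] - 1L; n3 <- d[3] - 1L
  corner_occ <- function(dx, dy, dz)
    occ[(1:n1) + dx, (1:n2) + dy, (1:n3) + dz]
  csum <- array(0L, c(n1, n2, n3))
  corner_shift <- list(c(0L,0L,0L), c(1L,0L,0L), c(0L,1L,0L), c(1L,1L,0L),
                       c(0L,0L,1L), c(1L,0L,1L), c(0L,1L,1L), c(1L,1L,1L))
  for (cs in corner_shift) csum <- csum + corner_occ(cs[1], cs[2], cs[3])
  mixed <- which(csum > 0L & csum < 8L)
  if (length(mixed) == 0) stop("degenerate voxel grid: no surface cells")
  cpos <- arrayInd(mixed, c(n1, n2, n3))
  ## Global voxel linear id of each cell corner.
  gid <- function(cs)
    (cpos[, 1] + cs[1]) + (cpos[, 2] + cs[2] - 1L) * d[1] +
    (cpos[, 3] + cs[3] - 1L) * d[1] * d[2]
  corner_ids <- vapply(corner_shift, gid, numeric(nrow(cpos)))
  corner_in <- matrix(occ[corner_ids], nrow(cpos), 8L)
  tris_a <- numeric(0); tris_b <- numeric(0); tris_c <- numeric(0)
  ins_id <- numeric(0); out_id <- numeric(0)  # representative corners
  for (tet in .tet_types) {
    ci <- tet + 1L
    pat <- corner_in[, ci[1]] + 2L * corner_in[, ci[2]] +
           4L * corner_in[, ci[3]] + 8L * corner_in[, ci[4]]
    for (p in 1:14) {
      sel <- which(pat == p)
      if (length(sel) == 0) next
      ids <- corner_ids[sel, ci, drop = FALSE]
      inside <- which(bitwAnd(p, c(1L, 2L, 4L, 8L)) != 0L)
      outside <- setdiff(1:4, inside)
      rin <- ids[, inside[1]]; rout <- ids[, outside[1]]
      for (tr in .tet_case[[p + 1L]]) {
        k1 <- edge_keys(ids[, tr[1, 1]], ids[, tr[1, 2]])
        k2 <- edge_keys(ids[, tr[2, 1]], ids[, tr[2, 2]])
        k3 <- edge_keys(ids[, tr[3, 1]], ids[, tr[3, 2]])
        tris_a <- c(tris_a, k1); tris_b <- c(tris_b, k2)
        tris_c <- c(tris_c, k3)
        ins_id <- c(ins_id, rin); out_id <- c(out_id, rout)
      }
    }
  }
  keys <- unique(c(tris_a, tris_b, tris_c))
  vox_center <- function(lin) {
    lin0 <- lin - 1
    ix <- lin0 %% d[1]; rest <- (lin0 - ix) / d[1]
    iy <- rest %% d[2]; iz <- (rest - iy) / d[2]
    cbind((grid$origin_index[1] + ix) * grid$spacing,
          (grid$origin_index[2] + iy) * grid$spacing,
          (grid$origin_index[3] + iz) * grid$spacing)
  }
  ka <- floor(keys / 2^26); kb <- keys %% 2^26
  verts <- (vox_center(ka) + vox_center(kb)) / 2
  faces <- cbind(match(tris_a, keys), match(tris_b, keys),
                 match(tris_c, keys))
  ## Orient each triangle so its normal points from occupied to empty.
  p1 <- verts[faces[, 1], , drop = FALSE]
  p2 <- verts[faces[, 2], , drop = FALSE]
  p3 <- verts[faces[, 3], , drop = FALSE]
  nrm <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) -
               (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
               (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) -
               (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
               (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
               (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
  dir <- vox_center(out_id) - vox_center(ins_id)
  flip <- rowSums(nrm * dir) < 0
  faces[flip, ] <- faces[flip, c(1, 3, 2)]
  spine_mesh(verts, faces)
}

## Separable 2D Gaussian blur of a numeric matrix (zero padding).
gaussian_blur_2d <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  d <- dim(m)
  out <- matrix(0, d[1], d[2])
  for (j in -r:r) {  # rows
    src <- max(1, 1 + j):min(d[1], d[1] + j)
    dst <- src - j
    out[dst, ] <- out[dst, ] + k[j + r + 1] * m[src, ]
  }
  out2 <- matrix(0, d[1], d[2])
  for (j in -r:r) {  # cols
    src <- max(1, 1 + j):min(d[2], d[2] + j)
    dst <- src - j
    out2[, dst] <- out2[, dst] + k[j + r + 1] * out[, src]
  }
  out2
}
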