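#' Ellipse in 3D
#'
#' Constructor for the boundary-ellipse record used throughout the
#' descriptor: centroid, unit normal, unit in-plane major direction and the
#' semi-axis lengths `R >= r`.
#'
#' @param centroid 3-vector (micrometres).
#' @param normal unit 3-vector.
#' @param major_dir unit 3-vector orthogonal to `normal`.
#' @param R,r semi-major/semi-minor lengths, `R >= r > 0`.
#' @return list of class `spine_ellipse`.
#' @export
spine_ellipse <- function(centroid, normal, major_dir, R, r) {
  normal <- normal / sqrt(sum(normal^2))
  major_dir <- major_dir - sum(major_dir * normal) * normal
  major_dir <- major_dir / sqrt(sum(major_dir^2))
  stopifnot(R >= r, r > 0)
  structure(list(centroid = as.numeric(centroid), normal = normal,
                 major_dir = major_dir, R = R, r = r),
            class = "spine_ellipse")
}

#' Sample points on a 3D ellipse
#'
#' `m` parameter-uniform points starting at the major axis.
#'
#' @param e a [spine_ellipse].
#' @param m number of points.
#' @return `m x 3` matrix.
#' @export
ellipse_points <- function(e, m = 32L) {
  t <- 2 * pi * (seq_len(m) - 1L) / m
  minor_dir <- c(e$normal[2] * e$major_dir[3] - e$normal[3] * e$major_dir[2],
                 e$normal[3] * e$major_dir[1] - e$normal[1] * e$major_dir[3],
                 e$normal[1] * e$major_dir[2] - e$normal[2] * e$major_dir[1])
  outer(rep(1, m), e$centroid) +
    outer(e$R * cos(t), e$major_dir) + outer(e$r * sin(t), minor_dir)
}

#' Fit an ellipse to a 3D boundary loop
#'
#' The loop is projected onto its best-fitting plane (centroid plus the two
#' leading principal directions); a direct least-squares conic fit
#' (Halir-Flusser) is then performed in the plane and returned with
#' semi-axes ordered `R >= r`. The ellipse normal is the third principal
#' direction; its sign (and the caller-facing major-axis sign) is left to
#' the caller.
#'
#' @param pts `k x 3` matrix of loop points, `k >= 6`.
#' @return a [spine_ellipse].
#' @export
fit_boundary_ellipse <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 6) stop("DegenerateBoundary: need at least 6 points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("DegenerateBoundary: points are collinear")
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]; nrm <- sv$v[, 3]
  u <- X %*% e1; w <- X %*% e2
  fit <- fit_ellipse_2d(cbind(u, w))
  centroid3 <- ctr + fit$cx * e1 + fit$cy * e2
  major3 <- cos(fit$phi) * e1 + sin(fit$phi) * e2
  spine_ellipse(centroid3, nrm, major3, fit$a, fit$b)
}

## Direct least-squares ellipse fit in 2D (Halir & Flusser's numerically
## stable split of the Fitzgibbon method).  Returns centre, semi-axes
## a >= b and major-axis angle phi.
fit_ellipse_2d <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, rep(1, length(x)))
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T_ <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  ## Feasible eigenvector: 4ac - b^2 > 0.
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) -
    Re(ev$vectors[2, ])^2
  a1 <- Re(ev$vectors[, which(cond > 0)[1]])
  if (!length(a1)) stop("DegenerateBoundary: no ellipse fits the loop")
  coef <- c(a1, T_ %*% a1)           # A B C D E F
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F_ <- coef[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F_ * B^2 - B * D * E - 4 * A * C * F_)
  s <- sqrt((A - C)^2 + B^2)
  a <- sqrt(num / (den * (-(A + C) - s)))
  b <- sqrt(num / (den * (-(A + C) + s)))
  phi <- if (abs(B) < 1e-12 && A <= C) 0 else
         if (abs(B) < 1e-12) pi / 2 else atan2(C - A - s, B)
  if (b > a) { tmp <- a; a <- b; b <- tmp; phi <- phi + pi / 2 }
  phi <- atan2(sin(phi), cos(phi))
  list(cx = cx, cy = cy, a = a, b = b, phi = phi)
}

## ---- 3D convex hull (incremental) and hull volume ------------------------

## Returns the hull triangles (rows of vertex indices, outward-oriented).
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points for a 3D hull")
  scale <- max(apply(pts, 2, function(c) diff(range(c))), 1e-12)
  eps <- 1e-10 * scale
  ## Initial simplex: extreme pair, farthest from line, farthest from plane.
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) i2 <- which.max(rowSums(sweep(pts, 2, pts[i1, ])^2))
  d12 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  crs <- cbind(rel[, 2] * d12[3] - rel[, 3] * d12[2],
               rel[, 3] * d12[1] - rel[, 1] * d12[3],
               rel[, 1] * d12[2] - rel[, 2] * d12[1])
  i3 <- which.max(rowSums(crs^2))
  nrm0 <- crossv(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  h <- abs(rel %*% nrm0)
  i4 <- which.max(h)
  if (h[i4] < eps) stop("degenerate point set: coplanar points")
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  ctr <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient <- function(tri) {
    nr <- crossv(pts[tri[2], ] - pts[tri[1], ], pts[tri[3], ] - pts[tri[1], ])
    if (sum(nr * (ctr - pts[tri[1], ])) > 0) tri[c(1, 3, 2)] else tri
  }
  faces <- t(apply(faces, 1, orient))
  alive <- rep(TRUE, 4)
  fnorm <- function(tri)
    crossv(pts[tri[2], ] - pts[tri[1], ], pts[tri[3], ] - pts[tri[1], ])
  norms <- t(apply(faces, 1, fnorm))
  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    live <- which(alive)
    d <- rowSums(norms[live, , drop = FALSE] *
                 (matrix(pts[p, ], length(live), 3, byrow = TRUE) -
                  pts[faces[live, 1], , drop = FALSE]))
    vis <- live[d > eps]
    if (length(vis) == 0) next
    ## Horizon = edges of visible faces shared with exactly one visible face.
    vfaces <- faces[vis, , drop = FALSE]
    ed <- rbind(vfaces[, c(1, 2)], vfaces[, c(2, 3)], vfaces[, c(3, 1)])
    key <- edge_keys(ed[, 1], ed[, 2])
    horiz <- ed[key_counts(key) == 1L, , drop = FALSE]
    alive[vis] <- FALSE
    for (hh in seq_len(nrow(horiz))) {
      tri <- orient(c(horiz[hh, 1], horiz[hh, 2], p))
      faces <- rbind(faces, tri)
      norms <- rbind(norms, fnorm(tri))
      alive <- c(alive, TRUE)
    }
  }
  faces[alive, , drop = FALSE]
}

crossv <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

## Volume of the convex hull of a 3D point set.
convex_hull_volume <- function(pts) {
  tri <- convex_hull_3d(pts)
  mesh_volume(spine_mesh(pts, tri))
}

#' Volume of one geodesic region from its boundary loops
#'
#' A region's volume is approximated by the convex hull of its two
#' boundaries: two ellipses for interior regions, or an ellipse and a point
#' for the basal (insertion) and apical regions.
#'
#' @param bottom,top a [spine_ellipse] each, or a numeric 3-vector for the
#'   degenerate point boundaries at the insertion point and the apex.
#' @param samples_per_ellipse points sampled on each ellipse boundary.
#' @return volume in cubic micrometres.
#' @export
region_volume <- function(bottom, top, samples_per_ellipse = 64L) {
  as_pts <- function(b) {
    if (inherits(b, "spine_ellipse")) ellipse_points(b, samples_per_ellipse)
    else matrix(as.numeric(b), 1, 3)
  }
  pb <- as_pts(bottom); pt <- as_pts(top)
  if (nrow(pb) == nrow(pt) && max(abs(pb - pt)) < 1e-12)
    stop("degenerate region: coincident boundaries enclose no volume")
  vol <- tryCatch(convex_hull_volume(rbind(pb, pt)),
                  error = function(e)
                    stop("degenerate region: ", conditionMessage(e)))
  if (vol <= 0) stop("degenerate region: zero volume")
  vol
}
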