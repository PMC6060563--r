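#' Simulation configuration
#'
#' @param points_per_ellipse ring sampling density (>= 8); identical for
#'   every ellipse of one spine so consecutive rings triangulate directly.
#' @param subdivision_iterations Loop subdivision rounds applied to the
#'   lofted mesh.
#' @param seed integer seed.
#' @param resample_invalid reject-and-resample Gaussian draws that violate
#'   the feature invariants (otherwise clamp with a warning count).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(points_per_ellipse = 32L,
                              subdivision_iterations = 2L, seed = 1L,
                              resample_invalid = TRUE) {
  stopifnot(points_per_ellipse >= 8L, subdivision_iterations >= 0L)
  structure(list(points_per_ellipse = as.integer(points_per_ellipse),
                 subdivision_iterations = as.integer(subdivision_iterations),
                 seed = as.integer(seed),
                 resample_invalid = isTRUE(resample_invalid)),
            class = "simulation_config")
}

#' Sample feature vectors from one mixture component
#'
#' Draws 54-feature vectors from `N(mu_c, Sigma_c)` of a fitted
#' [fit_mixture()] model (de-standardizing if the model was fitted on
#' z-scores). Draws violating the feature invariants (negative heights,
#' axes or volumes, `|cos phi| > 1`, angles out of range, `R < r`) are
#' rejected and redrawn by default.
#'
#' @param model a `mixture_model`.
#' @param cluster component index.
#' @param n number of spines to sample.
#' @param seed integer seed.
#' @param resample_invalid see [simulation_config()].
#' @return `n x 54` matrix with [feature_names()] columns; attribute
#'   `n_clamped` counts clamped draws when `resample_invalid = FALSE`.
#' @export
sample_features <- function(model, cluster, n, seed = 1L,
                            resample_invalid = TRUE) {
  stopifnot(inherits(model, "mixture_model"),
            cluster >= 1, cluster <= model$C)
  if (n == 0)
    return(matrix(numeric(0), 0, 54, dimnames = list(NULL, feature_names())))
  mu <- model$means[cluster, ]
  Sig <- model$covariances[[cluster]]
  L <- t(chol(Sig))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  draw <- function(k) {
    z <- matrix(rnorm(k * length(mu)), length(mu), k)
    X <- t(mu + L %*% z)
    X <- destandardize(model, X)
    colnames(X) <- feature_names()
    ## Spherical-coordinate canonicalization (exact reinterpretations):
    ## a negative h-direction colatitude is the same direction (the
    ## azimuth is not part of the descriptor), and azimuths are circular.
    ## Negative ellipse-normal colatitudes are left for the validity
    ## check (folding them would flip the stored azimuth by pi).
    tcols <- paste0("theta", 2:7)
    X[, tcols] <- abs(X[, tcols])
    ph <- grepl("^Phi", colnames(X))
    w <- atan2(sin(X[, ph]), cos(X[, ph]))
    w[w <= -pi] <- pi
    X[, ph] <- w
    X
  }
  out <- matrix(NA_real_, n, 54, dimnames = list(NULL, feature_names()))
  n_clamped <- 0L
  filled <- 0L; attempts <- 0L
  while (filled < n) {
    X <- draw(n - filled)
    ok <- apply(X, 1, function(r) isTRUE(check_feature_vector(r)))
    attempts <- attempts + nrow(X)
    if (resample_invalid) {
      keep <- X[ok, , drop = FALSE]
      if (nrow(keep)) {
        out[filled + seq_len(nrow(keep)), ] <- keep
        filled <- filled + nrow(keep)
      }
      if (attempts > 100 && (attempts - filled) / attempts > 0.5)
        stop("SimulationError: over half of the Gaussian draws violate ",
             "the feature invariants; inspect the fitted component")
    } else {
      n_clamped <- n_clamped + sum(!ok)
      out <- clamp_features(X)
      filled <- n
    }
  }
  if (!resample_invalid && n_clamped > 0)
    warning(n_clamped, " draws clamped to the feature domain")
  attr(out, "n_clamped") <- n_clamped
  out
}

clamp_features <- function(X) {
  nm <- colnames(X)
  eps <- 1e-6
  pos <- grepl("^(h|R|r|Vr|V$|phi_)", nm)
  X[, pos] <- pmax(X[, pos], eps)
  X[, grepl("^cos_phi", nm)] <- pmin(1, pmax(-1, X[, grepl("^cos_phi", nm)]))
  ang <- grepl("^(theta|Theta)", nm)
  X[, ang] <- pmin(pi, pmax(0, X[, ang]))
  ph <- grepl("^Phi", nm)
  X[, ph] <- atan2(sin(X[, ph]), cos(X[, ph]))
  ## enforce R >= r per ellipse
  for (e in 1:6) {
    R <- X[, paste0("R", e)]; r <- X[, paste0("r", e)]
    X[, paste0("R", e)] <- pmax(R, r); X[, paste0("r", e)] <- pmin(R, r)
  }
  X
}

#' Rebuild an ellipse skeleton from a feature vector
#'
#' Inverse of the angle conventions used by [extract_features()]: the
#' insertion point sits at the origin, the first centroid vector runs along
#' +z, and each subsequent direction is the unit vector whose angle with
#' its predecessor matches `cos_phi` and whose colatitude in the
#' spine-local frame matches `theta` (the branch with positive local-y
#' component is taken, since the descriptor does not store the azimuth).
#' Ellipse normals are placed at `(Theta, Phi)`; major axes are propagated
#' with minimal twist from +x.
#'
#' @param f named feature vector (names as [feature_names()]).
#' @param angle_tol tolerance (radians) for the `cos_phi`/`theta`
#'   compatibility check: the two angle families over-determine each
#'   direction, so residuals up to `angle_tol` are absorbed into the free
#'   azimuth (mixture-sampled vectors carry independent noise on both);
#'   larger inconsistencies raise an error.
#' @return a `spine_skeleton`.
#' @export
build_skeleton <- function(f, angle_tol = 0.05) {
  f <- setNames(as.numeric(f), feature_names())
  chk <- check_feature_vector(f)
  if (!isTRUE(chk))
    stop("invalid feature vector: ", paste(chk, collapse = ", "))
  hlen <- f[paste0("h", 1:7)]
  cosphi <- f[paste0("cos_phi", 1:6)]
  theta <- c(NA, f[paste0("theta", 2:7)])  # theta[i] for h_i, i = 2..7
  dirs <- matrix(0, 7, 3)
  dirs[1, ] <- c(0, 0, 1)
  for (i in 2:7) {
    a <- cos(theta[i])                  # local-z component
    prev <- dirs[i - 1, ]
    cz <- prev[3]
    uplane <- c(prev[1], prev[2], 0)
    un <- sqrt(sum(uplane^2))
    if (un < 1e-9) {
      ## Predecessor along z: cos_phi and theta describe the same angle,
      ## so they must agree up to the tolerance; theta wins.
      if (abs(acos(pmin(1, pmax(-1, cosphi[i - 1]))) - theta[i]) > angle_tol)
        stop("SkeletonError: cos_phi", i - 1, " and theta", i,
             " are inconsistent")
      s <- sin(theta[i])
      dirs[i, ] <- c(s, 0, a)           # azimuth 0 (along +x)
    } else {
      u <- uplane / un
      b <- (cosphi[i - 1] - a * cz) / un
      c2 <- 1 - a^2 - b^2
      if (c2 < -(2 * angle_tol + angle_tol^2))
        stop("SkeletonError: no direction matches cos_phi", i - 1,
             " and theta", i)
      w <- crossv(c(0, 0, 1), u)        # completes (u, w, z)
      dirs[i, ] <- a * c(0, 0, 1) + b * u + sqrt(max(0, c2)) * w
    }
    dirs[i, ] <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
  }
  cent <- apply(dirs * hlen, 2, cumsum)
  cent <- rbind(c(0, 0, 0), cent)       # c_0 .. c_7
  Theta <- f[paste0("Theta", 1:6)]; Phi <- f[paste0("Phi", 1:6)]
  Rax <- f[paste0("R", 1:6)]; rax <- f[paste0("r", 1:6)]
  ells <- vector("list", 6)
  prev_major <- c(1, 0, 0)
  for (e in 1:6) {
    nrm <- c(sin(Theta[e]) * cos(Phi[e]), sin(Theta[e]) * sin(Phi[e]),
             cos(Theta[e]))
    maj <- prev_major - sum(prev_major * nrm) * nrm
    if (sqrt(sum(maj^2)) < 1e-9) maj <- pick_orthogonal(nrm)
    maj <- maj / sqrt(sum(maj^2))
    ells[[e]] <- spine_ellipse(cent[e + 1, ], nrm, maj, Rax[e], rax[e])
    prev_major <- maj
  }
  structure(list(c0 = c(0, 0, 0), ellipses = ells, apex = cent[8, ],
                 centroids = cent,
                 frame = diag(3)), class = "spine_skeleton")
}

## Loft a stack of rings (list of m x 3 matrices, equal m) between two end
## points into a closed, consistently oriented triangle mesh.  Consecutive
## rings are joined by the cyclic vertex offset minimizing total edge
## length (minimal twist); the ends are capped with triangle fans.
loft_rings <- function(rings, bottom, top) {
  m <- nrow(rings[[1]])
  stopifnot(all(vapply(rings, nrow, integer(1)) == m))
  nr <- length(rings)
  ## Re-index rings so ring i+1 starts at the vertex nearest (in total
  ## band edge length) to ring i's start.
  for (i in seq_len(nr - 1L)) {
    a <- rings[[i]]; b <- rings[[i + 1L]]
    costs <- vapply(0:(m - 1L), function(off) {
      idx <- ((seq_len(m) - 1L + off) %% m) + 1L
      sum(sqrt(rowSums((a - b[idx, , drop = FALSE])^2)))
    }, numeric(1))
    off <- which.min(costs) - 1L
    if (off > 0) {
      idx <- ((seq_len(m) - 1L + off) %% m) + 1L
      rings[[i + 1L]] <- b[idx, , drop = FALSE]
    }
  }
  verts <- rbind(bottom, do.call(rbind, rings), top)
  ring_id <- function(i) 1L + (i - 1L) * m + seq_len(m)
  nv <- nrow(verts)
  faces <- NULL
  ## Bottom cap fan (vertex 1); wound against the ring direction so the
  ## cone faces outward when the bands do.
  r1 <- ring_id(1)
  faces <- rbind(faces, cbind(1L, r1[c(2:m, 1)], r1))
  for (i in seq_len(nr - 1L)) {
    a <- ring_id(i); b <- ring_id(i + 1L)
    a2 <- a[c(2:m, 1)]; b2 <- b[c(2:m, 1)]
    faces <- rbind(faces, cbind(a, a2, b2), cbind(a, b2, b))
  }
  rl <- ring_id(nr)
  faces <- rbind(faces, cbind(nv, rl, rl[c(2:m, 1)]))
  orient_outward(spine_mesh(verts, faces))
}

#' Triangulate a skeleton into a closed spine mesh
#'
#' Samples every ellipse at the same number of parameter-uniform points and
#' joins consecutive rings by quad strips (split into triangles with the
#' cyclic correspondence minimizing total edge length), capping the ends
#' with triangle fans to the insertion point and the apex. Between
#' consecutive ellipses, `band_subs` interpolated rings are inserted, and
#' each end cap is built as a rounded (quarter-ellipse profile) stack of
#' `cap_subs` rings, so the lofted surface is already close to its Loop
#' limit and subdivision does not erode the tips. The result is
#' watertight, single-component and oriented outward.
#'
#' @param sk a `spine_skeleton`.
#' @param cfg a [simulation_config()].
#' @param band_subs interpolated rings per inter-ellipse band.
#' @param cap_subs rings per end cap.
#' @return a [spine_mesh].
#' @export
surface_skeleton <- function(sk, cfg = simulation_config(), band_subs = 2L,
                             cap_subs = 3L) {
  m <- cfg$points_per_ellipse
  ells <- sk$ellipses
  ## Catmull-Rom through the station values: a linear loft between only
  ## six stations chops convex bulges (the spine head) and the Loop limit
  ## then underestimates the enclosed volume; the spline restores the
  ## smooth profile the stations were measured from.
  cr <- function(p0, p1, p2, p3, t)
    0.5 * ((2 * p1) + (-p0 + p2) * t +
           (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
           (-p0 + 3 * p1 - 3 * p2 + p3) * t^3)
  ## Station scaffold: insertion point and apex act as zero-radius ends.
  st_ctr <- rbind(sk$c0, t(vapply(ells, `[[`, numeric(3), "centroid")),
                  sk$apex)
  st_R <- c(0, vapply(ells, `[[`, numeric(1), "R"), 0)
  st_r <- c(0, vapply(ells, `[[`, numeric(1), "r"), 0)
  band_ellipse <- function(e, t) {
    i <- e + 1L                       # scaffold index of E_e
    idx <- c(max(1L, i - 1L), i, i + 1L, min(nrow(st_ctr), i + 2L))
    ctr <- cr(st_ctr[idx[1], ], st_ctr[idx[2], ], st_ctr[idx[3], ],
              st_ctr[idx[4], ], t)
    Rt <- max(cr(st_R[idx[1]], st_R[idx[2]], st_R[idx[3]], st_R[idx[4]], t),
              0.05 * min(st_R[i], st_R[i + 1L]))
    rt <- max(cr(st_r[idx[1]], st_r[idx[2]], st_r[idx[3]], st_r[idx[4]], t),
              0.05 * min(st_r[i], st_r[i + 1L]))
    e1 <- ells[[e]]; e2 <- ells[[e + 1L]]
    nrm <- (1 - t) * e1$normal + t * e2$normal
    nrm <- nrm / sqrt(sum(nrm^2))
    maj <- (1 - t) * e1$major_dir + t * e2$major_dir
    maj <- maj - sum(maj * nrm) * nrm
    if (sqrt(sum(maj^2)) < 1e-9) maj <- pick_orthogonal(nrm)
    spine_ellipse(ctr, nrm, maj, max(Rt, rt), min(Rt, rt))
  }
  rings <- list()
  ## Basal cap: rounded (quarter-ellipse profile) from the insertion
  ## point up to E_1.
  e1 <- ells[[1]]
  for (k in seq_len(cap_subs)) {
    s <- k / (cap_subs + 1)
    ctr <- sk$c0 + (e1$centroid - sk$c0) * (1 - cos(s * pi / 2))
    sc <- sin(s * pi / 2)
    rings <- c(rings, list(ellipse_points(
      spine_ellipse(ctr, e1$normal, e1$major_dir, e1$R * sc,
                    e1$r * sc), m)))
  }
  for (e in seq_along(ells)) {
    rings <- c(rings, list(ellipse_points(ells[[e]], m)))
    if (e < length(ells))
      for (k in seq_len(band_subs))
        rings <- c(rings, list(ellipse_points(
          band_ellipse(e, k / (band_subs + 1)), m)))
  }
  ## Apical cap: rounded profile from E_6 up to the apex.
  e6 <- ells[[length(ells)]]
  for (k in seq_len(cap_subs)) {
    s <- k / (cap_subs + 1)
    ctr <- e6$centroid + (sk$apex - e6$centroid) * sin(s * pi / 2)
    sc <- cos(s * pi / 2)
    rings <- c(rings, list(ellipse_points(
      spine_ellipse(ctr, e6$normal, e6$major_dir, e6$R * sc,
                    e6$r * sc), m)))
  }
  loft_rings(rings, matrix(sk$c0, 1, 3), matrix(sk$apex, 1, 3))
}

#' Loop subdivision
#'
#' One round quadrisects every face; new edge vertices take the 3/8-3/8-
#' 1/8-1/8 stencil and old vertices are re-weighted with the
#' valence-dependent beta (3/16 for valence 3, 3/(8k) otherwise).
#' Watertightness and orientation are preserved.
#'
#' @param mesh a watertight manifold [spine_mesh].
#' @param iterations number of rounds (0 = identity).
#' @return a [spine_mesh].
#' @export
loop_subdivide <- function(mesh, iterations = 1L) {
  if (iterations == 0L) return(mesh)
  for (it in seq_len(iterations)) {
    val <- validate_mesh(mesh)
    if (!val$watertight)
      stop("Loop subdivision requires a watertight manifold mesh")
    v <- mesh$vertices; f <- mesh$faces
    n <- nrow(v)
    ed <- mesh_edges(mesh)
    ekey <- edge_keys(ed[, 1], ed[, 2])
    ## Opposite (wing) vertices of each edge: on a watertight mesh every
    ## edge key occurs exactly twice across the faces.
    ek3 <- c(edge_keys(f[, 2], f[, 3]), edge_keys(f[, 3], f[, 1]),
             edge_keys(f[, 1], f[, 2]))
    opp3 <- c(f[, 1], f[, 2], f[, 3])
    ord3 <- order(ek3)
    ks <- ek3[ord3]; os <- opp3[ord3]
    pick <- match(ekey, ks[seq(1, length(ks), 2)])
    wing1 <- os[seq(1, length(os), 2)][pick]
    wing2 <- os[seq(2, length(os), 2)][pick]
    epos <- 0.375 * (v[ed[, 1], , drop = FALSE] + v[ed[, 2], , drop = FALSE]) +
            0.125 * (v[wing1, , drop = FALSE] + v[wing2, , drop = FALSE])
    ## Old-vertex update.
    deg <- tabulate(as.integer(c(ed[, 1], ed[, 2])), nbins = n)
    beta <- ifelse(deg == 3, 3 / 16, 3 / (8 * pmax(deg, 1)))
    nbr_sum <- rowsum(rbind(v[ed[, 2], , drop = FALSE],
                            v[ed[, 1], , drop = FALSE]),
                      c(ed[, 1], ed[, 2]), reorder = TRUE)
    vnew <- v * (1 - deg * beta) + nbr_sum * beta
    m12 <- n + match(edge_keys(f[, 1], f[, 2]), ekey)
    m23 <- n + match(edge_keys(f[, 2], f[, 3]), ekey)
    m31 <- n + match(edge_keys(f[, 3], f[, 1]), ekey)
    faces <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
                   cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
    mesh <- spine_mesh(rbind(vnew, epos), faces)
  }
  mesh
}

#' Simulate watertight spine meshes from a fitted mixture
#'
#' Convenience wrapper: sample features, rebuild skeletons, loft and
#' Loop-subdivide. Spines whose sampled angles admit no consistent
#' skeleton are redrawn (counted in `n_redrawn`).
#'
#' @param model a `mixture_model`.
#' @param cluster component to sample from.
#' @param n number of spines.
#' @param cfg a [simulation_config()].
#' @return list with `meshes` (list of [spine_mesh]), `features`
#'   (`n x 54`), `n_redrawn`.
#' @export
simulate_spines <- function(model, cluster, n, cfg = simulation_config()) {
  meshes <- vector("list", n)
  feats <- matrix(NA_real_, n, 54, dimnames = list(NULL, feature_names()))
  redrawn <- 0L
  i <- 1L; sub_seed <- cfg$seed
  while (i <= n) {
    x <- suppressWarnings(
      sample_features(model, cluster, 1L, seed = sub_seed,
                      resample_invalid = cfg$resample_invalid))
    sub_seed <- sub_seed + 1L
    sk <- tryCatch(build_skeleton(x[1, ]), error = function(e) NULL)
    if (is.null(sk)) { redrawn <- redrawn + 1L
      if (redrawn > 20 * n) stop("SimulationError: skeleton rebuild keeps ",
                                 "failing; inspect the fitted component")
      next }
    mesh <- surface_skeleton(sk, cfg)
    if (cfg$subdivision_iterations > 0)
      mesh <- loop_subdivide(mesh, cfg$subdivision_iterations)
    meshes[[i]] <- mesh
    feats[i, ] <- x
    i <- i + 1L
  }
  list(meshes = meshes, features = feats, n_redrawn = redrawn)
}

#' Realism of simulated spines via a cross-validated classifier
#'
#' Stacks real and simulated feature matrices with class labels and
#' measures the stratified k-fold cross-validated accuracy of a binary
#' classifier (default: a CART decision tree). Accuracy near 0.5 means the
#' simulated population is statistically indistinguishable from the real
#' one by that classifier; accuracy near 1 means it is easy to tell apart.
#'
#' @param real,simulated numeric matrices with identical columns.
#' @param folds number of cross-validation folds.
#' @param seed integer seed for the fold shuffle.
#' @param classifier function(`x_train`, `y_train`, `x_test`) returning
#'   predicted labels; the default fits [rpart::rpart()].
#' @return list with `accuracy` (mean over folds), `fold_accuracy`
#'   (length `folds`), `folds`.
#' @export
realism_score <- function(real, simulated, folds = 10L, seed = 1L,
                          classifier = NULL) {
  real <- as.matrix(real); simulated <- as.matrix(simulated)
  stopifnot(ncol(real) == ncol(simulated))
  X <- rbind(real, simulated)
  y <- factor(rep(c("real", "simulated"), c(nrow(real), nrow(simulated))))
  if (nrow(X) < folds) stop("fewer rows than folds")
  if (is.null(classifier)) classifier <- rpart_classifier
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  ## Stratified folds.  With equally many rows per class (the usual
  ## balanced design) real row i and simulated row i share a fold, so a
  ## literal copy of the real data cannot leak across folds and scores
  ## the indistinguishable 0.5 it should.
  fold <- integer(length(y))
  if (nrow(real) == nrow(simulated)) {
    fr <- rep_len(seq_len(folds), nrow(real))[sample.int(nrow(real))]
    fold <- c(fr, fr)
  } else {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  }
  acc <- vapply(seq_len(folds), function(k) {
    te <- fold == k
    pred <- classifier(X[!te, , drop = FALSE], y[!te],
                       X[te, , drop = FALSE])
    mean(pred == y[te])
  }, numeric(1))
  list(accuracy = mean(acc), fold_accuracy = acc, folds = folds)
}

rpart_classifier <- function(x_train, y_train, x_test) {
  df <- data.frame(x_train, check.names = TRUE)
  df$.y <- y_train
  fit <- rpart::rpart(.y ~ ., data = df, method = "class")
  predict(fit, newdata = data.frame(x_test, check.names = TRUE),
          type = "class")
}
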