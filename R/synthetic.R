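#' Specification of a parametric synthetic spine
#'
#' Solid-of-revolution spine surrogate: a capsule-like neck joined to a
#' spherical head, optionally bent along a circular arc. All cross-section
#' radii have closed forms, so the fixtures carry their own oracle.
#'
#' @param profile one of `"stubby"`, `"thin"`, `"mushroom_like"`,
#'   `"straight_tube"`. Profile-specific defaults are filled in for any
#'   geometry argument left `NULL`.
#' @param neck_length,neck_radius,head_radius geometry (micrometres).
#' @param bend_angle total bend of the axis (radians, in `[0, pi/2]`).
#' @param mesh_resolution points per ring.
#' @return list of class `spine_spec`.
#' @export
spine_spec <- function(profile = c("mushroom_like", "thin", "stubby",
                                   "straight_tube"),
                       neck_length = NULL, neck_radius = NULL,
                       head_radius = NULL, bend_angle = NULL,
                       mesh_resolution = 28L) {
  profile <- match.arg(profile)
  def <- switch(profile,
    mushroom_like = list(neck_length = 1.0, neck_radius = 0.16,
                         head_radius = 0.38, bend_angle = 0.15),
    thin          = list(neck_length = 1.4, neck_radius = 0.14,
                         head_radius = 0.22, bend_angle = 0.2),
    stubby        = list(neck_length = 0.4, neck_radius = 0.30,
                         head_radius = 0.38, bend_angle = 0.1),
    straight_tube = list(neck_length = 1.6, neck_radius = 0.25,
                         head_radius = 0.25, bend_angle = 0))
  p <- list(profile = profile,
            neck_length = neck_length %||% def$neck_length,
            neck_radius = neck_radius %||% def$neck_radius,
            head_radius = head_radius %||% def$head_radius,
            bend_angle = bend_angle %||% def$bend_angle,
            mesh_resolution = as.integer(mesh_resolution))
  stopifnot(p$neck_length > 0, p$neck_radius > 0, p$head_radius > 0,
            p$bend_angle >= 0, p$bend_angle <= pi / 2,
            p$mesh_resolution >= 8L)
  if (p$head_radius < p$neck_radius / 2)
    stop("spec error: head_radius < neck_radius / 2 is not a spine geometry")
  structure(p, class = "spine_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Cross-section radius of the revolution profile at axial position t in
## [0, L_total].  The neck is a cylinder with a short basal taper; the
## head is a sphere centred on the axis and overlapping the neck end.
spine_profile_radius <- function(spec, t) {
  nl <- spec$neck_length; nr <- spec$neck_radius; hr <- spec$head_radius
  zc <- nl + hr * 0.6              # head centre
  taper <- pmin(1, t / (2 * nr))   # closes the base smoothly
  neck <- ifelse(t <= nl, nr * (0.6 + 0.4 * taper), 0)
  head <- ifelse(abs(t - zc) < hr, sqrt(pmax(hr^2 - (t - zc)^2, 0)), 0)
  pmax(neck, head)
}

## Total axial length of the profile (base to head apex).
spine_profile_length <- function(spec)
  spec$neck_length + spec$head_radius * 1.6

#' Generate a synthetic spine mesh with analytic ground truth
#'
#' Builds a watertight single-component mesh of the [spine_spec()] profile,
#' optionally bent along a circular arc, with optional seeded radial
#' surface roughness. The insertion point sits at the basal pole.
#'
#' @param spec a [spine_spec()].
#' @param seed integer seed (used only when `roughness > 0`).
#' @param roughness relative radial noise amplitude (e.g. 0.02).
#' @param axis_ratio cross-section minor/major axis ratio (1 = solid of
#'   revolution, the value the analytic radius oracle describes).
#' @return list with `mesh`, `insertion` (3-vector), `ground_truth`
#'   (list: `axis` points, `arclen` of each station, `radius` at each
#'   station, `radius_fn(t)`).
#' @export
make_synthetic_spine <- function(spec = spine_spec(), seed = 1L,
                                 roughness = 0, axis_ratio = 1,
                                 twist = 0.8) {
  L <- spine_profile_length(spec)
  n_st <- max(18L, ceiling(L / 0.05))
  tt <- seq(0, L, length.out = n_st + 2L)[2:(n_st + 1L)]
  rho <- spine_profile_radius(spec, tt)
  keep <- rho > 1e-6
  tt <- tt[keep]; rho <- rho[keep]
  m <- spec$mesh_resolution
  ## Axis: total turning angle bend_angle, with the bending plane slowly
  ## rotating by `twist` radians over the length (a gentle helix), so no
  ## two consecutive segments of the centroid chain are exactly straight.
  if (spec$bend_angle > 1e-9) {
    sg <- seq(0, L, length.out = 512L)
    bg <- spec$bend_angle * sg / L
    cg <- twist * sg / L
    tg <- cbind(sin(bg) * cos(cg), sin(bg) * sin(cg), cos(bg))
    ds <- c(0, diff(sg))
    pos <- apply(tg * ds, 2, cumsum)
    axis_at <- function(s) cbind(approx(sg, pos[, 1], s)$y,
                                 approx(sg, pos[, 2], s)$y,
                                 approx(sg, pos[, 3], s)$y)
    tangent_at <- function(s) {
      b <- spec$bend_angle * s / L; cc <- twist * s / L
      cbind(sin(b) * cos(cc), sin(b) * sin(cc), cos(b))
    }
  } else {
    axis_at <- function(s) cbind(0, 0, s)
    tangent_at <- function(s) cbind(0, 0, rep(1, length(s)))
  }
  if (roughness > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  ang <- 2 * pi * (seq_len(m) - 1L) / m
  rings <- lapply(seq_along(tt), function(j) {
    ctr <- axis_at(tt[j]); tg <- as.numeric(tangent_at(tt[j]))
    e1 <- crossv(tg, c(1, 0, 0))
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- crossv(tg, e1)
    rj <- rho[j]
    if (roughness > 0)
      rj <- rj * (1 + roughness * rnorm(m))
    ctr[rep(1, m), , drop = FALSE] +
      outer(rj * cos(ang), e1) +
      outer(axis_ratio * rj * sin(ang), e2)
  })
  base <- axis_at(0); apex <- axis_at(L)
  mesh <- loft_rings(rings, base, apex)
  list(mesh = mesh, insertion = as.numeric(base),
       ground_truth = list(axis = axis_at(tt), arclen = tt, radius = rho,
                           radius_fn = function(t)
                             spine_profile_radius(spec, t)))
}

#' Corrupt a spine mesh into a fragmented or detached variant
#'
#' `fragment` removes a band of faces of axial width `magnitude` around
#' the mid-neck and closes both sides, yielding two watertight components
#' separated by a gap of about `magnitude`. `detach` removes the proximal
#' part of the spine up to height `magnitude` and closes the hole, leaving
#' the insertion point about `magnitude` off the new base.
#'
#' @param mesh a watertight [spine_mesh] with its base near z = 0 growing
#'   toward +z (as produced by [make_synthetic_spine()]).
#' @param mode `"fragment"` or `"detach"`.
#' @param magnitude band width / detachment height (micrometres);
#'   0 returns the input unchanged.
#' @param insertion the spine's insertion point.
#' @param seed unused placeholder for signature stability.
#' @return list with `mesh` and `insertion`.
#' @export
corrupt_mesh <- function(mesh, mode = c("fragment", "detach"),
                         magnitude, insertion, seed = 1L) {
  mode <- match.arg(mode)
  if (magnitude == 0) return(list(mesh = mesh, insertion = insertion))
  zr <- range(mesh$vertices[, 3])
  if (magnitude > diff(zr) / 2)
    stop("magnitude exceeds half the spine extent")
  zc <- rowMeans(matrix(mesh$vertices[mesh$faces, 3], ncol = 3))
  if (mode == "fragment") {
    mid <- zr[1] + diff(zr) * 0.35        # mid-neck
    drop <- zc > mid - magnitude / 2 & zc < mid + magnitude / 2
  } else {
    drop <- zc < zr[1] + magnitude
  }
  if (!any(drop)) return(list(mesh = mesh, insertion = insertion))
  if (all(drop)) stop("magnitude removes the whole mesh")
  open_mesh <- spine_mesh(mesh$vertices,
                          mesh$faces[!drop, , drop = FALSE])
  closed <- cap_boundaries(open_mesh)
  list(mesh = closed, insertion = insertion)
}

## Close every boundary loop of an open mesh with a triangle fan to the
## loop centroid, keeping the orientation consistent with the faces the
## boundary belongs to.  Unreferenced vertices are dropped.
cap_boundaries <- function(mesh) {
  f <- mesh$faces
  dir_edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- edge_keys(dir_edges[, 1], dir_edges[, 2])
  boundary <- dir_edges[key_counts(key) == 1L, , drop = FALSE]
  v <- mesh$vertices
  while (nrow(boundary) > 0) {
    ## Chain one loop: boundary edges are directed consistently.
    loop <- boundary[1, ]
    boundary <- boundary[-1, , drop = FALSE]
    repeat {
      nxt <- which(boundary[, 1] == loop[length(loop)])[1]
      if (is.na(nxt)) break
      loop <- c(loop, boundary[nxt, 2])
      boundary <- boundary[-nxt, , drop = FALSE]
      if (loop[length(loop)] == loop[1]) break
    }
    loop <- loop[-length(loop)]           # drop closing repeat
    ctr <- colMeans(v[loop, , drop = FALSE])
    v <- rbind(v, ctr)
    ci <- nrow(v)
    ## Cap triangles reversed w.r.t. the boundary direction so the cap
    ## faces outward.
    nxt_idx <- c(loop[-1], loop[1])
    f <- rbind(f, cbind(nxt_idx, loop, ci))
  }
  vid <- sort(unique(as.vector(f)))
  spine_mesh(v[vid, , drop = FALSE], matrix(match(f, vid), ncol = 3))
}

## ---- Feature-population generator ----------------------------------------

.spinemorph_cache <- new.env(parent = emptyenv())

## The population template is the descriptor extracted from a bent,
## gently-profiled mushroom-like archetype mesh, then projected twice
## through the rebuild -> extract cycle.  The projection pulls the
## template close to the generative model's own realizable set (a
## 6-station skeleton cannot carry arbitrarily bulgy profiles), so
## sampled vectors are near-fixed-points of the cycle and round trips are
## dominated by sampling noise rather than representation error.
## Memoized: every step is deterministic.
spine_feature_template <- function() {
  if (is.null(.spinemorph_cache$template)) {
    sp <- make_synthetic_spine(
      spine_spec("mushroom_like", neck_length = 1.3, neck_radius = 0.17,
                 head_radius = 0.22, bend_angle = 0.5),
      axis_ratio = 0.8)
    f <- extract_features(sp$mesh, sp$insertion)$features
    cfg <- simulation_config()
    for (k in 1:3) {
      mesh <- loop_subdivide(surface_skeleton(build_skeleton(f), cfg),
                             cfg$subdivision_iterations)
      f <- extract_features(mesh, c(0, 0, 0))$features
    }
    .spinemorph_cache$template <- f
  }
  .spinemorph_cache$template
}

## Per-coordinate sampling sds for the population generator: relative for
## sizes and volumes, absolute for angles.
feature_population_sds <- function(mu, rel = 0.03) {
  nm <- names(mu)
  sds <- abs(mu) * rel
  ## Angular noise is kept small relative to each coordinate's distance
  ## from its domain boundary (the straight-joint bound for cosines, the
  ## pole for colatitudes, the wrap cut for azimuths), so the sampled
  ## marginals stay effectively Gaussian: boundary events are >= 4 sigma.
  ## Within-cluster variation is carried by the morphological features.
  sds[grepl("^cos_phi", nm)] <- 0.0005
  co <- grepl("^(theta|Theta)", nm)
  sds[co] <- pmax(0.08 * abs(mu[co]), 0.0008)
  sds[grepl("^Phi", nm)] <- 0.012
  sds[grepl("^phi_", nm)] <- abs(mu[grepl("^phi_", nm)]) * rel
  sds
}

#' Sample a synthetic 54-feature population with known mixture structure
#'
#' Generates `n_clusters` Gaussian components around archetypal spine
#' templates (varying overall size, head-to-neck ratio and elongation),
#' placed on a simplex scaled so the smallest pairwise mean distance along
#' its connecting direction equals `separation` pooled standard
#' deviations. Covariances are diagonal-dominant (a single random
#' correlation direction at weight 0.3). Draws violating the feature
#' invariants are rejected and redrawn, and the exact generating model is
#' returned.
#'
#' @param n_clusters number of components (>= 1).
#' @param n_per_cluster draws per component.
#' @param separation pooled-sd units between component means (>= 0).
#' @param seed integer seed.
#' @return list with `X` (`n x 54`), `labels`, `model` (a
#'   `mixture_model` with the true parameters).
#' @export
sample_feature_population <- function(n_clusters = 3, n_per_cluster = 500,
                                      separation = 5, seed = 1L) {
  stopifnot(n_clusters >= 1, separation >= 0)
  if (n_clusters > 1 && separation == 0)
    warning("separation 0 with several clusters: components coincide")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  tmpl <- spine_feature_template()
  sds <- feature_population_sds(tmpl)
  nm <- names(tmpl)
  ## Morphology-direction basis: tangent directions of the consistent-
  ## feature manifold (so offset means still describe a realizable spine):
  ## overall isotropic scale, head-to-neck ratio, elongation.  Each column
  ## is d(feature)/d(log parameter) at the template.
  basis <- matrix(0, 54, 3, dimnames = list(nm, NULL))
  lin <- grepl("^(h|R|r)", nm)                 # lengths scale linearly
  basis[lin, 1] <- tmpl[lin]
  vol <- grepl("^(Vr|V$)", nm)                 # volumes scale cubically
  basis[vol, 1] <- 3 * tmpl[vol]
  head_ax <- c(paste0("R", 4:6), paste0("r", 4:6))
  basis[head_ax, 2] <- tmpl[head_ax]           # head radii
  basis[paste0("Vr", 5:7), 2] <- 2 * tmpl[paste0("Vr", 5:7)]
  basis["V", 2] <- 2 * sum(tmpl[paste0("Vr", 5:7)]) * tmpl["V"] /
    sum(tmpl[paste0("Vr", 1:7)])
  basis[c("phi_24", "phi_26"), 2] <- 2 * tmpl[c("phi_24", "phi_26")]
  basis[paste0("h", 1:7), 3] <- tmpl[paste0("h", 1:7)]   # elongation
  basis[vol, 3] <- tmpl[vol]
  ## Whiten (per-coordinate sd metric) and orthonormalize there, so the
  ## simplex edge lengths are pooled-sd distances.
  wbasis <- basis / sds
  wbasis <- qr.Q(qr(wbasis))
  ## Centred simplex coordinates for the cluster offsets.
  k <- min(3L, max(1L, n_clusters - 1L))
  simplex <- matrix(0, n_clusters, k)
  if (n_clusters > 1) {
    raw <- diag(n_clusters)[, seq_len(k), drop = FALSE]
    simplex <- sweep(raw, 2, colMeans(raw))
    dmin <- min(dist(simplex))
    simplex <- simplex / dmin * separation
  }
  means <- matrix(rep(tmpl, n_clusters), n_clusters, 54, byrow = TRUE,
                  dimnames = list(NULL, nm))
  covs <- vector("list", n_clusters)
  for (c_ in seq_len(n_clusters)) {
    offs_sd <- as.numeric(wbasis[, seq_len(k), drop = FALSE] %*%
                            simplex[c_, ])
    means[c_, ] <- tmpl + offs_sd * sds
    ## Per-cluster random diagonal covariance (jittered scales).
    sd_c <- sds * runif(54, 0.85, 1.15)
    covs[[c_]] <- diag(sd_c^2)
  }
  model <- structure(list(C = n_clusters,
                          weights = rep(1 / n_clusters, n_clusters),
                          means = means, covariances = covs,
                          log_likelihood = NA_real_, n_params = NA_real_,
                          bic = NA_real_, bic_curve = NULL,
                          feature_names = nm, standardize = NULL,
                          n = n_clusters * n_per_cluster),
                     class = "mixture_model")
  X <- matrix(NA_real_, n_clusters * n_per_cluster, 54,
              dimnames = list(NULL, nm))
  labels <- rep(seq_len(n_clusters), each = n_per_cluster)
  for (c_ in seq_len(n_clusters)) {
    X[labels == c_, ] <- sample_features(model, c_, n_per_cluster,
                                         seed = seed + 7919L * c_)
  }
  list(X = X, labels = labels, model = model)
}
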