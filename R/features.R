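#' Canonical names of the 54 spine features
#'
#' Order: 7 inter-centroid heights `h1..h7` (um); 6 semi-major axes
#' `R1..R6` and 6 semi-minor axes `r1..r6` (um); 6 bending cosines
#' `cos_phi1..cos_phi6` (cosine of the angle between consecutive centroid
#' vectors); 6 colatitudes `theta2..theta7` of the centroid vectors in the
#' spine-local frame (rad); 6 colatitudes `Theta1..Theta6` and 6 azimuths
#' `Phi1..Phi6` of the ellipse normals (rad); 3 section area ratios
#' `phi_24, phi_26, phi_46`; 7 region volumes `Vr1..Vr7` and the total
#' volume `V` (um^3). The first 36 (heights, axes, cosines, ratios,
#' volumes) are morphological; the 18 angles are directional.
#'
#' @return character vector of length 54.
#' @export
feature_names <- function() {
  c(paste0("h", 1:7), paste0("R", 1:6), paste0("r", 1:6),
    paste0("cos_phi", 1:6), paste0("theta", 2:7),
    paste0("Theta", 1:6), paste0("Phi", 1:6),
    "phi_24", "phi_26", "phi_46", paste0("Vr", 1:7), "V")
}

#' @rdname feature_names
#' @export
morphological_features <- function() {
  c(paste0("h", 1:7), paste0("R", 1:6), paste0("r", 1:6),
    paste0("cos_phi", 1:6), "phi_24", "phi_26", "phi_46",
    paste0("Vr", 1:7), "V")
}

#' @rdname feature_names
#' @export
directional_features <- function() {
  c(paste0("theta", 2:7), paste0("Theta", 1:6), paste0("Phi", 1:6))
}

## Check the FeatureVector invariants; returns TRUE or a character vector
## of violations.
check_feature_vector <- function(f) {
  stopifnot(length(f) == 54)
  f <- setNames(as.numeric(f), feature_names())
  bad <- character(0)
  if (any(f[paste0("h", 1:7)] <= 0)) bad <- c(bad, "heights")
  R <- f[paste0("R", 1:6)]; r <- f[paste0("r", 1:6)]
  if (any(r <= 0) || any(R < r)) bad <- c(bad, "axes")
  if (any(abs(f[paste0("cos_phi", 1:6)]) > 1)) bad <- c(bad, "cos_phi")
  if (any(f[paste0("theta", 2:7)] < 0 | f[paste0("theta", 2:7)] > pi))
    bad <- c(bad, "theta")
  if (any(f[paste0("Theta", 1:6)] < 0 | f[paste0("Theta", 1:6)] > pi))
    bad <- c(bad, "Theta")
  if (any(f[paste0("Phi", 1:6)] <= -pi | f[paste0("Phi", 1:6)] > pi))
    bad <- c(bad, "Phi")
  if (any(f[c("phi_24", "phi_26", "phi_46")] <= 0)) bad <- c(bad, "ratios")
  if (any(f[c(paste0("Vr", 1:7), "V")] <= 0)) bad <- c(bad, "volumes")
  if (length(bad)) bad else TRUE
}

## ---- Level-set boundary loops --------------------------------------------

## Extract the closed polyline(s) where the per-vertex field crosses
## `level`, as ordered point loops.  Returns a list of k x 3 matrices.
## When several loops exist at one level, they are ordered by decreasing
## enclosed (projected) area.
level_set_loops <- function(mesh, mu, level) {
  v <- mesh$vertices; f <- mesh$faces
  ## Nudge the level off any exact vertex hit.
  if (any(abs(mu - level) < 1e-12)) level <- level * (1 - 1e-9) + 1e-15
  s <- mu - level
  cross_edge <- function(a, b) s[a] * s[b] < 0
  c12 <- cross_edge(f[, 1], f[, 2])
  c23 <- cross_edge(f[, 2], f[, 3])
  c31 <- cross_edge(f[, 3], f[, 1])
  ncross <- c12 + c23 + c31
  use <- which(ncross == 2L)
  if (length(use) == 0) return(list())
  ## Each crossing point lives on a unique undirected edge.
  seg_from <- numeric(0); seg_to <- numeric(0)
  keyf <- cbind(ifelse(c12[use], edge_keys(f[use, 1], f[use, 2]), NA),
                ifelse(c23[use], edge_keys(f[use, 2], f[use, 3]), NA),
                ifelse(c31[use], edge_keys(f[use, 3], f[use, 1]), NA))
  segs <- t(apply(keyf, 1, function(x) x[!is.na(x)]))
  keys <- unique(as.vector(segs))
  ka <- floor(keys / 2^26); kb <- keys %% 2^26
  t_ <- s[ka] / (s[ka] - s[kb])
  pts <- v[ka, , drop = FALSE] * (1 - t_) + v[kb, , drop = FALSE] * t_
  a <- match(segs[, 1], keys); b <- match(segs[, 2], keys)
  ## Chain segments into loops: each crossing point touches exactly 2
  ## segments on a closed manifold level set.
  g <- igraph::make_empty_graph(n = length(keys), directed = FALSE)
  g <- igraph::add_edges(g, rbind(a, b))
  comp <- igraph::components(g)
  loops <- lapply(seq_len(comp$no), function(k) {
    nodes <- which(comp$membership == k)
    if (length(nodes) < 3) return(NULL)
    sub <- igraph::induced_subgraph(g, nodes)
    if (any(igraph::degree(sub) != 2)) return(NULL)  # open chain: skip
    ord <- igraph::dfs(sub, root = 1)$order
    pts[nodes[as.integer(ord)], , drop = FALSE]
  })
  loops <- Filter(Negate(is.null), loops)
  if (length(loops) > 1) {
    area <- vapply(loops, loop_area, numeric(1))
    loops <- loops[order(area, decreasing = TRUE)]
  }
  loops
}

## Enclosed area of a closed 3D polyline (norm of the vector area).
loop_area <- function(p) {
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  q2 <- q[c(2:nrow(q), 1), , drop = FALSE]
  cr <- cbind(q[, 2] * q2[, 3] - q[, 3] * q2[, 2],
              q[, 3] * q2[, 1] - q[, 1] * q2[, 3],
              q[, 1] * q2[, 2] - q[, 2] * q2[, 1])
  0.5 * sqrt(sum(colSums(cr)^2))
}

## ---- Descriptor assembly --------------------------------------------------

#' Extract the 54-feature descriptor of a spine
#'
#' Builds the geodesic field from the insertion point, partitions the
#' surface into `K = 7` equal geodesic bands, extracts the 6 level-set
#' boundary curves between consecutive bands, fits an ellipse to each in
#' its PCA plane (adjacent regions share their boundary ellipse exactly),
#' and assembles the canonical 54 features. All angles are measured in the
#' spine-local frame (origin at the insertion point, +z along the first
#' centroid vector, +x along the first ellipse's major axis), which makes
#' the descriptor invariant to rigid motion of the input mesh.
#'
#' @param mesh a repaired, watertight, single-component [spine_mesh].
#' @param insertion numeric 3-vector (micrometres).
#' @param K number of geodesic bands; the 54-feature layout requires 7.
#' @param steiner Steiner points per edge for the geodesic solve.
#' @param samples_per_ellipse boundary samples for region volumes.
#' @return list of class `spine_features`: `features` (named numeric,
#'   length 54), `skeleton` (a `spine_skeleton`), `alpha`, `sum_region_volume`
#'   (the `sum(Vr_i)` diagnostic), `n_vertices`.
#' @export
extract_features <- function(mesh, insertion, K = 7L, steiner = 2L,
                             samples_per_ellipse = 64L) {
  if (K != 7L)
    stop("the 54-feature descriptor is defined for K = 7 regions")
  field <- geodesic_distances(mesh, insertion, steiner = steiner)
  part <- partition_regions(field, K)
  mu <- field$mu; alpha <- field$alpha
  ## Boundary ellipses at levels e * alpha / K, e = 1..6.
  ells <- vector("list", K - 1L)
  for (e in seq_len(K - 1L)) {
    loops <- level_set_loops(mesh, mu, e * alpha / K)
    if (length(loops) == 0)
      stop("FeatureExtractionError: no boundary loop at region ", e)
    loop <- loops[[1]]
    ell <- tryCatch(fit_boundary_ellipse(loop), error = function(err)
      stop("FeatureExtractionError: degenerate boundary at region ", e,
           " (", conditionMessage(err), ")"))
    ## Deterministic, rigid-motion-invariant major-axis sign: point toward
    ## the first loop vertex.
    if (sum(ell$major_dir * (loop[1, ] - ell$centroid)) < 0)
      ell$major_dir <- -ell$major_dir
    ells[[e]] <- ell
  }
  c0 <- as.numeric(insertion)
  apex_i <- which(mu == max(mu))[1]
  c7 <- mesh$vertices[apex_i, ]
  cent <- rbind(c0, do.call(rbind, lapply(ells, `[[`, "centroid")), c7)
  h <- diff(cent)                      # 7 x 3, rows h_1..h_7
  hlen <- sqrt(rowSums(h^2))
  if (any(hlen <= 0)) stop("FeatureExtractionError: coincident centroids")
  ## Orient ellipse normals distally: normal_e . h_e > 0.
  for (e in seq_len(K - 1L))
    if (sum(ells[[e]]$normal * h[e, ]) < 0)
      ells[[e]]$normal <- -ells[[e]]$normal
  ## Spine-local frame.
  zax <- h[1, ] / hlen[1]
  xraw <- ells[[1]]$major_dir
  xax <- xraw - sum(xraw * zax) * zax
  if (sqrt(sum(xax^2)) < 1e-9)
    xax <- pick_orthogonal(zax) else xax <- xax / sqrt(sum(xax^2))
  yax <- crossv(zax, xax)
  to_local <- function(vec) c(sum(vec * xax), sum(vec * yax), sum(vec * zax))
  ## Directional features.
  cosphi <- vapply(1:6, function(i)
    sum(h[i, ] * h[i + 1, ]) / (hlen[i] * hlen[i + 1]), numeric(1))
  cosphi <- pmin(1, pmax(-1, cosphi))
  theta <- vapply(2:7, function(i) {
    hl <- to_local(h[i, ]); acos(pmin(1, pmax(-1, hl[3] / hlen[i])))
  }, numeric(1))
  Theta <- numeric(6); Phi <- numeric(6)
  for (e in 1:6) {
    nl <- to_local(ells[[e]]$normal)
    Theta[e] <- acos(pmin(1, pmax(-1, nl[3])))
    Phi[e] <- atan2(nl[2], nl[1])
    if (Phi[e] <= -pi) Phi[e] <- pi
  }
  ## Morphological features.
  Rax <- vapply(ells, `[[`, numeric(1), "R")
  rax <- vapply(ells, `[[`, numeric(1), "r")
  area <- Rax * rax                    # ~ ellipse area / pi
  ratios <- c(phi_24 = area[4] / area[2], phi_26 = area[6] / area[2],
              phi_46 = area[6] / area[4])
  Vr <- numeric(7)
  Vr[1] <- region_volume(c0, ells[[1]], samples_per_ellipse)
  for (i in 2:6) Vr[i] <- region_volume(ells[[i - 1]], ells[[i]],
                                        samples_per_ellipse)
  Vr[7] <- region_volume(ells[[6]], c7, samples_per_ellipse)
  V <- mesh_volume(mesh)
  feats <- setNames(c(hlen, Rax, rax, cosphi, theta, Theta, Phi,
                      ratios, Vr, V), feature_names())
  skel <- structure(list(c0 = c0, ellipses = ells, apex = c7,
                         centroids = cent,
                         frame = rbind(x = xax, y = yax, z = zax)),
                    class = "spine_skeleton")
  structure(list(features = feats, skeleton = skel, alpha = alpha,
                 sum_region_volume = sum(Vr),
                 n_vertices = nrow(mesh$vertices),
                 partition = part), class = "spine_features")
}

pick_orthogonal <- function(z) {
  p <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- p - sum(p * z) * z
  p / sqrt(sum(p^2))
}

#' Extract features for many spines into a matrix
#'
#' @param records list of records from [read_spine_records()], each with a
#'   repaired mesh.
#' @param ... passed to [extract_features()].
#' @return data.frame: `spine_id`, the 54 feature columns, `alpha`,
#'   `n_vertices`.
#' @export
extract_feature_table <- function(records, ...) {
  rows <- lapply(records, function(rec) {
    fx <- extract_features(rec$mesh, rec$insertion, ...)
    data.frame(spine_id = rec$spine_id, t(fx$features), alpha = fx$alpha,
               n_vertices = fx$n_vertices, check.names = FALSE)
  })
  do.call(rbind, rows)
}
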