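#' Repair-stage parameters
#'
#' Collects the tunables of the voxel-morphology repair stage. Defaults:
#' isotropic voxel spacing 0.075 um (the in-plane confocal voxel size of
#' the data regime the pipeline targets), spherical closing element of
#' radius 3 voxels, slice-fill Gaussian sigma 1.5 voxels thresholded at
#' 0.5, and 10 curvature-flow iterations of step 0.1.
#'
#' @param voxel_spacing voxel edge length (micrometres).
#' @param closing_radius radius (voxels) of the spherical structuring
#'   element tried first; [repair_fragmentation()] escalates it up to
#'   `max_closing_radius` when fragments remain disconnected.
#' @param max_closing_radius largest closing radius attempted (voxels).
#' @param gaussian_sigma sigma (voxels) of the 2D Gaussian slice filter
#'   used by [reconstruct_neck()].
#' @param fill_threshold occupancy threshold in (0,1) applied after the
#'   slice blur.
#' @param smoothing_iterations,smoothing_step curvature-flow defaults.
#' @param max_gap largest neck gap (voxels) [reconstruct_neck()] will fill.
#' @return a list of class `repair_params`.
#' @export
repair_params <- function(voxel_spacing = 0.075, closing_radius = 3,
                          max_closing_radius = 16, gaussian_sigma = 1.5,
                          fill_threshold = 0.5, smoothing_iterations = 10,
                          smoothing_step = 0.1, max_gap = 100) {
  stopifnot(voxel_spacing > 0, closing_radius > 0,
            max_closing_radius >= closing_radius, gaussian_sigma > 0,
            fill_threshold > 0, fill_threshold < 1,
            smoothing_iterations >= 0, smoothing_step > 0, max_gap > 0)
  structure(list(voxel_spacing = voxel_spacing,
                 closing_radius = closing_radius,
                 max_closing_radius = max_closing_radius,
                 gaussian_sigma = gaussian_sigma,
                 fill_threshold = fill_threshold,
                 smoothing_iterations = smoothing_iterations,
                 smoothing_step = smoothing_step,
                 max_gap = max_gap), class = "repair_params")
}

#' Repair a fragmented spine mesh
#'
#' Joins the closed components of a fragmented spine into a single body:
#' the mesh is voxelized, a morphological closing with a spherical
#' structuring element is applied, and only the added material that
#' actually bridges two or more fragments is retained (so the closing
#' cannot inflate concave regions elsewhere). The repaired surface is
#' re-extracted from the voxel volume. If the fragments are still
#' disconnected, the structuring-element radius is escalated up to
#' `params$max_closing_radius` before giving up.
#'
#' @param mesh a [spine_mesh]; each component must be closed.
#' @param params a [repair_params()] list.
#' @return a single-component watertight [spine_mesh]. Already-connected
#'   meshes still make the voxel round trip, which is near-identity.
#' @export
repair_fragmentation <- function(mesh, params = repair_params()) {
  stopifnot(inherits(mesh, "spine_mesh"))
  grid <- voxelize_mesh(mesh, params$voxel_spacing,
                        pad = as.integer(ceiling(params$max_closing_radius)) + 2L)
  occ <- grid$occ
  comp <- voxel_components(occ)
  if (comp$n > 1L) {
    r <- params$closing_radius
    repeat {
      closed <- binary_close(occ, r)
      occ2 <- bridge_components(occ, closed, comp$labels)
      if (voxel_components(occ2)$n == 1L) { occ <- occ2; break }
      if (r >= params$max_closing_radius) {
        n_left <- voxel_components(occ2)$n
        stop("RepairFailure: ", n_left,
             " components remain after closing at radius ",
             r, " voxels")
      }
      r <- min(params$max_closing_radius, r + max(3, ceiling(r / 2)))
    }
  }
  grid$occ <- occ
  orient_outward(extract_isosurface(grid))
}

## Keep only the closing-added material that bridges two or more original
## components; returns the union of the original occupancy and the bridges.
bridge_components <- function(occ, closed, labels) {
  added <- closed & !occ
  if (!any(added)) return(occ)
  ac <- voxel_components(added)
  ## Which original components does each added blob touch?  Grow the
  ## original labels by one voxel and read them under each blob.
  grown <- labels
  d <- dim(occ)
  for (sh in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                  c(0,0,1), c(0,0,-1))) {
    xs <- max(1, 1 + sh[1]):min(d[1], d[1] + sh[1])
    ys <- max(1, 1 + sh[2]):min(d[2], d[2] + sh[2])
    zs <- max(1, 1 + sh[3]):min(d[3], d[3] + sh[3])
    tgt <- grown[xs, ys, zs]
    src <- labels[xs - sh[1], ys - sh[2], zs - sh[3]]
    tgt[tgt == 0L] <- src[tgt == 0L]
    grown[xs, ys, zs] <- tgt
  }
  out <- occ
  for (b in seq_len(ac$n)) {
    blob <- ac$labels == b
    touched <- unique(grown[blob])
    if (length(setdiff(touched, 0L)) >= 2L) out <- out | blob
  }
  out
}

#' Regrow a detached spine neck toward its insertion point
#'
#' For a spine whose insertion point lies off the mesh surface, the segment
#' from the nearest mesh vertex to the insertion point is aligned with the
#' negative z axis, the mesh is voxelized, and the gap slices are filled
#' iteratively downward: each slice is the 2D-Gaussian-blurred copy of the
#' slice above it, thresholded at `fill_threshold`, with a small anchor
#' disk around the insertion axis added so the regrown base always reaches
#' the insertion point. The surface is re-extracted and returned in the
#' original pose.
#'
#' @param mesh a watertight [spine_mesh].
#' @param insertion numeric 3-vector (micrometres).
#' @param params a [repair_params()] list.
#' @param surface_tol distance below which the insertion point counts as
#'   already attached (micrometres).
#' @return a watertight single-component [spine_mesh] containing the
#'   insertion point within one voxel of its interior. Attached spines are
#'   returned unchanged with a warning.
#' @export
reconstruct_neck <- function(mesh, insertion, params = repair_params(),
                             surface_tol = 2 * params$voxel_spacing) {
  stopifnot(inherits(mesh, "spine_mesh"), length(insertion) == 3)
  d2 <- colSums((t(mesh$vertices) - insertion)^2)
  vi <- which.min(d2)
  gap <- sqrt(d2[vi])
  if (gap <= surface_tol) {
    warning("insertion point already on the surface; nothing to reconstruct")
    return(mesh)
  }
  if (gap / params$voxel_spacing > params$max_gap)
    stop("RepairFailure: gap of ", round(gap / params$voxel_spacing),
         " voxels exceeds max_gap = ", params$max_gap)
  ## Pose: nearest vertex -> insertion along -z, insertion at the origin.
  dir <- insertion - mesh$vertices[vi, ]
  R <- rotation_between(dir / gap, c(0, 0, -1))
  posed <- transform_mesh(mesh, R, -as.vector(R %*% insertion))
  ## Padding must reach below the insertion point (one gap length under
  ## the mesh) plus room for the anchor disk.
  grid <- voxelize_mesh(posed, params$voxel_spacing,
                        pad = as.integer(ceiling(gap / params$voxel_spacing)) + 4L)
  occ <- grid$occ
  zc <- voxel_axis(grid, 3)
  xc <- voxel_axis(grid, 1); yc <- voxel_axis(grid, 2)
  iz_ins <- which.min(abs(zc - 0))
  per_slice <- apply(occ, 3, sum)
  iz_base <- which(per_slice > 0)[1]          # lowest occupied slice
  if (iz_base <= iz_ins) iz_base <- iz_ins + 1L
  ## The regrown base slices: 2D-Gaussian propagation of the slice above.
  for (k in seq(iz_base - 1L, iz_ins)) {
    above <- gaussian_blur_2d(occ[, , k + 1L] * 1.0, params$gaussian_sigma)
    occ[, , k] <- above >= params$fill_threshold
  }
  ## Anchor column: a 2-voxel disk around the insertion axis (x = y = 0)
  ## from the insertion slice up past the nearest surface vertex, so the
  ## regrown base always reaches both the insertion point and the spine
  ## body even when another part of a bent spine hangs lower.
  axis_d2 <- outer(xc^2, yc^2, `+`)
  anchor <- axis_d2 <= (2 * params$voxel_spacing)^2
  iz_near <- min(dim(occ)[3], which.min(abs(zc - gap)) + 2L)
  for (k in seq(iz_ins, iz_near)) occ[, , k] <- occ[, , k] | anchor
  grid$occ <- occ
  out <- extract_isosurface(grid)
  orient_outward(transform_mesh(out, t(R), insertion))
}

#' Curvature-flow smoothing
#'
#' Explicit cotangent-weighted curvature flow: each iteration moves every
#' vertex by `step` times its normalized mean-curvature (umbrella) vector.
#' Connectivity is unchanged.
#'
#' @param mesh a watertight [spine_mesh].
#' @param iterations number of explicit iterations.
#' @param step step size in (0, 1]; larger values smooth faster but shrink
#'   more.
#' @return a [spine_mesh].
#' @export
smooth_curvature_flow <- function(mesh, iterations = 10, step = 0.1) {
  if (step <= 0) stop("smoothing step must be positive")
  if (iterations == 0) return(mesh)
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(v)
  for (it in seq_len(iterations)) {
    ## Cotangent weights per face corner.
    p1 <- v[f[, 1], , drop = FALSE]
    p2 <- v[f[, 2], , drop = FALSE]
    p3 <- v[f[, 3], , drop = FALSE]
    cot_at <- function(a, b, c) {  # angle at a, edge (b,c) opposite
      u <- b - a; w <- c - a
      cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                  u[, 3] * w[, 1] - u[, 1] * w[, 3],
                  u[, 1] * w[, 2] - u[, 2] * w[, 1])
      dn <- sqrt(rowSums(cr^2))
      pmax(rowSums(u * w), 0) / pmax(dn, 1e-12)  # clamp obtuse to 0
    }
    w3 <- cot_at(p3, p1, p2)  # opposite edge (v1,v2)
    w1 <- cot_at(p1, p2, p3)  # opposite edge (v2,v3)
    w2 <- cot_at(p2, p3, p1)  # opposite edge (v3,v1)
    ii <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
    jj <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
    ww <- c(w3, w3, w1, w1, w2, w2)
    wsum <- as.vector(rowsum(ww, ii, reorder = TRUE))
    lap <- rowsum(v[jj, , drop = FALSE] * ww, ii, reorder = TRUE) /
      pmax(wsum, 1e-12) - v
    v <- v + step * lap
  }
  mesh$vertices <- v
  mesh
}

#' Accept or reject a repaired spine
#'
#' Operationalizes the discard rules for spines whose repair deformed them
#' too much: the repaired/original volume ratio must stay inside
#' `[1/max_volume_ratio_change, max_volume_ratio_change]` and the repaired
#' mesh may have at most `max_components` components.
#'
#' @param original,repaired watertight [spine_mesh] objects.
#' @param max_volume_ratio_change largest tolerated volume ratio (> 1).
#' @param max_components largest tolerated component count.
#' @return list with `accepted` (logical) and `reasons` (character vector,
#'   empty when accepted; subset of `"volume_change"`, `"fragmentation"`).
#' @export
quality_gate <- function(original, repaired, max_volume_ratio_change = 1.5,
                         max_components = 1) {
  stopifnot(max_volume_ratio_change >= 1)
  reasons <- character(0)
  vr <- mesh_volume(repaired) / mesh_volume(original)
  if (vr > max_volume_ratio_change || vr < 1 / max_volume_ratio_change)
    reasons <- c(reasons, "volume_change")
  if (validate_mesh(repaired)$n_components > max_components)
    reasons <- c(reasons, "fragmentation")
  list(accepted = length(reasons) == 0, reasons = reasons,
       volume_ratio = vr)
}

#' Repair one spine record end to end
#'
#' Dispatcher used by the pipeline: closes fragmentation if present,
#' regrows the neck if the insertion point is detached, smooths with
#' curvature flow, and applies the quality gate.
#'
#' @param record a record as produced by [read_spine_records()].
#' @param params a [repair_params()] list.
#' @param detach_tol surface tolerance for the detachment test
#'   (micrometres).
#' @return list with `mesh`, `action` (`"none"`, `"closed"`,
#'   `"neck_grown"`, or both), `accepted`, `reasons`, `volume_before`,
#'   `volume_after`.
#' @export
repair_spine <- function(record, params = repair_params(),
                         detach_tol = 2 * params$voxel_spacing) {
  mesh <- record$mesh
  v_before <- mesh_volume(mesh)
  action <- character(0)
  rep0 <- validate_mesh(mesh)
  if (rep0$n_components > 1L) {
    mesh <- repair_fragmentation(mesh, params)
    action <- c(action, "closed")
  }
  d <- sqrt(min(colSums((t(mesh$vertices) - record$insertion)^2)))
  if (d > detach_tol) {
    mesh <- reconstruct_neck(mesh, record$insertion, params,
                             surface_tol = detach_tol)
    action <- c(action, "neck_grown")
  }
  if (params$smoothing_iterations > 0)
    mesh <- smooth_curvature_flow(mesh, params$smoothing_iterations,
                                  params$smoothing_step)
  gate <- quality_gate(record$mesh, mesh)
  list(mesh = mesh, action = if (length(action)) paste(action, collapse = "+")
       else "none",
       accepted = gate$accepted, reasons = gate$reasons,
       volume_before = v_before, volume_after = mesh_volume(mesh))
}
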