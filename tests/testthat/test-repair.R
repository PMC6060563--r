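test_that("voxelize + isosurface recovers a sphere's volume within 5%", {
  r <- 10 * 0.075
  sph <- mesh_icosphere(3, radius = r)
  grid <- voxelize_mesh(sph, 0.075)
  out <- extract_isosurface(grid)
  val <- validate_mesh(out)
  expect_true(val$watertight)
  expect_equal(val$n_components, 1)
  expect_lt(abs(mesh_volume(out) / (4 / 3 * pi * r^3) - 1), 0.05)
})

test_that("closing repairs a fragmented spine into one watertight body", {
  sp <- make_synthetic_spine(spine_spec("straight_tube"), seed = 3)
  cor <- corrupt_mesh(sp$mesh, "fragment", 0.3, sp$insertion)
  expect_equal(validate_mesh(cor$mesh)$n_components, 2)
  fixed <- repair_fragmentation(cor$mesh, repair_params())
  val <- validate_mesh(fixed)
  expect_equal(val$n_components, 1)
  expect_true(val$watertight)
  ## Near-identity on an already-connected solid: volume change <= 5%.
  solid <- repair_fragmentation(sp$mesh, repair_params())
  expect_lt(abs(mesh_volume(solid) / mesh_volume(sp$mesh) - 1), 0.05)
  ## Idempotence up to re-extraction tolerance.
  again <- repair_fragmentation(fixed, repair_params())
  expect_lt(abs(mesh_volume(again) / mesh_volume(fixed) - 1), 0.01)
})

test_that("components beyond closing reach fail with a residual count", {
  r <- 6 * 0.075
  a <- mesh_icosphere(2, radius = r)
  b <- mesh_icosphere(2, radius = r, center = c(0, 0, 2 * r + 20 * 0.075))
  both <- spine_mesh(rbind(a$vertices, b$vertices),
                     rbind(a$faces, b$faces + nrow(a$vertices)))
  p <- repair_params(closing_radius = 2, max_closing_radius = 2)
  expect_error(repair_fragmentation(both, p), "RepairFailure: 2 components")
})

test_that("the 2D Gaussian slice filter matches direct convolution", {
  set.seed(4)
  m <- matrix(runif(30 * 28) > 0.6, 30, 28) * 1.0
  sig <- 1.5
  r <- ceiling(3 * sig)
  k1 <- exp(-((-r:r)^2) / (2 * sig^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  brute <- matrix(0, 30, 28)
  for (i in 1:30) for (j in 1:28) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 30 && jj >= 1 && jj <= 28)
        acc <- acc + K[di + r + 1, dj + r + 1] * m[ii, jj]
    }
    brute[i, j] <- acc
  }
  expect_lt(max(abs(spinemorph:::gaussian_blur_2d(m, sig) - brute)), 1e-12)
})

test_that("neck reconstruction regrows down to the insertion point", {
  sp <- make_synthetic_spine(spine_spec("mushroom_like"), seed = 5)
  cor <- corrupt_mesh(sp$mesh, "detach", 0.4, sp$insertion)
  d_before <- sqrt(min(colSums((t(cor$mesh$vertices) - cor$insertion)^2)))
  expect_gt(d_before, 0.3)
  p <- repair_params()
  out <- reconstruct_neck(cor$mesh, cor$insertion, p)
  val <- validate_mesh(out)
  expect_true(val$watertight)
  expect_equal(val$n_components, 1)
  ## Insertion point within one voxel of the regrown surface.
  d_after <- sqrt(min(colSums((t(out$vertices) - cor$insertion)^2)))
  expect_lt(d_after, 2 * p$voxel_spacing)
  ## Filled slice areas never grow while descending: the regrown base is
  ## monotone under the blur-threshold rule.
  grid <- voxelize_mesh(out, p$voxel_spacing, pad = 4L)
  zc <- spinemorph:::voxel_axis(grid, 3)
  below <- which(zc < min(cor$mesh$vertices[, 3]) - p$voxel_spacing &
                 zc > cor$insertion[3] + p$voxel_spacing)
  areas <- apply(grid$occ[, , below, drop = FALSE], 3, sum)
  expect_true(all(diff(areas) >= -2))  # descending slices shrink
})

test_that("neck reconstruction guards its no-op and max-gap edges", {
  sp <- make_synthetic_spine(spine_spec("stubby"), seed = 6)
  expect_warning(out <- reconstruct_neck(sp$mesh, sp$insertion),
                 "already on the surface")
  expect_identical(out, sp$mesh)
  far <- sp$insertion - c(0, 0, 30)
  expect_error(reconstruct_neck(sp$mesh, far,
                                repair_params(max_gap = 100)),
               "max_gap")
})

test_that("curvature flow smooths noise and preserves connectivity", {
  sph <- mesh_icosphere(3, radius = 10)
  set.seed(7)
  noisy <- sph
  radial <- noisy$vertices / 10
  noisy$vertices <- noisy$vertices + radial * rnorm(nrow(radial), 0, 0.3)
  sd_before <- sd(sqrt(rowSums(noisy$vertices^2)))
  out <- smooth_curvature_flow(noisy, 10, 0.1)
  expect_identical(out$faces, noisy$faces)
  sd_after <- sd(sqrt(rowSums(out$vertices^2)))
  expect_lt(sd_after, sd_before)
  ## Volume change under default smoothing stays under 10%.
  expect_lt(abs(mesh_volume(out) / mesh_volume(noisy) - 1), 0.10)
  expect_identical(smooth_curvature_flow(sph, 0, 0.1), sph)
  expect_error(smooth_curvature_flow(sph, 5, -1), "positive")
  ## Per-iteration displacement is bounded by step times the local span.
  one <- smooth_curvature_flow(sph, 1, 0.1)
  disp <- sqrt(rowSums((one$vertices - sph$vertices)^2))
  ed <- spinemorph:::mesh_edges(sph)
  span <- max(sqrt(rowSums((sph$vertices[ed[, 1], ] -
                            sph$vertices[ed[, 2], ])^2)))
  expect_lt(max(disp), 0.1 * span)
})

test_that("the quality gate enumerates every violated rule", {
  sph <- mesh_icosphere(2)
  ok <- quality_gate(sph, sph)
  expect_true(ok$accepted)
  expect_length(ok$reasons, 0)
  big <- sph; big$vertices <- big$vertices * 3^(1 / 3)
  verdict <- quality_gate(sph, big, max_volume_ratio_change = 1.5)
  expect_false(verdict$accepted)
  expect_equal(verdict$reasons, "volume_change")
  two <- spine_mesh(rbind(sph$vertices, sph$vertices + 5),
                    rbind(sph$faces, sph$faces + nrow(sph$vertices)))
  verdict <- quality_gate(sph, two, max_volume_ratio_change = 10,
                          max_components = 1)
  expect_false(verdict$accepted)
  expect_equal(verdict$reasons, "fragmentation")
})
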