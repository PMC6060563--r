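test_that("feature sampling respects the component distribution", {
  pop <- small_population()
  model <- pop$model
  expect_equal(nrow(sample_features(model, 1, 0)), 0L)
  ## Delta limit: vanishing covariance reproduces the mean.
  degen <- model
  degen$covariances <- lapply(degen$covariances, function(S) S * 1e-18)
  x <- sample_features(degen, 2, 5, seed = 41)
  expect_lt(max(abs(sweep(x, 2, model$means[2, ]))), 1e-6)
  ## Monte-Carlo mean bound: sample mean within 3 SE per coordinate
  ## (boundary-truncated angle coordinates excluded: rejection shifts
  ## them by design).
  x <- sample_features(model, 1, 1000, seed = 42)
  se <- sqrt(diag(model$covariances[[1]])) / sqrt(1000)
  dev <- abs(colMeans(x) - model$means[1, ])
  untrunc <- morphological_features()
  expect_true(all(dev[untrunc] <= 3.5 * se[match(untrunc,
                                                 feature_names())]))
  ## Determinism.
  expect_identical(sample_features(model, 1, 10, seed = 7),
                   sample_features(model, 1, 10, seed = 7))
})

test_that("build_skeleton inverts the angle conventions", {
  f <- spinemorph:::spine_feature_template()
  ## Straight spine: unit heights, circles.
  fs <- f
  fs[paste0("h", 1:7)] <- 1
  fs[paste0("cos_phi", 1:6)] <- 1
  fs[paste0("theta", 2:7)] <- 0
  fs[paste0("Theta", 1:6)] <- 0
  sk <- build_skeleton(fs)
  expect_equal(sk$centroids[, 1:2], matrix(0, 8, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sk$centroids[, 3], 0:7, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sk$apex, c(0, 0, 7), tolerance = 1e-9)
  ## Bent spine: chain lengths and consecutive cosines reproduce exactly.
  sk2 <- build_skeleton(f)
  h <- diff(sk2$centroids)
  hl <- sqrt(rowSums(h^2))
  expect_equal(unname(hl), unname(f[paste0("h", 1:7)]), tolerance = 1e-9)
  cphi <- vapply(1:6, function(i)
    sum(h[i, ] * h[i + 1, ]) / (hl[i] * hl[i + 1]), numeric(1))
  expect_equal(cphi, unname(f[paste0("cos_phi", 1:6)]), tolerance = 1e-6)
  ## Inconsistent angle pair is refused.
  bad <- f
  bad["theta2"] <- 1.2
  bad["cos_phi1"] <- 0.999
  expect_error(build_skeleton(bad), "SkeletonError")
})

test_that("surfacing produces closed genus-0 meshes with the stated counts", {
  f <- spinemorph:::spine_feature_template()
  sk <- build_skeleton(f)
  cfg <- simulation_config(points_per_ellipse = 32, subdivision_iterations = 0)
  m0 <- surface_skeleton(sk, cfg, band_subs = 0L, cap_subs = 0L)
  ## 6 rings of 32 + 2 poles; each band 64 triangles, caps 32 each.
  expect_equal(nrow(m0$vertices), 6 * 32 + 2)
  expect_equal(nrow(m0$faces), 5 * 64 + 2 * 32)
  val <- validate_mesh(m0)
  expect_true(val$watertight)
  expect_equal(val$n_components, 1)
  euler <- function(m) nrow(m$vertices) -
    nrow(spinemorph:::mesh_edges(m)) + nrow(m$faces)
  expect_equal(euler(m0), 2)
  expect_gt(mesh_volume(m0), 0)
  ## Straight circular skeleton volume ~ frustum sum.
  fs <- f
  fs[paste0("h", 1:7)] <- 0.5
  fs[paste0("cos_phi", 1:6)] <- 1
  fs[paste0("theta", 2:7)] <- 0
  fs[paste0("Theta", 1:6)] <- 0
  fs[paste0("R", 1:6)] <- 0.3
  fs[paste0("r", 1:6)] <- 0.3
  tube <- surface_skeleton(build_skeleton(fs),
                           simulation_config(64, 0), band_subs = 0L,
                           cap_subs = 0L)
  frusta <- 5 * 0.5 * pi * 0.3^2 + 2 * (0.5 * pi * 0.3^2 / 3)
  expect_lt(abs(mesh_volume(tube) / frusta - 1), 0.05)
})

test_that("Loop subdivision has exact combinatorics and smooths", {
  ico <- mesh_icosphere(0)
  expect_identical(loop_subdivide(ico, 0), ico)
  one <- loop_subdivide(ico, 1)
  E <- nrow(spinemorph:::mesh_edges(ico))
  expect_equal(nrow(one$faces), 4 * nrow(ico$faces))
  expect_equal(nrow(one$vertices), nrow(ico$vertices) + E)
  expect_true(validate_mesh(one)$watertight)
  ## Convergence to the smooth limit surface: the update applied to the
  ## original vertices shrinks geometrically with each round, and the
  ## radius spread of a once-subdivided icosahedron keeps tightening.
  m <- loop_subdivide(ico, 1)
  cv <- function(m) {
    r <- sqrt(rowSums(m$vertices^2)); sd(r) / mean(r)
  }
  moves <- numeric(0); cvs <- cv(m)
  for (k in 1:3) {
    nxt <- loop_subdivide(m, 1)
    moves <- c(moves, max(sqrt(rowSums(
      (nxt$vertices[seq_len(nrow(m$vertices)), ] - m$vertices)^2))))
    m <- nxt
    cvs <- c(cvs, cv(m))
  }
  expect_true(all(diff(moves) < 0))
  expect_true(all(diff(cvs) < 0))
  holed <- spine_mesh(ico$vertices, ico$faces[-1, ])
  expect_error(loop_subdivide(holed, 1), "watertight")
})

test_that("simulated meshes are deterministic, closed and genus 0", {
  pop <- small_population()
  cfg <- simulation_config(seed = 9)
  s1 <- simulate_spines(pop$model, 1, 2, cfg)
  s2 <- simulate_spines(pop$model, 1, 2, cfg)
  expect_identical(s1$features, s2$features)
  expect_identical(s1$meshes[[1]]$vertices, s2$meshes[[1]]$vertices)
  for (m in s1$meshes) {
    val <- validate_mesh(m)
    expect_true(val$watertight)
    expect_equal(val$n_components, 1)
    expect_equal(nrow(m$vertices) -
                 nrow(spinemorph:::mesh_edges(m)) + nrow(m$faces), 2)
    expect_gt(mesh_volume(m), 0)
  }
})

test_that("the realism score calibrates against its limits", {
  pop <- small_population()
  X <- pop$X[pop$labels == 1, ]
  ## Identical rows: indistinguishable by construction.
  r0 <- realism_score(X, X, folds = 10, seed = 1)
  expect_length(r0$fold_accuracy, 10)
  expect_lt(abs(r0$accuracy - 0.5), 0.1)
  ## A 10-pooled-sd shift in one column is trivially separable.
  shifted <- X
  shifted[, "h1"] <- shifted[, "h1"] + 10 * sd(X[, "h1"])
  ## Brute-force single-threshold oracle confirms separability.
  thr <- (max(X[, "h1"]) + min(shifted[, "h1"])) / 2
  expect_true(all(X[, "h1"] < thr) && all(shifted[, "h1"] > thr))
  r1 <- realism_score(X, shifted, folds = 10, seed = 1)
  expect_gte(r1$accuracy, 0.95)
  expect_error(realism_score(X[1:3, ], X[1:3, ], folds = 10), "folds")
})
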