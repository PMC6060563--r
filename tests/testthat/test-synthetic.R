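test_that("synthetic spines are watertight with oracle cross-sections", {
  for (prof in c("mushroom_like", "thin", "stubby", "straight_tube")) {
    sp <- make_synthetic_spine(spine_spec(prof), seed = 51)
    val <- validate_mesh(sp$mesh)
    expect_true(val$watertight)
    expect_equal(val$n_components, 1)
  }
  ## Straight tube: every internal boundary loop is a circle of the stated
  ## radius.
  sp <- make_synthetic_spine(spine_spec("straight_tube", neck_radius = 0.25))
  fx <- extract_features(sp$mesh, sp$insertion)
  interior <- paste0("R", 2:5)
  expect_true(all(abs(fx$features[interior] / 0.25 - 1) < 0.05))
  expect_true(all(abs(fx$features[paste0("r", 2:5)] / 0.25 - 1) < 0.05))
  ## Mushroom: distal radii dominate proximal ones.
  spm <- make_synthetic_spine(spine_spec("mushroom_like",
                                         neck_radius = 0.12,
                                         head_radius = 0.36))
  fm <- extract_features(spm$mesh, spm$insertion)$features
  expect_gt(unname(fm["R5"]), 2 * unname(fm["R1"]))
  expect_error(spine_spec("thin", head_radius = 0.05, neck_radius = 0.2),
               "spec error")
})

test_that("corruption operators produce the advertised defects", {
  sp <- make_synthetic_spine(spine_spec("straight_tube"), seed = 52)
  frag <- corrupt_mesh(sp$mesh, "fragment", 0.5, sp$insertion)
  expect_equal(validate_mesh(frag$mesh)$n_components, 2)
  for (piece in spinemorph:::split_components(frag$mesh))
    expect_true(validate_mesh(piece)$watertight)
  det <- corrupt_mesh(sp$mesh, "detach", 1.0, sp$insertion)
  expect_equal(validate_mesh(det$mesh)$n_components, 1)
  d <- sqrt(min(colSums((t(det$mesh$vertices) - det$insertion)^2)))
  expect_lt(abs(d - 1.0), 0.15)
  same <- corrupt_mesh(sp$mesh, "fragment", 0, sp$insertion)
  expect_identical(same$mesh, sp$mesh)
  expect_error(corrupt_mesh(sp$mesh, "fragment", 10, sp$insertion),
               "half the spine extent")
})

test_that("the feature population has known parameters and is reproducible", {
  pop1 <- sample_feature_population(1, 150, seed = 53)
  expect_true(all(pop1$labels == 1))
  se <- sqrt(diag(pop1$model$covariances[[1]])) / sqrt(150)
  dev <- abs(colMeans(pop1$X) - pop1$model$means[1, ])
  morph <- morphological_features()
  expect_true(all(dev[morph] <= 3.5 * se[match(morph, feature_names())]))
  pop2 <- sample_feature_population(1, 150, seed = 53)
  expect_identical(pop1$X, pop2$X)
  expect_warning(sample_feature_population(2, 20, separation = 0, seed = 1),
                 "separation 0")
  ## Every row satisfies the descriptor invariants.
  ok <- apply(pop1$X, 1, function(r)
    isTRUE(spinemorph:::check_feature_vector(r)))
  expect_true(all(ok))
  ## Separation is delivered in whitened units.
  pop3 <- small_population()
  expect_equal(pop3$model$C, 3L)
  expect_length(pop3$model$weights, 3)
})

test_that("repair heals corrupted synthetics across profiles", {
  profiles <- c("mushroom_like", "thin", "stubby", "straight_tube")
  set.seed(54)
  ok <- logical(0)
  for (k in 1:8) {
    prof <- profiles[(k - 1) %% 4 + 1]
    mode <- if (k %% 2 == 0) "fragment" else "detach"
    sp <- make_synthetic_spine(spine_spec(prof), seed = 100 + k,
                               roughness = 0.015)
    ext <- diff(range(sp$mesh$vertices[, 3]))
    mag <- runif(1, 0.2, min(1, 0.4 * ext))
    cor <- corrupt_mesh(sp$mesh, mode, mag, sp$insertion, seed = k)
    res <- tryCatch(repair_spine(list(spine_id = "s", mesh = cor$mesh,
                                      insertion = cor$insertion)),
                    error = function(e) NULL)
    ok <- c(ok, !is.null(res) && res$accepted &&
              validate_mesh(res$mesh)$n_components == 1)
  }
  expect_gte(mean(ok), 7 / 8)
})
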