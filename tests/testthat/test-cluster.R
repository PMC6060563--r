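test_that("BIC keeps one component for single-Gaussian data", {
  set.seed(31)
  X <- matrix(rnorm(500 * 3), 500, 3)
  fit <- fit_mixture(X, C_range = 1:4, seed = 1, n_init = 2)
  expect_equal(fit$C, 1L)
})

test_that("two well-separated 2D Gaussians are recovered", {
  set.seed(32)
  X <- rbind(matrix(rnorm(500), 250, 2),
             matrix(rnorm(500, 10), 250, 2))
  fit <- fit_mixture(X, C_range = 1:4, seed = 2, n_init = 3)
  expect_equal(fit$C, 2L)
  mu <- spinemorph:::destandardize(fit, fit$means)
  mu <- mu[order(mu[, 1]), ]
  expect_lt(max(abs(mu - rbind(c(0, 0), c(10, 10)))), 0.2)
  ## EM monotonicity on the winning run.
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  ## BIC curve covers the requested range.
  fit2 <- fit_mixture(X, C_range = 2:10, seed = 2, n_init = 1)
  expect_equal(nrow(fit2$bic_curve), 9L)
  expect_equal(fit2$bic_curve$C, 2:10)
})

test_that("memberships are posterior probabilities with the right limits", {
  model <- structure(list(
    C = 2L, weights = c(0.5, 0.5),
    means = rbind(c(0, 0), c(20, 0)),
    covariances = list(diag(2), diag(2)),
    feature_names = c("a", "b"), standardize = NULL), class = "mixture_model")
  mem <- memberships(model, rbind(c(0, 0), c(10, 0), c(20, 0)))
  expect_equal(rowSums(mem$p), rep(1, 3), tolerance = 1e-9)
  expect_gt(mem$p[1, 1], 0.999)
  expect_equal(mem$p[2, ], c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(mem$label, c(1L, 2L, 2L))
  expect_error(memberships(model, matrix(0, 2, 3)), "dimension mismatch")
  ## Identical components: every point is a coin flip.
  same <- model; same$means <- rbind(c(0, 0), c(0, 0))
  ms <- memberships(same, matrix(rnorm(20), 10, 2))
  expect_equal(ms$p, matrix(0.5, 10, 2), tolerance = 1e-12)
})

test_that("threshold counts grow as the threshold drops", {
  pop <- small_population()
  fit <- fit_mixture(pop$X, C_range = 3, seed = 3, n_init = 1,
                     covariance = "diagonal")
  mem <- memberships(fit, pop$X)
  tab <- membership_threshold_table(mem)
  expect_equal(tab$threshold, c(0.99, 0.9, 0.8, 0.7, 0.6, 0.5))
  expect_true(all(diff(tab$total) >= 0))
  brute <- sum(mem$p_star > 0.9)
  expect_equal(tab$total[tab$threshold == 0.9], brute)
})

test_that("the log-variance summary matches closed forms and dense determinants", {
  model <- structure(list(covariances = list(diag(4), diag(10, 2))),
                     class = "mixture_model")
  expect_equal(cluster_variance_summary(model), c(0, 2), tolerance = 1e-12)
  set.seed(33)
  A <- crossprod(matrix(rnorm(25), 5))
  m2 <- structure(list(covariances = list(A)), class = "mixture_model")
  expect_equal(cluster_variance_summary(m2),
               abs(log10(det(A))), tolerance = 1e-8)
  bad <- structure(list(covariances = list(diag(c(1, -1)))),
                   class = "mixture_model")
  expect_error(cluster_variance_summary(bad), "positive definite")
})

test_that("Bhattacharyya distance matches its closed forms", {
  expect_equal(bhattacharyya_distance(c(0, 0), diag(2), c(0, 0), diag(2)), 0)
  expect_equal(bhattacharyya_distance(0, matrix(1), 2, matrix(1)), 0.5,
               tolerance = 1e-12)
  expect_equal(bhattacharyya_distance(0, matrix(1), 0, matrix(4)),
               0.5 * log(2.5 / 2), tolerance = 1e-12)
  a <- bhattacharyya_distance(c(1, 2), diag(2), c(3, -1), 2 * diag(2))
  b <- bhattacharyya_distance(c(3, -1), 2 * diag(2), c(1, 2), diag(2))
  expect_equal(a, b)
  expect_error(bhattacharyya_distance(0, matrix(1), c(1, 2), diag(2)),
               "dimension mismatch")
})

test_that("classical MDS reproduces Euclidean-realizable distances", {
  D <- as.matrix(dist(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))))
  Y <- embed_mds(D, 2)
  expect_equal(as.matrix(dist(Y)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  Y2 <- embed_mds(matrix(c(0, 5, 5, 0), 2), 2)
  expect_equal(as.numeric(dist(Y2)), 5, tolerance = 1e-9)
  Y0 <- embed_mds(matrix(0, 3, 3), 2)
  expect_true(all(Y0 == 0))
  expect_error(embed_mds(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("overlap estimates match the analytic likelihood-ratio boundary", {
  m1 <- structure(list(C = 2L, weights = c(0.5, 0.5),
                       means = rbind(0, 2),
                       covariances = list(matrix(1), matrix(1)),
                       standardize = NULL), class = "mixture_model")
  o <- overlap_probability(m1, 1, 2, n_samples = 1e5, seed = 5)
  expect_lt(abs(o$omega - (1 - pnorm(1))), 0.01)
  expect_lte(o$std_error, 0.5 / sqrt(1e5))
  ## Unequal priors shift the boundary to 1 + ln(9)/2.
  m2 <- m1; m2$weights <- c(0.9, 0.1)
  o2 <- overlap_probability(m2, 1, 2, n_samples = 1e5, seed = 6)
  expect_lt(abs(o2$omega - (1 - pnorm(1 + log(9) / 2))), 0.01)
  ## Separation limit.
  m3 <- m1; m3$means <- rbind(0, 40)
  o3 <- overlap_probability(m3, 1, 2, n_samples = 1e5, seed = 7)
  expect_lte(o3$omega, 0.001)
  expect_error(overlap_probability(m1, 1, 1, 1e4), "distinct")
  expect_error(overlap_probability(m1, 1, 2, 50), "at least 100")
  ## Asymmetry is tolerated: both directions valid probabilities.
  W <- overlap_matrix(m2, n_samples = 2000, seed = 8)
  expect_true(all(W >= 0 & W <= 1))
})

test_that("label permutation leaves the model summaries unchanged", {
  pop <- small_population()
  fit <- fit_mixture(pop$X, C_range = 3, seed = 4, n_init = 1,
                     covariance = "diagonal")
  perm <- c(3L, 1L, 2L)
  pfit <- fit
  pfit$weights <- fit$weights[perm]
  pfit$means <- fit$means[perm, ]
  pfit$covariances <- fit$covariances[perm]
  D0 <- cluster_distance_matrix(fit)
  D1 <- cluster_distance_matrix(pfit)
  expect_equal(D1, D0[perm, perm], tolerance = 1e-12)
  m0 <- memberships(fit, pop$X)
  m1 <- memberships(pfit, pop$X)
  expect_equal(m1$p, m0$p[, perm], tolerance = 1e-12)
  expect_equal(sort(unname(cluster_variance_summary(pfit))),
               sort(unname(cluster_variance_summary(fit))))
})

test_that("chi-squared contingency tests match hand computation", {
  r1 <- crosstab_chi2(rep(1:2, each = 50), rep(rep(c("a", "b"), each = 25), 2))
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 1)
  lab <- rep(1:2, c(30, 30))
  grp <- c(rep("a", 10), rep("b", 20), rep("a", 20), rep("b", 10))
  r2 <- crosstab_chi2(lab, grp)
  expect_equal(r2$statistic, 20 / 3, tolerance = 1e-12)  # sum (O-E)^2/E, E=15
  expect_equal(r2$df, 1)
  lab3 <- rep(1:3, each = 20)
  r3 <- crosstab_chi2(lab3, rep(c("a", "b"), 30), per_cluster = TRUE)
  expect_length(r3, 3)
  expect_error(crosstab_chi2(rep(1, 10), rep("a", 10)), "at least 2")
})
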