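#' Fit a Gaussian mixture with BIC model selection
#'
#' Fits full-covariance Gaussian mixtures by expectation-maximization for
#' every component count in `C_range`, each from `n_init` distinct
#' k-means++-seeded initializations, and returns the model maximizing
#' `BIC = 2 logL - n_params log(n)` (higher is better). Columns are
#' z-scored before fitting by default; the standardization is stored in
#' the model so sampling and membership evaluation are transparent to the
#' caller.
#'
#' @param X numeric matrix `n x d` (rows = spines, columns = features).
#' @param C_range integer vector of component counts to try.
#' @param seed integer seed.
#' @param n_init EM restarts per component count.
#' @param reg ridge added to covariance diagonals (in standardized units).
#' @param standardize z-score the columns before fitting.
#' @param covariance component covariance structure: `"full"`
#'   (unconstrained, the default), `"diagonal"`, or `"tied"` (one full
#'   covariance shared by all components). At 54 dimensions the BIC
#'   penalty of a full covariance is ~1500 parameters per component, so
#'   thousands of spines per cluster are needed before BIC will split;
#'   the diagonal structure is the practical choice for modest samples.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` or after `max_iter` iterations.
#' @return a `mixture_model`: `C`, `weights`, `means` (`C x d`, original
#'   units of the standardized space in which the fit ran), `covariances`
#'   (list of `d x d`), `log_likelihood`, `n_params`, `bic`, `bic_curve`
#'   (data.frame over `C_range`), `feature_names`, `standardize`
#'   (`center`/`scale` or `NULL`), `loglik_trace` of the winning run.
#' @export
fit_mixture <- function(X, C_range = 2:10, seed = 1L, n_init = 10L,
                        reg = 1e-6, standardize = TRUE,
                        covariance = c("full", "diagonal", "tied"),
                        max_iter = 500L, tol = 1e-6) {
  covariance <- match.arg(covariance)
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (anyNA(X)) stop("X contains missing values")
  if (n <= 2 * max(C_range))
    stop("too few rows (", n, ") for up to ", max(C_range), " components")
  std <- NULL
  if (standardize) {
    ctr <- colMeans(X); scl <- apply(X, 2, sd)
    scl[scl < 1e-12] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    std <- list(center = ctr, scale = scl)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  best <- NULL
  curve <- data.frame(C = C_range, bic = NA_real_,
                      log_likelihood = NA_real_)
  for (ci in seq_along(C_range)) {
    C <- C_range[ci]
    best_ll <- -Inf; best_fit <- NULL
    for (init in seq_len(n_init)) {
      set.seed(seed * 1000L + C * 37L + init)
      fit <- tryCatch(em_gaussian(X, C, reg, max_iter, tol, covariance),
                      error = function(e) NULL)
      if (!is.null(fit) && fit$log_likelihood > best_ll) {
        best_ll <- fit$log_likelihood; best_fit <- fit
      }
    }
    if (is.null(best_fit)) next
    k <- (C - 1) + C * d + switch(covariance,
      full = C * d * (d + 1) / 2,
      diagonal = C * d,
      tied = d * (d + 1) / 2)
    bic <- 2 * best_fit$log_likelihood - k * log(n)
    curve$bic[ci] <- bic
    curve$log_likelihood[ci] <- best_fit$log_likelihood
    if (is.null(best) || bic > best$bic)
      best <- c(best_fit, list(bic = bic, n_params = k, C = C))
  }
  if (is.null(best)) stop("EM failed for every component count; ",
                          "try reg > 0 or fewer components")
  structure(list(C = best$C, weights = best$weights, means = best$means,
                 covariances = best$covariances,
                 log_likelihood = best$log_likelihood,
                 n_params = best$n_params, bic = best$bic,
                 bic_curve = curve,
                 feature_names = colnames(X),
                 covariance_type = covariance,
                 standardize = std,
                 loglik_trace = best$trace,
                 n = n), class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture: C = %d components, d = %d, n = %d\n",
              x$C, ncol(x$means), x$n))
  cat(sprintf("  logL = %.2f, BIC = %.2f (higher is better)\n",
              x$log_likelihood, x$bic))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

## One EM run from a k-means++ initialization (uses the current RNG state).
em_gaussian <- function(X, C, reg, max_iter, tol,
                        covariance = "full") {
  n <- nrow(X); d <- ncol(X)
  centers <- kmeanspp_centers(X, C)
  km <- suppressWarnings(kmeans(X, centers = centers, iter.max = 20))
  resp <- matrix(1e-8, n, C)
  resp[cbind(seq_len(n), km$cluster)] <- 1
  resp <- resp / rowSums(resp)
  ll_old <- -Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    ## M step.
    nk <- colSums(resp)
    ## Starvation guard: a full covariance needs at least d + 2 effective
    ## points or EM collapses onto degenerate spikes.
    min_nk <- if (covariance == "diagonal") 3 else d + 2
    if (any(nk < min_nk)) stop("component starved")
    w <- nk / n
    means <- crossprod(resp, X) / nk
    covs <- vector("list", C)
    for (c_ in seq_len(C)) {
      Xc <- sweep(X, 2, means[c_, ])
      if (covariance == "diagonal") {
        v <- colSums(Xc^2 * resp[, c_]) / nk[c_]
        covs[[c_]] <- diag(v + reg, d)
      } else {
        S <- crossprod(Xc * sqrt(resp[, c_])) / nk[c_]
        covs[[c_]] <- S + diag(reg, d)
      }
    }
    if (covariance == "tied") {
      pooled <- Reduce(`+`, lapply(seq_len(C), function(c_)
        covs[[c_]] * nk[c_])) / n
      covs <- rep(list(pooled), C)
    }
    ## E step.
    logdens <- matrix(0, n, C)
    for (c_ in seq_len(C)) {
      U <- chol(covs[[c_]])
      Z <- forwardsolve(t(U), t(sweep(X, 2, means[c_, ])))
      logdens[, c_] <- -0.5 * colSums(Z^2) - sum(log(diag(U))) -
        d / 2 * log(2 * pi) + log(w[c_])
    }
    mx <- apply(logdens, 1, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    ll <- sum(lse)
    resp <- exp(logdens - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(weights = w, means = means, covariances = covs,
       log_likelihood = ll, trace = trace)
}

## k-means++ seeding on the current RNG stream.
kmeanspp_centers <- function(X, C) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1), , drop = FALSE]
  d2 <- colSums((t(X) - centers[1, ])^2)
  while (nrow(centers) < C) {
    p <- d2 / sum(d2)
    nxt <- sample.int(n, 1, prob = p)
    centers <- rbind(centers, X[nxt, , drop = FALSE])
    d2 <- pmin(d2, colSums((t(X) - X[nxt, ])^2))
  }
  centers
}

## Map points into the model's fitting space / back out of it.
standardize_data <- function(model, X) {
  if (is.null(model$standardize)) return(as.matrix(X))
  sweep(sweep(as.matrix(X), 2, model$standardize$center), 2,
        model$standardize$scale, "/")
}

destandardize <- function(model, X) {
  if (is.null(model$standardize)) return(X)
  sweep(sweep(X, 2, model$standardize$scale, "*"), 2,
        -model$standardize$center)
}

#' Posterior cluster memberships
#'
#' Soft assignment of each spine to the mixture components:
#' `p_ic = pi_c N(x_i | mu_c, Sigma_c) / sum_k pi_k N(x_i | mu_k, Sigma_k)`.
#'
#' @param model a `mixture_model`.
#' @param X feature matrix in original units (standardization is applied
#'   internally if the model was fitted on z-scores).
#' @return list of class `membership_matrix`: `p` (`n x C`, rows sum to 1),
#'   `p_star` (row maxima), `label` (hard assignments).
#' @export
memberships <- function(model, X) {
  X <- standardize_data(model, X)
  if (ncol(X) != ncol(model$means))
    stop("feature dimension mismatch: model has ", ncol(model$means),
         " columns, X has ", ncol(X))
  n <- nrow(X); C <- model$C
  logdens <- matrix(0, n, C)
  for (c_ in seq_len(C)) {
    U <- chol(model$covariances[[c_]])
    Z <- forwardsolve(t(U), t(sweep(X, 2, model$means[c_, ])))
    logdens[, c_] <- -0.5 * colSums(Z^2) - sum(log(diag(U))) -
      ncol(X) / 2 * log(2 * pi) + log(model$weights[c_])
  }
  mx <- apply(logdens, 1, max)
  p <- exp(logdens - (mx + log(rowSums(exp(logdens - mx)))))
  structure(list(p = p, p_star = apply(p, 1, max),
                 label = max.col(p)), class = "membership_matrix")
}

#' Count confident assignments at decreasing thresholds
#'
#' For each threshold `t`, the number of spines whose maximum membership
#' probability exceeds `t` — per cluster and in total.
#'
#' @param mem a `membership_matrix`.
#' @param thresholds decreasing probability thresholds.
#' @return data.frame with one row per threshold.
#' @export
membership_threshold_table <- function(mem,
                                       thresholds = c(0.99, 0.9, 0.8, 0.7,
                                                      0.6, 0.5)) {
  C <- ncol(mem$p)
  rows <- lapply(thresholds, function(t) {
    sel <- mem$p_star > t
    counts <- vapply(seq_len(C), function(c_)
      sum(sel & mem$label == c_), integer(1))
    data.frame(threshold = t, t(setNames(counts, paste0("cluster", 1:C))),
               total = sum(sel))
  })
  do.call(rbind, rows)
}

#' Per-cluster generalized variance summary
#'
#' `|log10 det Sigma_c|` for every component, computed through a Cholesky
#' factorization for numerical stability.
#'
#' @param model a `mixture_model`.
#' @return numeric vector of length `C`.
#' @export
cluster_variance_summary <- function(model) {
  vapply(model$covariances, function(S) {
    U <- tryCatch(chol(S), error = function(e)
      stop("covariance is not positive definite"))
    abs(2 * sum(log(diag(U))) / log(10))
  }, numeric(1))
}

#' Bhattacharyya distance between two Gaussians
#'
#' `D_B = (1/8) (mu_a - mu_b)' S^-1 (mu_a - mu_b)
#'        + (1/2) ln( det S / sqrt(det Sa det Sb) )`, with
#' `S = (Sa + Sb) / 2`. Symmetric, nonnegative, zero iff the Gaussians
#' coincide.
#'
#' @param mu_a,mu_b mean vectors.
#' @param sigma_a,sigma_b covariance matrices (positive definite).
#' @return nonnegative scalar.
#' @export
bhattacharyya_distance <- function(mu_a, sigma_a, mu_b, sigma_b) {
  mu_a <- as.numeric(mu_a); mu_b <- as.numeric(mu_b)
  sigma_a <- as.matrix(sigma_a); sigma_b <- as.matrix(sigma_b)
  if (length(mu_a) != length(mu_b) || any(dim(sigma_a) != dim(sigma_b)))
    stop("dimension mismatch between the two Gaussians")
  Sbar <- (sigma_a + sigma_b) / 2
  Ub <- chol(Sbar); Ua <- chol(sigma_a); Uc <- chol(sigma_b)
  dm <- mu_a - mu_b
  z <- forwardsolve(t(Ub), dm)
  ld <- function(U) 2 * sum(log(diag(U)))
  sum(z^2) / 8 + 0.5 * (ld(Ub) - 0.5 * (ld(Ua) + ld(Uc)))
}

#' Pairwise Bhattacharyya distances between mixture components
#'
#' @param model a `mixture_model`.
#' @return symmetric `C x C` matrix with zero diagonal.
#' @export
cluster_distance_matrix <- function(model) {
  C <- model$C
  D <- matrix(0, C, C)
  for (i in seq_len(C - 1)) for (j in (i + 1):C) {
    D[i, j] <- D[j, i] <- bhattacharyya_distance(
      model$means[i, ], model$covariances[[i]],
      model$means[j, ], model$covariances[[j]])
  }
  D
}

#' Classical MDS embedding of a cluster distance matrix
#'
#' Torgerson scaling (double-centred `-D^2/2`, top eigenpairs). For a
#' Euclidean-realizable distance matrix, the embedded pairwise distances
#' reproduce the input.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param dim embedding dimension.
#' @return `nrow(D) x dim` coordinate matrix.
#' @export
embed_mds <- function(D, dim = 2L) {
  D <- as.matrix(D)
  if (any(abs(D - t(D)) > 1e-8) || any(abs(diag(D)) > 1e-12))
    stop("D must be symmetric with zero diagonal")
  if (all(D == 0)) return(matrix(0, nrow(D), dim))
  out <- cmdscale(D, k = min(dim, nrow(D) - 1L), eig = TRUE)
  if (any(out$eig < -1e-6 * max(abs(out$eig))))
    warning("distance matrix is not Euclidean-realizable; ",
            "negative eigenvalues clamped")
  pts <- out$points
  if (ncol(pts) < dim)
    pts <- cbind(pts, matrix(0, nrow(pts), dim - ncol(pts)))
  pts
}

#' Cluster overlap probability
#'
#' Monte-Carlo estimate of
#' `omega_{j|i} = P[ pi_i N(x|mu_i,Sigma_i) < pi_j N(x|mu_j,Sigma_j) ]`
#' for `x` drawn from component `i`: the probability of misclassifying a
#' member of cluster `i` into cluster `j`.
#'
#' @param model a `mixture_model`.
#' @param i,j distinct component indices.
#' @param n_samples Monte-Carlo draws (>= 100).
#' @param seed integer seed.
#' @return list with `omega`, `std_error` (binomial SE), `n_samples`.
#' @export
overlap_probability <- function(model, i, j, n_samples = 1e5, seed = 1L) {
  if (i == j) stop("i and j must name distinct components")
  if (n_samples < 100) stop("n_samples must be at least 100")
  d <- ncol(model$means)
  L <- t(chol(model$covariances[[i]]))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  X <- t(model$means[i, ] + L %*% matrix(rnorm(n_samples * d), d))
  logd <- function(c_) {
    U <- chol(model$covariances[[c_]])
    Z <- forwardsolve(t(U), t(sweep(X, 2, model$means[c_, ])))
    -0.5 * colSums(Z^2) - sum(log(diag(U))) + log(model$weights[c_])
  }
  mis <- logd(i) < logd(j)           # strict: ties count as retained
  omega <- mean(mis)
  list(omega = omega, std_error = sqrt(omega * (1 - omega) / n_samples),
       n_samples = n_samples)
}

#' Pairwise overlap matrix
#'
#' @param model a `mixture_model`.
#' @param n_samples,seed see [overlap_probability()].
#' @return `C x C` matrix with `omega_{j|i}` in row `i`, column `j`.
#' @export
overlap_matrix <- function(model, n_samples = 1e4, seed = 1L) {
  C <- model$C
  W <- matrix(0, C, C)
  for (i in seq_len(C)) for (j in seq_len(C)) if (i != j)
    W[i, j] <- overlap_probability(model, i, j, n_samples,
                                   seed + i * 101L + j)$omega
  W
}

#' Contingency test of cluster membership against a grouping
#'
#' Pearson chi-squared test of independence between hard cluster labels
#' and a categorical covariate (dendritic compartment, age group, ...),
#' either on the full `C x g` table or cluster-by-cluster (each cluster
#' against the rest, one 2 x g table per cluster).
#'
#' @param labels integer/factor cluster labels.
#' @param groups categorical covariate, same length.
#' @param per_cluster if `TRUE`, run one cluster-vs-rest test per cluster.
#' @return for the joint test: list with `table`, `statistic`, `df`,
#'   `p_value`, `warning_low_expected`; for `per_cluster = TRUE`, a list of
#'   such lists, one per cluster.
#' @export
crosstab_chi2 <- function(labels, groups, per_cluster = FALSE) {
  labels <- as.factor(labels); groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (nlevels(labels) < 2) stop("need at least 2 clusters")
  one_test <- function(lab) {
    tab <- table(lab, groups)
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(table = tab, statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value,
         warning_low_expected = any(ht$expected < 5))
  }
  if (!per_cluster) return(one_test(labels))
  res <- lapply(levels(labels), function(cl)
    one_test(factor(ifelse(labels == cl, cl, "rest"),
                    levels = c(cl, "rest"))))
  names(res) <- levels(labels)
  res
}
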