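#' Serialize a fitted mixture model to JSON
#'
#' Plain-text serialization (weights, means, row-major covariances,
#' feature names, standardization) so fitted models travel between the
#' cluster and simulate stages and across sessions.
#'
#' @param model a `mixture_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mixture_model <- function(model, path) {
  obj <- list(C = model$C, weights = model$weights,
              means = model$means,
              covariances = lapply(model$covariances, function(S)
                as.vector(t(S))),
              dim = ncol(model$means),
              log_likelihood = model$log_likelihood,
              n_params = model$n_params, bic = model$bic,
              covariance_type = model$covariance_type %||% "full",
              feature_names = model$feature_names,
              standardize = model$standardize, n = model$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mixture_model
#' @export
read_mixture_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$dim
  std <- obj$standardize
  if (!is.null(std)) std <- list(center = as.numeric(std$center),
                                 scale = as.numeric(std$scale))
  craw <- obj$covariances
  if (is.matrix(craw)) craw <- lapply(seq_len(nrow(craw)),
                                      function(i) craw[i, ])
  structure(list(C = obj$C, weights = as.numeric(obj$weights),
                 means = matrix(as.numeric(obj$means), obj$C, d),
                 covariances = lapply(craw, function(v)
                   matrix(as.numeric(v), d, d, byrow = TRUE)),
                 log_likelihood = obj$log_likelihood,
                 n_params = obj$n_params, bic = obj$bic,
                 covariance_type = obj$covariance_type,
                 feature_names = obj$feature_names,
                 standardize = std, n = obj$n),
            class = "mixture_model")
}

#' Run the spine-morphometry pipeline
#'
#' Wires the stages end to end with one seed: generate (or read) spines,
#' repair, extract features, cluster, simulate, and score realism. Every
#' artifact is written under `out_dir` together with a manifest recording
#' the configuration and seed.
#'
#' @param out_dir output directory (created if missing).
#' @param stages character subset of
#'   `c("synth", "repair", "extract", "cluster", "simulate", "realism")`.
#' @param mesh_dir,insertions existing inputs (used when `"synth"` is not
#'   among the stages): a mesh directory and an insertion-point CSV.
#' @param n_synthetic number of synthetic spines for the `synth` stage.
#' @param corrupt_fraction fraction of synthetic spines corrupted
#'   (alternating fragment/detach) before repair.
#' @param seed integer seed propagated to every stochastic stage.
#' @param K geodesic bands for feature extraction.
#' @param C_range component counts tried by the cluster stage.
#' @param covariance covariance structure for [fit_mixture()].
#' @param n_init EM restarts.
#' @param n_simulated simulated spines per selected cluster.
#' @param params a [repair_params()] list.
#' @param cfg a [simulation_config()].
#' @return invisibly, a list with the artifact paths and in-memory
#'   results (`features`, `model`, `memberships`, `realism`).
#' @export
run_pipeline <- function(out_dir,
                         stages = c("synth", "repair", "extract",
                                    "cluster", "simulate", "realism"),
                         mesh_dir = NULL, insertions = NULL,
                         n_synthetic = 30L, corrupt_fraction = 0.5,
                         seed = 1L, K = 7L, C_range = 1:6,
                         covariance = "diagonal", n_init = 2L,
                         n_simulated = 20L,
                         params = repair_params(),
                         cfg = simulation_config(seed = seed,
                                                 resample_invalid = FALSE)) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  records <- NULL
  if ("synth" %in% stages) {
    synth_dir <- file.path(out_dir, "meshes")
    dir.create(synth_dir, showWarnings = FALSE)
    profiles <- c("mushroom_like", "thin", "stubby", "straight_tube")
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    ins <- NULL
    records <- vector("list", n_synthetic)
    for (k in seq_len(n_synthetic)) {
      prof <- profiles[(k - 1L) %% 4L + 1L]
      sp <- make_synthetic_spine(spine_spec(prof), seed = seed + k,
                                 roughness = 0.015)
      mesh <- sp$mesh; insertion <- sp$insertion
      if (k <= ceiling(corrupt_fraction * n_synthetic)) {
        mode <- if (k %% 2L == 0L) "fragment" else "detach"
        ext <- diff(range(mesh$vertices[, 3]))
        mag <- runif(1, 0.2, min(1, 0.4 * ext))
        cor <- corrupt_mesh(mesh, mode, mag, insertion, seed = seed + k)
        mesh <- cor$mesh; insertion <- cor$insertion
      }
      id <- sprintf("spine%03d", k)
      write_mesh(mesh, file.path(synth_dir, paste0(id, ".ply")))
      ins <- rbind(ins, data.frame(spine_id = id, x = insertion[1],
                                   y = insertion[2], z = insertion[3]))
      records[[k]] <- list(spine_id = id, mesh = mesh,
                           insertion = insertion)
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    write_insertion_points(ins, file.path(out_dir, "insertions.csv"))
    artifacts$meshes <- synth_dir
    artifacts$insertions <- file.path(out_dir, "insertions.csv")
  } else if (any(c("repair", "extract") %in% stages)) {
    if (is.null(mesh_dir) || is.null(insertions))
      stop("mesh_dir and insertions are required when synth is skipped",
           call. = FALSE)
    if (!dir.exists(mesh_dir))
      stop("mesh directory does not exist: ", mesh_dir, call. = FALSE)
    records <- read_spine_records(mesh_dir, insertions)
  }
  if ("repair" %in% stages) {
    report <- NULL
    for (k in seq_along(records)) {
      res <- tryCatch(repair_spine(records[[k]], params),
                      error = function(e) e)
      if (inherits(res, "error")) {
        report <- rbind(report, data.frame(
          spine_id = records[[k]]$spine_id, action = "failed",
          accepted = FALSE, reasons = conditionMessage(res),
          volume_before = NA, volume_after = NA))
        records[[k]]$failed <- TRUE
      } else {
        records[[k]]$mesh <- res$mesh
        report <- rbind(report, data.frame(
          spine_id = records[[k]]$spine_id, action = res$action,
          accepted = res$accepted,
          reasons = paste(res$reasons, collapse = ";"),
          volume_before = res$volume_before,
          volume_after = res$volume_after))
        records[[k]]$failed <- !res$accepted
      }
    }
    write.csv(report, file.path(out_dir, "repair_report.csv"),
              row.names = FALSE)
    artifacts$repair_report <- file.path(out_dir, "repair_report.csv")
    records <- Filter(function(r) !isTRUE(r$failed), records)
  }
  result <- list(artifacts = artifacts)
  if ("extract" %in% stages) {
    feats <- extract_feature_table(records, K = K)
    write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
    artifacts$features <- file.path(out_dir, "features.csv")
    result$features <- feats
  }
  if ("cluster" %in% stages) {
    X <- as.matrix(result$features[, feature_names()])
    model <- fit_mixture(X, C_range = C_range, seed = seed,
                         n_init = n_init, covariance = covariance)
    write_mixture_model(model, file.path(out_dir, "model.json"))
    write.csv(model$bic_curve, file.path(out_dir, "bic.csv"),
              row.names = FALSE)
    mem <- memberships(model, X)
    memdf <- data.frame(spine_id = result$features$spine_id, mem$p,
                        p_star = mem$p_star, label = mem$label)
    names(memdf)[1 + seq_len(model$C)] <- paste0("p_", seq_len(model$C))
    write.csv(memdf, file.path(out_dir, "memberships.csv"),
              row.names = FALSE)
    artifacts$model <- file.path(out_dir, "model.json")
    result$model <- model
    result$memberships <- mem
  }
  if ("simulate" %in% stages && !is.null(result$model)) {
    sim_dir <- file.path(out_dir, "simulated")
    dir.create(sim_dir, showWarnings = FALSE)
    sims <- simulate_spines(result$model, cluster = 1L, n = n_simulated,
                            cfg = cfg)
    for (k in seq_along(sims$meshes))
      write_mesh(sims$meshes[[k]],
                 file.path(sim_dir, sprintf("sim%03d.ply", k)))
    artifacts$simulated <- sim_dir
    result$simulated <- sims
  }
  if ("realism" %in% stages && !is.null(result$model)) {
    X <- as.matrix(result$features[, feature_names()])
    simf <- suppressWarnings(
      sample_features(result$model, 1L, nrow(X), seed = seed,
                      resample_invalid = cfg$resample_invalid))
    rs <- realism_score(X, simf, folds = min(10L, nrow(X)), seed = seed)
    jsonlite::write_json(rs, file.path(out_dir, "realism.json"),
                         digits = NA, auto_unbox = TRUE)
    artifacts$realism <- file.path(out_dir, "realism.json")
    result$realism <- rs
  }
  manifest <- list(seed = seed, stages = stages, K = K,
                   C_range = C_range, covariance = covariance,
                   n_synthetic = n_synthetic,
                   voxel_spacing = params$voxel_spacing,
                   points_per_ellipse = cfg$points_per_ellipse,
                   subdivision_iterations = cfg$subdivision_iterations,
                   artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  result$artifacts <- artifacts
  invisible(result)
}
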