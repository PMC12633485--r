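# Orchestration of the twelve picking workflows:
# {intensities, fft, gabor} x {kmeans, gmm} x {cc, ws}.

#' The twelve canonical workflow specifications
#'
#' Every combination of a feature mode, a clustering algorithm and a
#' particle extraction algorithm, named `"<mode>-<method>-<extraction>"`.
#'
#' @return A 12-row `data.frame` with columns `feature_mode`,
#'   `cluster_method`, `extraction`, `name`.
#' @export
workflow_specs <- function() {
  g <- expand.grid(extraction = c("cc", "ws"),
                   cluster_method = c("kmeans", "gmm"),
                   feature_mode = c("intensities", "fft", "gabor"),
                   stringsAsFactors = FALSE)
  g <- g[, c("feature_mode", "cluster_method", "extraction")]
  g$name <- paste(g$feature_mode, g$cluster_method, g$extraction, sep = "-")
  rownames(g) <- NULL
  g
}

#' Default pipeline configuration
#'
#' All tunables of the pipeline in one list: preprocessing (blur sigma
#' in voxels, optional Z-slabs for model estimation and for centroid
#' reporting), feature extraction (neighborhood size, Gabor bank
#' geometry and selection), clustering (fit subsample cap, restarts,
#' EM control, polarity inversion) and instance extraction
#' (connectivity, size filter, watershed seed spacing).
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    preprocess = list(blur_sigma = 2, z_bounds_semantic = NULL,
                      z_bounds_instances = NULL),
    features = list(ns = 5L, n_per_axis = 10L, mout = 64L,
                    normalize_filters = TRUE, include_zero_freq = TRUE,
                    selection_max_voxels = 2^20),
    cluster = list(max_fit_voxels = 2^17, standardize = FALSE,
                   invert = FALSE, kmeans_nstart = 10L,
                   kmeans_iter_max = 50L, gmm_iter_max = 200L,
                   gmm_tol = 1e-4, gmm_ridge = 1e-6),
    instances = list(connectivity = 26L, min_size_voxels = 5L,
                     min_seed_separation = 3),
    evaluate = list(threshold_angstrom = 100, random_reps = 20L))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

semantic_for <- function(feat, method, config, seed, fit_feat = NULL) {
  model <- stage("fit_clusters", fit_clusters(
    fit_feat %||% feat, method = method,
    max_fit_voxels = config$cluster$max_fit_voxels,
    seed = derive_seed(seed, paste0("cluster-", feat$mode, "-", method)),
    standardize = config$cluster$standardize,
    kmeans_nstart = config$cluster$kmeans_nstart,
    kmeans_iter_max = config$cluster$kmeans_iter_max,
    gmm_iter_max = config$cluster$gmm_iter_max,
    gmm_tol = config$cluster$gmm_tol,
    gmm_ridge = config$cluster$gmm_ridge %||% 1e-6))
  lab <- stage("assign_clusters", assign_clusters(feat, model))
  sem <- stage("labels_to_semantic", labels_to_semantic(
    lab, invert = config$cluster$invert,
    z_bounds = config$preprocess$z_bounds_semantic))
  sem$model_ref <- sprintf("%s on %s features (seed %d)", method,
                           feat$mode, model$seed)
  sem
}

instances_for <- function(sem, extraction, config) {
  if (extraction == "cc")
    connected_components(sem, connectivity = config$instances$connectivity,
                         min_size_voxels = config$instances$min_size_voxels)
  else
    watershed_instances(
      sem, min_seed_separation_voxels = config$instances$min_seed_separation,
      min_size_voxels = config$instances$min_size_voxels,
      connectivity = config$instances$connectivity)
}

features_for <- function(tp, mode, config, seed) {
  stage("features", compute_features(
    tp, mode, config$features,
    seed = derive_seed(seed, paste0("features-", mode))))
}

#' Run a single picking workflow
#'
#' Executes preprocess (blur + normalize) -> feature extraction ->
#' two-cluster semantic segmentation -> instance segmentation ->
#' centroid extraction; deterministic given `seed`. When
#' `config$preprocess$z_bounds_semantic` is set, the cluster model is
#' estimated on features of that Z-slab only and then applied to the
#' whole volume (two-step slab estimation).
#'
#' @param t A [tomogram()].
#' @param spec A row of [workflow_specs()], a workflow name such as
#'   `"gabor-kmeans-cc"`, or a list with `feature_mode`,
#'   `cluster_method`, `extraction`.
#' @param config See [default_config()].
#' @param seed Integer master seed.
#' @return List with `semantic`, `instances`, `particles`, `spec`,
#'   `seed`.
#' @export
run_workflow <- function(t, spec, config = default_config(), seed = 1L) {
  stopifnot(inherits(t, "tomogram"))
  if (is.character(spec)) {
    all <- workflow_specs()
    row <- match(spec, all$name)
    if (is.na(row)) stop("unknown workflow name: ", spec)
    spec <- all[row, ]
  }
  tp <- stage("preprocess",
              preprocess_tomogram(t, config$preprocess$blur_sigma))
  feat <- features_for(tp, spec$feature_mode, config, seed)
  fit_feat <- NULL
  zb <- config$preprocess$z_bounds_semantic
  if (!is.null(zb))
    fit_feat <- features_for(stage("crop_z", crop_z(tp, zb[1], zb[2])),
                             spec$feature_mode, config, seed)
  sem <- semantic_for(feat, spec$cluster_method, config, seed, fit_feat)
  inst <- stage(spec$extraction, instances_for(sem, spec$extraction, config))
  parts <- stage("extract_centroids",
                 extract_centroids(inst,
                                   config$preprocess$z_bounds_instances))
  list(semantic = sem, instances = inst, particles = parts,
       spec = spec, seed = as.integer(seed))
}

#' Run the full workflow library on one tomogram
#'
#' Computes each feature mode once, each of the six (mode, method)
#' semantic segmentations once, and reuses every semantic segmentation
#' for both extraction algorithms, yielding six semantic segmentations
#' and twelve particle sets. A failing workflow is recorded and does
#' not abort the others. Seeds are derived per stage exactly as in
#' [run_workflow()], so `run_all()` reproduces twelve independent
#' [run_workflow()] calls.
#'
#' @param t A [tomogram()].
#' @param config See [default_config()].
#' @param seed Integer master seed.
#' @return List with `semantics` (6, named `"<mode>-<method>"`),
#'   `results` (12, named by workflow; each has `particles`,
#'   `instances`, `semantic_name`, or `error`), `dim`, `voxel_size`,
#'   `config`, `seed`.
#' @export
run_all <- function(t, config = default_config(), seed = 1L) {
  stopifnot(inherits(t, "tomogram"))
  specs <- workflow_specs()
  tp <- stage("preprocess",
              preprocess_tomogram(t, config$preprocess$blur_sigma))
  zb <- config$preprocess$z_bounds_semantic
  tp_slab <- if (!is.null(zb)) stage("crop_z", crop_z(tp, zb[1], zb[2]))
  semantics <- list()
  results <- list()
  for (mode in unique(specs$feature_mode)) {
    feat <- try(features_for(tp, mode, config, seed), silent = TRUE)
    fit_feat <- if (!is.null(zb) && !inherits(feat, "try-error"))
      try(features_for(tp_slab, mode, config, seed), silent = TRUE)
    for (method in unique(specs$cluster_method)) {
      sem_name <- paste(mode, method, sep = "-")
      sem <- if (inherits(feat, "try-error"))
        structure(list(message = conditionMessage(attr(feat, "condition"))),
                  class = "workflow_error")
      else tryCatch(
        semantic_for(feat, method, config, seed,
                     if (!is.null(zb)) fit_feat),
        error = function(e) structure(list(message = conditionMessage(e)),
                                      class = "workflow_error"))
      semantics[[sem_name]] <- sem
      for (extraction in unique(specs$extraction)) {
        wf <- paste(sem_name, extraction, sep = "-")
        results[[wf]] <- if (inherits(sem, "workflow_error"))
          list(error = sem$message, semantic_name = sem_name)
        else tryCatch({
          inst <- instances_for(sem, extraction, config)
          parts <- extract_centroids(inst,
                                     config$preprocess$z_bounds_instances)
          list(particles = parts, instances = inst,
               semantic_name = sem_name)
        }, error = function(e) list(error = conditionMessage(e),
                                    semantic_name = sem_name))
      }
    }
    feat <- NULL; fit_feat <- NULL   # free the feature matrix
  }
  list(semantics = semantics, results = results[specs$name],
       dim = dim(t$data), voxel_size = t$voxel_size,
       config = config, seed = as.integer(seed))
}

#' Evaluate a full run against ground truth
#'
#' One evaluation row per workflow ([evaluate_particles()] per
#' particle set); the best workflow is flagged by F1 when the ground
#' truth is complete (simulated/phantom regime) or by relative recall
#' when it is incomplete (real-data regime).
#'
#' @param outputs The result of [run_all()].
#' @param gt Ground-truth [particle_set()].
#' @param threshold_angstrom Match radius (default 100).
#' @param random_reps Random-baseline repetitions (default 20).
#' @param seed Seed for the random baseline.
#' @param rank_by `"f1"` or `"r_rel"`.
#' @return A `data.frame` with one row per workflow, metric columns
#'   from [evaluate_particles()], and a logical `best` column.
#' @export
evaluate_run <- function(outputs, gt, threshold_angstrom = 100,
                         random_reps = 20L, seed = 1L,
                         rank_by = c("f1", "r_rel")) {
  rank_by <- match.arg(rank_by)
  stopifnot(inherits(gt, "particle_set"))
  zb <- outputs$config$preprocess$z_bounds_instances
  rows <- lapply(names(outputs$results), function(wf) {
    res <- outputs$results[[wf]]
    if (!is.null(res$error)) {
      row <- data.frame(workflow = wf, n_pred = NA_integer_,
                        n_gt = n_particles(gt), tp = NA, fp = NA, fn = NA,
                        precision = NA, recall = NA, f1 = NA,
                        r_random = NA, r_rel = NA,
                        error = res$error)
      return(row)
    }
    ev <- evaluate_particles(
      res$particles, gt, outputs$dim,
      threshold_angstrom = threshold_angstrom, random_reps = random_reps,
      seed = derive_seed(seed, paste0("eval-", wf)), z_bounds = zb)
    cbind(data.frame(workflow = wf), ev, data.frame(error = NA_character_))
  })
  tab <- do.call(rbind, rows)
  score <- tab[[rank_by]]
  tab$best <- !is.na(score) & score == max(score, na.rm = TRUE)
  tab
}
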