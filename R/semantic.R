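# Two-cluster semantic segmentation of voxel features.

#' Fit a two-cluster model to voxel features
#'
#' A 2-cluster model is fitted on a seeded uniform subsample of at most
#' `max_fit_voxels` feature vectors. `"kmeans"` uses [stats::kmeans()]
#' with 10 restarts; `"gmm"` fits a 2-component Gaussian mixture with
#' full covariances by EM, initialized from a k-means partition and
#' ridge-regularized (`gmm_ridge` on every covariance diagonal) so that
#' near-degenerate feature dimensions -- high-frequency responses that
#' Gaussian smoothing has annihilated -- cannot break the fit. The fit
#' is deterministic given `seed`.
#'
#' Optional per-dimension standardization (`standardize = TRUE`) is off
#' by default: intensity, DFT-magnitude and normalized-filter features
#' are already commensurate, and rescaling inflates dimensions that
#' carry only noise, which measurably degrades the two-cluster split.
#'
#' Fitting the model on features from a central Z-slab
#' ([crop_z()] + feature extraction) and then assigning the full
#' volume with [assign_clusters()] implements two-step slab estimation.
#'
#' @param f A `feature_volume`.
#' @param method `"kmeans"` or `"gmm"`.
#' @param max_fit_voxels Subsample cap for fitting (default `2^17`).
#' @param seed Integer seed.
#' @param standardize Standardize features per dimension before
#'   fitting (default FALSE, see Details).
#' @param kmeans_nstart,kmeans_iter_max k-means restarts and iteration cap.
#' @param gmm_iter_max,gmm_tol EM iteration cap and relative
#'   log-likelihood tolerance.
#' @param gmm_ridge Ridge added to every covariance diagonal
#'   (default `1e-6`).
#' @return A `cluster_model`.
#' @export
fit_clusters <- function(f, method = c("kmeans", "gmm"),
                         max_fit_voxels = 2^17, seed = 1L,
                         standardize = FALSE,
                         kmeans_nstart = 10L, kmeans_iter_max = 50L,
                         gmm_iter_max = 200L, gmm_tol = 1e-4,
                         gmm_ridge = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(f, "feature_volume"))
  X <- f$values
  n <- nrow(X)
  if (n < 2) stop("feature region is empty or has a single voxel")
  ctr <- colMeans(X)
  scl <- sqrt(pmax(colMeans(X^2) - ctr^2, 0) * n / (n - 1))
  kept <- which(scl > 1e-12)
  if (length(kept) == 0)
    stop("degenerate input: all feature vectors are identical, ",
         "no two-cluster structure to fit")
  fit_idx <- if (n > max_fit_voxels)
    with_seed(derive_seed(seed, "fit-subsample"),
              sort(sample.int(n, max_fit_voxels)))
  else seq_len(n)
  Xs <- X[fit_idx, kept, drop = FALSE]
  if (standardize)
    Xs <- sweep(sweep(Xs, 2, ctr[kept]), 2, scl[kept], "/")
  if (all(rowSums(abs(sweep(Xs, 2, Xs[1, ]))) < 1e-10))
    stop("degenerate input: all sampled feature vectors are identical")

  params <- with_seed(seed, {
    if (method == "kmeans") {
      km <- kmeans(Xs, centers = 2L, nstart = kmeans_nstart,
                   iter.max = kmeans_iter_max)
      list(centers = km$centers)
    } else {
      km <- kmeans(Xs, centers = 2L, nstart = max(3L, kmeans_nstart %/% 3L),
                   iter.max = kmeans_iter_max)
      z0 <- cbind(as.numeric(km$cluster == 1L), as.numeric(km$cluster == 2L))
      fit <- gmm_fit_em(Xs, z0, ridge = gmm_ridge, itmax = gmm_iter_max,
                        tol = gmm_tol)
      list(pro = fit$pro, mean = fit$mean, sigma = fit$sigma,
           loglik = fit$loglik, iterations = fit$iterations)
    }
  })
  structure(
    list(method = method, params = params,
         feature_dim = f$dim, kept_dims = kept,
         standardize = standardize,
         center = ctr, scale = scl,
         fit_sample_size = length(fit_idx), seed = as.integer(seed)),
    class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(paste0("<cluster_model> %s, 2 clusters, feature dim %d ",
                     "(%d kept), fitted on %d voxels, seed %d\n"),
              x$method, x$feature_dim, length(x$kept_dims),
              x$fit_sample_size, x$seed))
  invisible(x)
}

#' Assign every region voxel to a cluster
#'
#' k-means assigns the nearest centroid; the Gaussian mixture assigns
#' the maximum-posterior component (hard assignment, computed in
#' chunks to bound memory). The returned integer array has the full
#' tomogram shape with values 1/2 on the feature region and `NA` on the
#' peripheral margin; tomogram provenance travels as attributes.
#'
#' @param f A `feature_volume` with `f$dim == m$feature_dim`.
#' @param m A `cluster_model` from [fit_clusters()].
#' @param chunk Rows per assignment chunk.
#' @return Integer array of cluster labels (`cluster_labels`).
#' @export
assign_clusters <- function(f, m, chunk = 262144L) {
  stopifnot(inherits(f, "feature_volume"), inherits(m, "cluster_model"))
  if (f$dim != m$feature_dim)
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 f$dim, m$feature_dim))
  X <- f$values[, m$kept_dims, drop = FALSE]
  if (m$standardize)
    X <- sweep(sweep(X, 2, m$center[m$kept_dims]), 2,
               m$scale[m$kept_dims], "/")
  n <- nrow(X)
  lab <- integer(n)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    Xi <- X[s:e, , drop = FALSE]
    lab[s:e] <- if (m$method == "kmeans") {
      cen <- m$params$centers
      d2 <- outer(rowSums(Xi^2), rowSums(cen^2), `+`) - 2 * Xi %*% t(cen)
      max.col(-d2, ties.method = "first")
    } else {
      ld <- gmm_log_dens(Xi, m$params$pro, m$params$mean, m$params$sigma)
      max.col(ld, ties.method = "first")
    }
  }
  grid <- array(NA_integer_, f$full_dim)
  grid[region_indices(f$full_dim, f$margin)] <- lab
  attr(grid, "voxel_size") <- f$voxel_size
  attr(grid, "origin") <- f$origin
  attr(grid, "margin") <- f$margin
  class(grid) <- c("cluster_labels", class(grid))
  grid
}

#' Convert cluster labels to a binary semantic segmentation
#'
#' The cluster with fewer member voxels is taken as the particle class
#' (particles occupy a minority of a tomogram); `invert` swaps the
#' mapping for the rare segmentations where the assumption fails. On an
#' exact tie, cluster 1 becomes the particle class. Voxels on the
#' peripheral margin, and outside `z_bounds` when given, are background.
#'
#' @param labels A `cluster_labels` array from [assign_clusters()].
#' @param invert Swap the particle/background mapping (default FALSE).
#' @param z_bounds Optional half-open full-frame `[zmin, zmax)` voxel
#'   bounds outside which the mask is zeroed.
#' @return A `semantic_segmentation`: binary mask (`1` = particle) of
#'   full tomogram shape plus `particle_fraction` over the feature
#'   region and provenance.
#' @export
labels_to_semantic <- function(labels, invert = FALSE, z_bounds = NULL) {
  stopifnot(inherits(labels, "cluster_labels"))
  n1 <- sum(labels == 1L, na.rm = TRUE)
  n2 <- sum(labels == 2L, na.rm = TRUE)
  particle <- if (n2 < n1) 2L else 1L      # tie goes to cluster 1
  if (invert) particle <- 3L - particle
  d <- dim(labels)
  mask <- array(0L, d)
  mask[which(labels == particle)] <- 1L
  origin <- attr(labels, "origin")
  if (!is.null(z_bounds)) {
    if (length(z_bounds) != 2 || z_bounds[1] >= z_bounds[2])
      stop("`z_bounds` must be an increasing pair")
    zfull <- origin[1] + seq_len(d[1]) - 1L   # full-frame z of each slice
    mask[zfull < z_bounds[1] | zfull >= z_bounds[2], , ] <- 0L
  }
  inside <- !is.na(labels)
  structure(
    list(mask = mask, inverted = invert,
         particle_fraction = mean(mask[inside]),
         voxel_size = attr(labels, "voxel_size"),
         origin = origin, margin = attr(labels, "margin")),
    class = "semantic_segmentation")
}

#' @export
print.semantic_segmentation <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(paste0("<semantic_segmentation> %d x %d x %d, particle ",
                     "fraction %.4f%s\n"), d[1], d[2], d[3],
              x$particle_fraction, if (x$inverted) ", inverted" else ""))
  invisible(x)
}

#' Serialize a cluster model to a JSON sidecar
#'
#' Enables reuse of one fitted model across many tomograms (estimate on
#' a subset, apply to the rest).
#'
#' @param m A `cluster_model`.
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
save_cluster_model <- function(m, path) {
  stopifnot(inherits(m, "cluster_model"))
  ser <- m
  class(ser) <- NULL
  pack <- function(a) list(dim = dim(a), values = as.vector(a))
  ser$params <- if (m$method == "gmm")
    list(pro = m$params$pro, mean = pack(m$params$mean),
         sigma = pack(m$params$sigma))
  else list(centers = pack(m$params$centers))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cluster model written by [save_cluster_model()]
#' @param path JSON path.
#' @return A `cluster_model`.
#' @export
read_cluster_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- j
  unpack <- function(p) array(p$values, p$dim)
  m$params <- if (j$method == "gmm")
    list(pro = j$params$pro, mean = unpack(j$params$mean),
         sigma = unpack(j$params$sigma))
  else list(centers = unpack(j$params$centers))
  m$kept_dims <- as.integer(j$kept_dims)
  class(m) <- "cluster_model"
  m
}
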