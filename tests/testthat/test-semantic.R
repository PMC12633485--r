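# build a feature_volume directly from a matrix, for clustering tests
fake_features <- function(X, region_dim = NULL) {
  n <- nrow(X)
  if (is.null(region_dim)) region_dim <- c(n, 1L, 1L)
  structure(
    list(values = X, mode = "intensities", dim = ncol(X), ns = 5L,
         margin = 2L, region_dim = as.integer(region_dim),
         region_origin = c(2L, 2L, 2L),
         full_dim = as.integer(region_dim + 4L), origin = c(0L, 0L, 0L),
         voxel_size = 10, selected_filter_indices = NULL),
    class = "feature_volume")
}

two_blob_features <- function(n = 2000, d = 4, sep = 5, seed = 21) {
  set.seed(seed)
  lab <- rep(1:2, c(round(0.3 * n), n - round(0.3 * n)))
  X <- matrix(rnorm(n * d), n, d) + sep * (lab == 1) - sep * (lab == 2)
  list(X = X, lab = lab)
}

test_that("both fitters recover two well-separated Gaussian clusters", {
  tb <- two_blob_features()
  f <- fake_features(tb$X)
  for (method in c("kmeans", "gmm")) {
    m <- fit_clusters(f, method, seed = 5)
    lab <- assign_clusters(f, m)
    got <- lab[!is.na(lab)]
    agree <- max(mean(got == tb$lab), mean(got == 3 - tb$lab))
    expect_gte(agree, 0.99)
    centers <- if (method == "kmeans") m$params$centers else t(m$params$mean)
    ord <- order(centers[, 1])
    expect_equal(unname(centers[ord, ]),
                 rbind(rep(-5, 4), rep(5, 4)), tolerance = 0.5)
  }
})

test_that("identical feature vectors raise a degenerate-input error", {
  f <- fake_features(matrix(3, 100, 4))
  expect_error(fit_clusters(f, "kmeans"), "degenerate")
  expect_error(fit_clusters(f, "gmm"), "degenerate")
})

test_that("fits are bit-reproducible given the seed", {
  tb <- two_blob_features(seed = 31)
  f <- fake_features(tb$X)
  for (method in c("kmeans", "gmm")) {
    m1 <- fit_clusters(f, method, seed = 9)
    m2 <- fit_clusters(f, method, seed = 9)
    expect_identical(m1$params, m2$params)
  }
})

test_that("assignment is nearest-centroid / maximum posterior", {
  set.seed(41)
  X <- matrix(rnorm(1000 * 3), 1000, 3)
  f <- fake_features(X)
  centers <- matrix(c(1, 1, 1, -1, -1, -1), 2, 3, byrow = TRUE)
  m <- structure(list(method = "kmeans", params = list(centers = centers),
                      feature_dim = 3L, kept_dims = 1:3,
                      standardize = FALSE, center = rep(0, 3),
                      scale = rep(1, 3), fit_sample_size = 0L, seed = 1L),
                 class = "cluster_model")
  lab <- assign_clusters(f, m)
  got <- lab[!is.na(lab)]
  # oracle: explicit distance comparison
  d1 <- rowSums(sweep(X, 2, centers[1, ])^2)
  d2 <- rowSums(sweep(X, 2, centers[2, ])^2)
  expect_equal(got, ifelse(d1 <= d2, 1L, 2L))
  # a vector exactly at a centroid goes to that centroid
  fx <- fake_features(centers)
  labx <- assign_clusters(fx, m)
  expect_equal(labx[!is.na(labx)], c(1L, 2L))
  # GMM with equal weights and equal isotropic covariances reduces to
  # nearest-mean assignment
  sig <- array(0, c(3, 3, 2)); sig[, , 1] <- diag(3); sig[, , 2] <- diag(3)
  mg <- structure(list(method = "gmm",
                       params = list(pro = c(0.5, 0.5), mean = t(centers),
                                     sigma = sig),
                       feature_dim = 3L, kept_dims = 1:3,
                       standardize = FALSE, center = rep(0, 3),
                       scale = rep(1, 3), fit_sample_size = 0L, seed = 1L),
                  class = "cluster_model")
  labg <- assign_clusters(f, mg)
  expect_equal(labg[!is.na(labg)], got)
  # dimension mismatch is rejected
  expect_error(assign_clusters(fake_features(X[, 1:2]), m), "dimension")
})

test_that("ridge EM agrees with an independent GMM fitter on clean data", {
  tb <- two_blob_features(n = 1500, d = 3, sep = 3, seed = 51)
  set.seed(6)
  km <- kmeans(tb$X, 2, nstart = 5)
  z0 <- cbind(as.numeric(km$cluster == 1), as.numeric(km$cluster == 2))
  fit <- tomopick:::gmm_fit_em(tb$X, z0, ridge = 1e-6)
  ref <- mclust::meVVV(data = tb$X, z = z0)
  ord <- order(fit$mean[1, ]); oref <- order(ref$parameters$mean[1, ])
  expect_equal(unname(fit$mean[, ord]),
               unname(ref$parameters$mean[, oref]), tolerance = 1e-3)
  expect_equal(unname(fit$pro[ord]), unname(ref$parameters$pro[oref]),
               tolerance = 1e-3)
  expect_equal(unname(fit$sigma[, , ord[1]]),
               unname(ref$parameters$variance$sigma[, , oref[1]]),
               tolerance = 1e-2)
})

test_that("smaller-cluster polarity, inversion, tie-break and bounds", {
  d <- c(10L, 9L, 9L)
  grid <- array(NA_integer_, d)
  idx <- tomopick:::region_indices(d, 2L)
  vals <- rep(2L, length(idx))
  vals[seq_len(round(0.3 * length(idx)))] <- 1L     # cluster 1 is smaller
  grid[idx] <- vals
  attr(grid, "voxel_size") <- 10
  attr(grid, "origin") <- c(0L, 0L, 0L)
  attr(grid, "margin") <- 2L
  class(grid) <- c("cluster_labels", class(grid))
  sem <- labels_to_semantic(grid)
  expect_equal(sort(unique(as.vector(sem$mask))), c(0L, 1L))
  expect_equal(sum(sem$mask), round(0.3 * length(idx)))   # minority = 1
  expect_lte(sem$particle_fraction, 0.5)
  inv <- labels_to_semantic(grid, invert = TRUE)
  expect_equal(sum(inv$mask), length(idx) - round(0.3 * length(idx)))
  # exact tie: cluster 1 becomes particle
  vals_tie <- rep(c(1L, 2L), length.out = length(idx))
  grid[idx] <- vals_tie
  tie <- labels_to_semantic(grid)
  expect_equal(which(tie$mask == 1L), idx[vals_tie == 1L])
  # peripheral margin voxels are always background
  expect_true(all(sem$mask[1:2, , ] == 0L))
  # z bounds zero the mask outside the slab
  semz <- labels_to_semantic(grid, z_bounds = c(4, 7))
  expect_true(all(semz$mask[c(1:4, 8:10), , ] == 0L))
})

test_that("cluster models survive a JSON round trip", {
  tb <- two_blob_features(n = 800, d = 3, seed = 61)
  f <- fake_features(tb$X)
  for (method in c("kmeans", "gmm")) {
    m <- fit_clusters(f, method, seed = 4)
    path <- withr::local_tempfile(fileext = ".json")
    save_cluster_model(m, path)
    m2 <- read_cluster_model(path)
    l1 <- assign_clusters(f, m)
    l2 <- assign_clusters(f, m2)
    expect_identical(as.vector(l1), as.vector(l2))
  }
})
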