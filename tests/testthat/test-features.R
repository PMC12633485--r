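test_that("default Gabor bank geometry matches its construction rules", {
  bank <- build_gabor_bank()
  expect_equal(bank$m, 1000L)               # 10 x 10 x 10 frequency grid
  expect_equal(length(bank$filters), 1000L)
  expect_equal(bank$sigma, 2 / 3)           # floor(5/2) / 3
  expect_equal(bank$mu, c(2, 2, 2))
  expect_true(all(vapply(bank$filters, function(f)
    identical(dim(f), c(5L, 5L, 5L)), logical(1))))
  expect_true(all(bank$freqs >= 0 & bank$freqs <= 0.5))
  expect_equal(build_gabor_bank(n_per_axis = 3)$m, 27L)
  expect_error(build_gabor_bank(ns = 4), "odd")
})

test_that("the zero-frequency filter is the L2-normalized Gaussian envelope", {
  bank <- build_gabor_bank()
  i0 <- which(rowSums(abs(bank$freqs)) == 0)
  expect_length(i0, 1)
  mu <- 2; sigma <- 2 / 3
  e1 <- exp(-((0:4) - mu)^2 / (2 * sigma^2))
  env <- outer(outer(e1, e1), e1)
  expect_equal(bank$filters[[i0]], env / sqrt(sum(env^2)), tolerance = 1e-12)
  # every filter is unit L2 norm after normalization
  norms <- vapply(bank$filters, function(f) sum(f^2), numeric(1))
  expect_equal(norms, rep(1, 1000), tolerance = 1e-12)
})

test_that("intensity features are the flattened neighborhoods, z-major", {
  set.seed(10)
  v <- array(rnorm(9^3), c(9, 9, 9))
  f <- intensity_features(tomogram(v, 10))
  expect_equal(f$dim, 125L)
  expect_equal(f$margin, 2L)
  expect_identical(f$region_dim, c(5L, 5L, 5L))
  # feature vector at voxel (4,4,4) 0-based = R index (5,5,5): the
  # directly sliced block, x offset fastest
  block <- v[3:7, 3:7, 3:7]
  expected <- as.vector(aperm(block, c(3, 2, 1)))  # x fastest in columns
  row <- which(apply(expand.grid(z = 2:6, y = 2:6, x = 2:6), 1,
                     function(r) all(r == c(4, 4, 4))))
  expect_equal(unname(f$values[row, ]), expected, tolerance = 0)
  # constant volume: every vector is constant
  fc <- intensity_features(tomogram(array(1.5, c(7, 7, 7)), 10))
  expect_true(all(fc$values == 1.5))
  expect_error(intensity_features(tomogram(array(0, c(4, 9, 9)), 10)),
               "smaller")
})

test_that("FFT features equal naive DFT magnitudes and known constants", {
  # constant neighborhood: DC magnitude 125c, all other bins 0
  fc <- fft_features(tomogram(array(2, c(7, 7, 7)), 10))
  expect_equal(unname(fc$values[1, 1]), 125 * 2, tolerance = 1e-9)
  expect_equal(max(abs(fc$values[, -1])), 0, tolerance = 1e-9)
  set.seed(11)
  v <- array(rnorm(7^3), c(7, 7, 7))
  f <- fft_features(tomogram(v, 10))
  # center voxel (R index 4,4,4) is region row ceiling(27/2) = 14
  center_row <- 14L
  expect_equal(unname(f$values[center_row, ]),
               naive_dft_mags(v[2:6, 2:6, 2:6]), tolerance = 1e-5)
  # real input: magnitude array is Hermitian symmetric, |X[k]| = |X[-k]|
  ns <- 5
  for (probe in list(c(1, 0, 0), c(2, 1, 0), c(4, 3, 2))) {
    k <- probe; kneg <- (ns - k) %% ns
    col <- function(kv) kv[3] * ns^2 + kv[2] * ns + kv[1] + 1
    expect_equal(f$values[, col(k)], f$values[, col(kneg)],
                 tolerance = 1e-8)
  }
})

test_that("Gabor responses equal naive correlation with the explicit filter", {
  set.seed(12)
  v <- array(rnorm(8^3), c(8, 8, 8))
  t1 <- tomogram(v, 10)
  bank <- build_gabor_bank(n_per_axis = 3)   # 27 filters incl. Nyquist
  f <- gabor_features(t1, bank, mout = 27L, seed = 1)
  rd <- f$region_dim
  # probe several filters x several region voxels against the oracle
  probe_rows <- c(1L, 17L, prod(rd))
  coords <- expand.grid(z = seq_len(rd[1]) + 1, y = seq_len(rd[2]) + 1,
                        x = seq_len(rd[3]) + 1)
  for (col in c(1L, 5L, 27L)) {
    fi <- f$selected_filter_indices[col]
    for (row in probe_rows) {
      pos <- as.integer(coords[row, c("z", "y", "x")]) + 1L
      expect_equal(unname(f$values[row, col]),
                   naive_correlate_at(v, bank$filters[[fi]], pos),
                   tolerance = 1e-5)
    }
  }
})

test_that("Gabor selection keeps the highest-variance filters, ties by index", {
  set.seed(13)
  v <- array(rnorm(9^3), c(9, 9, 9))
  t1 <- tomogram(v, 10)
  bank <- build_gabor_bank(n_per_axis = 3)
  f <- gabor_features(t1, bank, mout = 5L, seed = 2)
  expect_equal(f$dim, 5L)
  expect_length(f$selected_filter_indices, 5L)
  # columns ordered by decreasing response standard deviation
  sds <- apply(f$values, 2, sd)
  expect_true(all(diff(sds) <= 1e-12))
  # constant volume: all stds 0, tie-break falls back to lowest indices
  fc <- gabor_features(tomogram(array(1, c(7, 7, 7)), 10), bank,
                       mout = 4L, seed = 2)
  expect_identical(fc$selected_filter_indices, 1:4)
  expect_error(gabor_features(t1, bank, mout = 28L), "mout")
  # determinism of the full feature object given the seed
  f2 <- gabor_features(t1, bank, mout = 5L, seed = 2)
  expect_identical(f2$values, f$values)
  expect_identical(f2$selected_filter_indices, f$selected_filter_indices)
})

test_that("feature maps are translation-equivariant on the interior", {
  set.seed(14)
  v <- array(rnorm(10 * 9 * 9), c(10, 9, 9))
  vs <- v[c(2:10, 1), , ]        # shift down by one voxel along z
  t1 <- tomogram(v, 10); t2 <- tomogram(vs, 10)
  f1 <- intensity_features(t1); f2 <- intensity_features(t2)
  a1 <- array(f1$values[, 63], f1$region_dim)   # center offset column
  a2 <- array(f2$values[, 63], f2$region_dim)
  expect_equal(a2[1:5, , ], a1[2:6, , ], tolerance = 0)
  bank <- build_gabor_bank(n_per_axis = 2)
  g1 <- gabor_features(t1, bank, mout = 8L, seed = 1)
  g2 <- gabor_features(t2, bank, mout = 8L, seed = 1)
  expect_setequal(g1$selected_filter_indices, g2$selected_filter_indices)
  b1 <- array(g1$values[, which(g1$selected_filter_indices == 1L)],
              g1$region_dim)
  b2 <- array(g2$values[, which(g2$selected_filter_indices == 1L)],
              g2$region_dim)
  expect_equal(b2[1:5, , ], b1[2:6, , ], tolerance = 1e-10)
})
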