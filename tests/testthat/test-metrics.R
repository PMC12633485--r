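pset <- function(m, voxel_size = 1) particle_set(m, voxel_size)

test_that("matching handles identity, nearest-neighbor choice and counts", {
  set.seed(71)
  g <- matrix(runif(15, 0, 100), 5, 3)
  m <- match_particles(pset(g), pset(g), threshold_angstrom = 1)
  expect_equal(c(m$tp, m$fp, m$fn), c(5L, 0L, 0L))
  # one prediction, two ground truths at 90 and 300 A: matches the
  # 90 A neighbor within a 100 A threshold
  pred <- pset(matrix(c(0, 0, 0), 1))
  gt <- pset(matrix(c(90, 0, 0, 300, 0, 0), 2, 3, byrow = TRUE))
  m2 <- match_particles(pred, gt, 100)
  expect_equal(c(m2$tp, m2$fn), c(1L, 1L))
  expect_equal(unname(m2$pairing[1, "dist"]), 90)
  # 3 predictions, 2 gt, one pair within threshold
  pred3 <- pset(rbind(c(0, 0, 0), c(500, 0, 0), c(900, 0, 0)))
  gt2 <- pset(rbind(c(50, 0, 0), c(1500, 0, 0)))
  m3 <- match_particles(pred3, gt2, 100)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(1L, 2L, 1L))
  prf <- precision_recall_f1(m3$tp, m3$fp, m3$fn)
  expect_equal(unname(prf), c(1 / 3, 1 / 2, 0.4))
  expect_error(match_particles(pset(g, 1), pset(g, 2), 100), "voxel sizes")
})

test_that("precision/recall/F1 zero-denominator conventions", {
  expect_equal(unname(precision_recall_f1(2, 0, 0)), c(1, 1, 1))
  expect_equal(unname(precision_recall_f1(0, 5, 3)), c(0, 0, 0))
  expect_equal(unname(precision_recall_f1(0, 0, 0)), c(0, 0, 0))
})

test_that("greedy matching versus the exhaustive bipartite optimum", {
  # dense random clouds with a threshold comparable to the point
  # spacing: greedy may fall short of the optimum, but never by more
  # than a factor of two (every maximal matching is >= half maximum),
  # and the shortfall is rare -- measure it
  set.seed(72)
  short <- 0L
  for (case in 1:60) {
    np <- sample(0:6, 1); ng <- sample(0:6, 1)
    P <- matrix(runif(np * 3, 0, 10), np, 3)
    G <- matrix(runif(ng * 3, 0, 10), ng, 3)
    thr <- runif(1, 1, 6)
    m <- match_particles(pset(P), pset(G), thr)
    dmat <- if (np > 0 && ng > 0)
      sqrt(pmax(outer(rowSums(P^2), rowSums(G^2), `+`) - 2 * P %*% t(G), 0))
    else matrix(0, np, ng)
    opt <- best_matching_size(dmat, thr)
    expect_lte(m$tp, opt)
    expect_gte(m$tp, ceiling(opt / 2))
    short <- short + (m$tp < opt)
  }
  expect_lte(short / 60, 0.15)
  # well-separated regime (spacing >> threshold, as in real picking):
  # greedy is exactly optimal
  set.seed(75)
  for (case in 1:40) {
    grid <- as.matrix(expand.grid(x = seq(0, 80, 20), y = seq(0, 80, 20),
                                  z = c(0, 20)))
    ng <- sample(3:6, 1); np <- sample(3:6, 1)
    G <- grid[sample(nrow(grid), ng), , drop = FALSE]
    P <- grid[sample(nrow(grid), np), , drop = FALSE] +
      matrix(runif(np * 3, -2, 2), np, 3)
    thr <- 5
    m <- match_particles(pset(P), pset(G), thr)
    dmat <- sqrt(pmax(outer(rowSums(P^2), rowSums(G^2), `+`) -
                        2 * P %*% t(G), 0))
    expect_equal(m$tp, best_matching_size(dmat, thr))
  }
})

test_that("random baseline: edge cases and monotonicity in n_pred", {
  g <- pset(matrix(runif(30, 0, 50), 10, 3), voxel_size = 1)
  expect_equal(random_recall(0, g, c(50, 50, 50), 10, seed = 1), 0)
  # threshold larger than the region diagonal: every draw matches
  expect_equal(random_recall(10, g, c(50, 50, 50), 1e4, reps = 3, seed = 1),
               1.0)
  rr <- vapply(c(2, 8, 32, 128), function(n)
    random_recall(n, g, c(50, 50, 50), 8, reps = 20, seed = 5), numeric(1))
  expect_true(all(diff(rr) >= 0))
  # determinism
  expect_identical(random_recall(7, g, c(50, 50, 50), 8, seed = 3),
                   random_recall(7, g, c(50, 50, 50), 8, seed = 3))
  # z-restricted draws stay in the slab
  expect_error(random_recall(5, g, c(50, 50, 50), 8, seed = 1,
                             z_bounds = c(30, 20)), "empty|bounds")
})

test_that("relative recall formula, range and monotonicity", {
  expect_equal(relative_recall(1, 0), 1)
  expect_equal(relative_recall(0, 0.7), 0)
  expect_equal(relative_recall(0.6, 0.2), 2 * 0.6 * 0.8 / (0.6 + 0.8))
  expect_error(relative_recall(1.2, 0), "\\[0, 1\\]")
  gr <- seq(0, 1, by = 0.05)
  vals <- outer(gr, gr, relative_recall)
  expect_true(all(vals >= 0 & vals <= 1))
  # non-decreasing in R (rows), non-increasing in r_random (columns)
  expect_true(all(apply(vals, 2, function(v) all(diff(v) >= -1e-12))))
  expect_true(all(apply(vals, 1, function(v) all(diff(v) <= 1e-12))))
})

test_that("at constant precision, more predictions raise F1 but lower
           relative recall", {
  # fixed ground truth; prediction sets of growing size with precision
  # held at 1/2: half the predictions sit on distinct truths, half far
  # outside the annotated region. As predictions grow, random guessing
  # covers an ever larger share of the volume, so the random baseline
  # eats the recall gain.
  set.seed(73)
  n_gt <- 400
  G <- matrix(runif(n_gt * 3, 5, 95), n_gt, 3)
  gt <- pset(G, voxel_size = 1)
  sizes <- c(200, 400, 800)
  f1s <- rrels <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    hits <- G[seq_len(s / 2), , drop = FALSE]
    misses <- matrix(runif(s / 2 * 3, 300, 400), s / 2, 3)
    pred <- pset(rbind(hits, misses), voxel_size = 1)
    m <- match_particles(pred, gt, 15)
    prf <- precision_recall_f1(m$tp, m$fp, m$fn)
    expect_equal(unname(prf["precision"]), 0.5)
    rr <- random_recall(s, gt, c(100, 100, 100), 15, reps = 20, seed = 9)
    f1s[i] <- prf[["f1"]]
    rrels[i] <- relative_recall(prf[["recall"]], rr)
  }
  expect_true(all(diff(f1s) > 0))
  expect_true(all(diff(rrels) < 0))
})

test_that("per-type recall is tallied from the global matching", {
  G <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0), c(300, 0, 0))
  gt <- particle_set(G, 1, labels = c("ribo", "ribo", "atp", "atp"))
  pred <- pset(G[c(1, 3), , drop = FALSE])
  ev <- evaluate_particles(pred, gt, c(400, 50, 50),
                           threshold_angstrom = 10, random_reps = 2,
                           seed = 1)
  expect_equal(ev$tp, 2L)
  rbt <- attr(ev, "recall_by_type")
  expect_equal(unname(rbt[c("atp", "ribo")]), c(0.5, 0.5))
})
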