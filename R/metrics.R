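# Coordinate-set evaluation: threshold matching, precision/recall/F1,
# Monte-Carlo random baseline, relative recall.

#' Match predicted to ground-truth centroids
#'
#' One-to-one greedy matching: all (prediction, ground truth) pairs
#' closer than `threshold_angstrom` are sorted by ascending distance
#' and accepted whenever both members are still unused, so a single
#' prediction can never satisfy several ground-truth particles.
#' Accepted pairs are true positives; unmatched predictions false
#' positives; unmatched ground truth false negatives.
#'
#' @param pred,gt [particle_set()]s in the same frame (equal voxel sizes).
#' @param threshold_angstrom Match radius in Angstrom (100 is typical
#'   for simulated ground truth, 125 for real-world annotations whose
#'   own positions carry error).
#' @return List with `tp`, `fp`, `fn` and `pairing` (matrix of matched
#'   `pred`/`gt` indices and their `dist` in Angstrom).
#' @export
match_particles <- function(pred, gt, threshold_angstrom) {
  stopifnot(inherits(pred, "particle_set"), inherits(gt, "particle_set"))
  stop_if_not_scalar_number(threshold_angstrom, "threshold_angstrom",
                            positive = TRUE)
  if (abs(pred$voxel_size - gt$voxel_size) >
      1e-6 * max(pred$voxel_size, gt$voxel_size))
    stop("prediction and ground truth have mismatched voxel sizes")
  np <- n_particles(pred); ng <- n_particles(gt)
  empty <- matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("pred", "gt", "dist")))
  if (np == 0 || ng == 0)
    return(list(tp = 0L, fp = np, fn = ng, pairing = empty))
  P <- centroids_angstrom(pred); G <- centroids_angstrom(gt)
  d2 <- outer(rowSums(P^2), rowSums(G^2), `+`) - 2 * P %*% t(G)
  d <- sqrt(pmax(d2, 0))
  cand <- which(d <= threshold_angstrom, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(list(tp = 0L, fp = np, fn = ng, pairing = empty))
  dc <- d[cand]
  o <- order(dc, cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]; dc <- dc[o]
  used_p <- logical(np); used_g <- logical(ng)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used_p[i] && !used_g[j]) {
      used_p[i] <- TRUE; used_g[j] <- TRUE; keep[r] <- TRUE
    }
  }
  pairing <- cbind(pred = cand[keep, 1], gt = cand[keep, 2], dist = dc[keep])
  list(tp = sum(keep), fp = np - sum(keep), fn = ng - sum(keep),
       pairing = pairing)
}

#' Precision, recall and F1 from match counts
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`; any
#' zero-denominator case returns 0, penalizing empty predictions rather
#' than erroring.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Recall of uniformly random predictions (Monte-Carlo baseline)
#'
#' For each repetition, `n_pred` centroids are drawn uniformly over the
#' evaluation region (the Z-slab box when `z_bounds` is given,
#' otherwise the full volume), matched against the ground truth with
#' [match_particles()], and the mean recall over repetitions is
#' returned. Deterministic given `seed`.
#'
#' @param n_pred Number of random predictions per repetition.
#' @param gt Ground-truth [particle_set()].
#' @param volume_dim Volume shape `(z, y, x)` in voxels.
#' @param threshold_angstrom Match radius in Angstrom.
#' @param reps Repetitions (default 20).
#' @param seed Integer seed.
#' @param z_bounds Optional half-open voxel Z bounds of the slab.
#' @return Mean recall over repetitions.
#' @export
random_recall <- function(n_pred, gt, volume_dim, threshold_angstrom,
                          reps = 20L, seed = 1L, z_bounds = NULL) {
  stopifnot(n_pred >= 0, reps >= 1, inherits(gt, "particle_set"))
  if (n_pred == 0 || n_particles(gt) == 0) return(0)
  lo <- c(0, 0, 0)
  hi <- pmax(as.numeric(volume_dim) - 1, 0)
  if (!is.null(z_bounds)) {
    lo[1] <- z_bounds[1]
    hi[1] <- min(hi[1], z_bounds[2] - 1)
  }
  if (any(hi < lo)) stop("empty evaluation region")
  with_seed(seed, {
    recalls <- vapply(seq_len(reps), function(rep) {
      cv <- cbind(z = runif(n_pred, lo[1], hi[1]),
                  y = runif(n_pred, lo[2], hi[2]),
                  x = runif(n_pred, lo[3], hi[3]))
      m <- match_particles(particle_set(cv, gt$voxel_size), gt,
                           threshold_angstrom)
      precision_recall_f1(m$tp, m$fp, m$fn)[["recall"]]
    }, numeric(1))
    mean(recalls)
  })
}

#' Relative recall
#'
#' The harmonic mean of the achieved recall and one minus the random
#' baseline recall:
#' \deqn{R_{rel} = \frac{2 R (1 - R_{random})}{R + (1 - R_{random})}}
#' It ranges from 0 to 1; values near 1 mean the picker recalls the
#' annotations far better than random placement of the same number of
#' predictions, which makes it robust to incomplete ground truth where
#' precision (and hence F1) is misleading.
#'
#' @param R Recall in `[0, 1]`.
#' @param r_random Random-baseline recall in `[0, 1]`.
#' @return Relative recall in `[0, 1]`.
#' @export
relative_recall <- function(R, r_random) {
  if (any(R < 0 | R > 1) || any(r_random < 0 | r_random > 1))
    stop("`R` and `r_random` must lie in [0, 1]")
  denom <- R + (1 - r_random)
  ifelse(denom > 0, 2 * R * (1 - r_random) / denom, 0)
}

#' Evaluate one predicted particle set against ground truth
#'
#' Runs threshold matching, computes precision/recall/F1, the
#' Monte-Carlo random baseline and relative recall, and (when the
#' ground truth carries type labels) per-type recall tallied from the
#' single global matching.
#'
#' @param pred,gt [particle_set()]s.
#' @param volume_dim Volume shape `(z, y, x)` in voxels (random
#'   baseline region).
#' @param threshold_angstrom Match radius (default 100).
#' @param random_reps Baseline repetitions (default 20).
#' @param seed Seed for the baseline.
#' @param z_bounds Optional voxel Z bounds of the evaluation slab.
#' @return One-row `data.frame` with counts and metrics; per-type
#'   recall, if any, in `attr(, "recall_by_type")`.
#' @export
evaluate_particles <- function(pred, gt, volume_dim,
                               threshold_angstrom = 100, random_reps = 20L,
                               seed = 1L, z_bounds = NULL) {
  m <- match_particles(pred, gt, threshold_angstrom)
  prf <- precision_recall_f1(m$tp, m$fp, m$fn)
  rr <- random_recall(n_particles(pred), gt, volume_dim,
                      threshold_angstrom, reps = random_reps, seed = seed,
                      z_bounds = z_bounds)
  out <- data.frame(
    n_pred = n_particles(pred), n_gt = n_particles(gt),
    tp = m$tp, fp = m$fp, fn = m$fn,
    precision = prf[["precision"]], recall = prf[["recall"]],
    f1 = prf[["f1"]], r_random = rr,
    r_rel = relative_recall(prf[["recall"]], rr))
  if (!is.null(gt$labels) && n_particles(gt) > 0) {
    matched <- logical(n_particles(gt))
    if (nrow(m$pairing) > 0) matched[m$pairing[, "gt"]] <- TRUE
    rbt <- tapply(matched, gt$labels, mean)
    attr(out, "recall_by_type") <- setNames(as.numeric(rbt), names(rbt))
  }
  out
}
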