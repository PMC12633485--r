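# Independent brute-force oracles, deliberately naive: each recomputes
# a quantity by direct definition, sharing no code path with the
# package internals it checks.

# Correlation of a volume (z, y, x) with a kernel array at one voxel
# (1-based center position), by explicit triple loop.
naive_correlate_at <- function(vol, kern, pos) {
  kn <- dim(kern)
  m <- (kn - 1) %/% 2
  acc <- 0
  for (iz in 1:kn[1]) for (iy in 1:kn[2]) for (ix in 1:kn[3]) {
    acc <- acc + kern[iz, iy, ix] *
      vol[pos[1] + iz - 1 - m[1], pos[2] + iy - 1 - m[2],
          pos[3] + ix - 1 - m[3]]
  }
  acc
}

# 3D DFT magnitudes of an ns^3 block by explicit quadruple loop,
# flattened z-major (kx fastest) to match the documented feature order.
naive_dft_mags <- function(block) {
  ns <- dim(block)[1]
  out <- numeric(ns^3)
  for (kz in 0:(ns - 1)) for (ky in 0:(ns - 1)) for (kx in 0:(ns - 1)) {
    acc <- 0 + 0i
    for (jz in 0:(ns - 1)) for (jy in 0:(ns - 1)) for (jx in 0:(ns - 1)) {
      acc <- acc + block[jz + 1, jy + 1, jx + 1] *
        exp(-2i * pi * (kx * jx + ky * jy + kz * jz) / ns)
    }
    out[kz * ns^2 + ky * ns + kx + 1] <- Mod(acc)
  }
  out
}

# Connected components by breadth-first flood fill over an explicit
# neighbor list; returns labels in raster discovery order.
flood_fill_cc <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & nz <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ]
  labels <- array(0L, d)
  cur <- 0L
  for (start in which(mask != 0)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      p <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        w <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
        if (mask[w] != 0 && labels[w] == 0L) {
          labels[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

# Maximum-cardinality bipartite matching under a distance threshold by
# exhaustive recursion (feasible for <= ~6 predictions).
best_matching_size <- function(dmat, threshold) {
  np <- nrow(dmat)
  rec <- function(i, used_gt) {
    if (i > np) return(0L)
    best <- rec(i + 1L, used_gt)   # leave prediction i unmatched
    for (j in seq_len(ncol(dmat))) {
      if (!used_gt[j] && dmat[i, j] <= threshold) {
        used_gt[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used_gt))
        used_gt[j] <- FALSE
      }
    }
    best
  }
  if (np == 0 || ncol(dmat) == 0) return(0L)
  rec(1L, logical(ncol(dmat)))
}

# Round a numeric vector/array through IEEE float32.
quantize_f32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}

# A small, quick phantom for pipeline-level tests.
tiny_phantom <- function(seed = 5L, n = 6L, noise = 0.08) {
  generate_phantom(phantom_config(
    shape = c(28L, 48L, 48L), n_particles = n,
    shape_mix = c(sphere = 0.7, ellipsoid = 0.3),
    radius_range = c(3.5, 4.5), noise_sigma = noise, min_separation = 13,
    seed = seed))
}

# Tweak a phantom_config while preserving its class; setting a field to
# NULL removes it, which reads back as NULL.
modifyList2 <- function(cfg, ...) {
  out <- utils::modifyList(unclass(cfg), list(...))
  class(out) <- class(cfg)
  out
}
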