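# Per-voxel feature extraction from Ns x Ns x Ns neighborhoods.
#
# Features are computed for every non-peripheral voxel: a voxel at least
# floor(ns/2) voxels from every volume face, so that its whole
# neighborhood lies inside the volume. Feature vectors are stored as a
# matrix with one row per region voxel in column-major (z fastest)
# region order; neighborhood flattening within a vector is z-major
# (x fastest, z slowest).

feature_volume <- function(values, mode, t, ns, region_dim,
                           selected_filter_indices = NULL) {
  margin <- ns %/% 2L
  structure(
    list(values = values, mode = mode, dim = ncol(values),
         ns = as.integer(ns), margin = margin,
         region_dim = as.integer(region_dim),
         region_origin = t$origin + margin,   # full-frame (z, y, x)
         full_dim = dim(t$data),
         origin = t$origin,
         voxel_size = t$voxel_size,
         selected_filter_indices = selected_filter_indices),
    class = "feature_volume")
}

#' @export
print.feature_volume <- function(x, ...) {
  cat(sprintf(paste0("<feature_volume> mode = %s, dim = %d, region ",
                     "%d x %d x %d (z,y,x), margin = %d\n"),
              x$mode, x$dim, x$region_dim[1], x$region_dim[2],
              x$region_dim[3], x$margin))
  invisible(x)
}

# Linear indices (into the full volume array) of the non-peripheral
# region, in region column-major order.
region_indices <- function(full_dim, margin) {
  nz <- full_dim[1]; ny <- full_dim[2]; nx <- full_dim[3]
  z <- (margin + 1):(nz - margin)
  y <- (margin + 1):(ny - margin)
  x <- (margin + 1):(nx - margin)
  iz <- rep(z, times = length(y) * length(x))
  iy <- rep(rep(y, each = length(z)), times = length(x))
  ix <- rep(x, each = length(z) * length(y))
  iz + nz * (iy - 1L) + nz * ny * (ix - 1L)
}

check_feature_input <- function(t, ns) {
  stopifnot(inherits(t, "tomogram"))
  ns <- as.integer(ns)
  if (ns < 3L || ns %% 2L == 0L) stop("`ns` must be an odd integer >= 3")
  if (any(dim(t$data) < ns))
    stop(sprintf("volume (%s) smaller than the neighborhood size %d",
                 paste(dim(t$data), collapse = "x"), ns))
  ns
}

#' Raw-intensity neighborhood features
#'
#' For every non-peripheral voxel, the feature vector is the flattened
#' `ns^3` neighborhood of raw intensities (dimension 125 for the
#' default `ns = 5`), flattened z-major (x offset fastest).
#'
#' @param t A (preprocessed) [tomogram()].
#' @param ns Odd neighborhood edge length (default 5).
#' @return A `feature_volume`.
#' @export
intensity_features <- function(t, ns = 5L) {
  ns <- check_feature_input(t, ns)
  m <- ns %/% 2L
  d <- dim(t$data)
  rdim <- d - 2L * m
  vals <- matrix(0, prod(rdim), ns^3)
  col <- 0L
  for (dz in -m:m) for (dy in -m:m) for (dx in -m:m) {
    # column position: z offset slowest, x offset fastest
    col <- (dz + m) * ns^2 + (dy + m) * ns + (dx + m) + 1L
    vals[, col] <- as.vector(
      t$data[(m + 1 + dz):(d[1] - m + dz),
             (m + 1 + dy):(d[2] - m + dy),
             (m + 1 + dx):(d[3] - m + dx)])
  }
  feature_volume(vals, "intensities", t, ns, rdim)
}

#' 3D DFT magnitude features
#'
#' For every non-peripheral voxel, the magnitudes of the unnormalized 3D
#' discrete Fourier transform of its `ns^3` neighborhood (dimension
#' `ns^3`). Bins are flattened z-major: column `kz*ns^2 + ky*ns + kx + 1`
#' holds bin `(kx, ky, kz)`. The transform is evaluated as a separable
#' complex correlation per axis, which is exact on the interior.
#'
#' @inheritParams intensity_features
#' @return A `feature_volume`.
#' @export
fft_features <- function(t, ns = 5L) {
  ns <- check_feature_input(t, ns)
  m <- ns %/% 2L
  d <- dim(t$data)
  rdim <- d - 2L * m
  ridx <- region_indices(d, m)
  vol <- as.vector(t$data) + 0i
  j <- 0:(ns - 1)
  vals <- matrix(0, prod(rdim), ns^3)
  for (kx in j) {
    hx <- exp(-2i * pi * kx * j / ns)
    ax <- conv_axis_cplx(vol, d, hx, 3L, m)
    for (ky in j) {
      hy <- exp(-2i * pi * ky * j / ns)
      axy <- conv_axis_cplx(ax, d, hy, 2L, m)
      for (kz in j) {
        hz <- exp(-2i * pi * kz * j / ns)
        full <- conv_axis_cplx(axy, d, hz, 1L, m)
        vals[, kz * ns^2 + ky * ns + kx + 1L] <- Mod(full[ridx])
      }
    }
  }
  feature_volume(vals, "fft", t, ns, rdim)
}

#' Gabor filter-bank features
#'
#' Correlates the volume with every filter of a [build_gabor_bank()]
#' (separably, exact on the non-peripheral interior), measures each
#' filter's response standard deviation over the (optionally
#' subsampled) region voxels, and keeps the `mout` filters with the
#' largest response standard deviations -- ties broken toward the lower
#' filter index. Feature columns are ordered by decreasing response
#' standard deviation.
#'
#' @inheritParams intensity_features
#' @param bank A [build_gabor_bank()]; its `ns` must match.
#' @param mout Number of filters to keep (default 64).
#' @param selection_max_voxels Upper bound on the number of region
#'   voxels used to estimate response standard deviations; a seeded
#'   uniform subsample is taken above it (memory/time lever).
#' @param seed Seed for the selection subsample.
#' @return A `feature_volume` with `dim = mout` and the chosen
#'   `selected_filter_indices`.
#' @export
gabor_features <- function(t, bank = build_gabor_bank(), mout = 64L,
                           selection_max_voxels = 2^20, seed = 1L) {
  ns <- check_feature_input(t, bank$ns)
  if (mout < 1L || mout > bank$m)
    stop(sprintf("`mout` must be in [1, %d]", bank$m))
  m <- ns %/% 2L
  d <- dim(t$data)
  rdim <- d - 2L * m
  ridx <- region_indices(d, m)
  nreg <- length(ridx)
  sel <- if (nreg > selection_max_voxels) {
    with_seed(seed, sort(sample.int(nreg, selection_max_voxels)))
  } else seq_len(nreg)
  if (length(sel) == 0) stop("empty selection sample")
  sidx <- ridx[sel]

  n <- bank$n_per_axis
  fax <- unique(bank$freqs[, "fx"])   # per-axis frequency grid
  vol <- as.vector(t$data) + 0i

  # pass 1: response standard deviation per filter over the sample
  stds <- numeric(bank$m)
  for (ix in seq_len(n)) {
    ax <- conv_axis_cplx(vol, d, gabor_carrier_1d(ns, fax[ix]), 3L, m)
    for (iy in seq_len(n)) {
      axy <- conv_axis_cplx(ax, d, gabor_carrier_1d(ns, fax[iy]), 2L, m)
      for (iz in seq_len(n)) {
        i <- (iz - 1L) * n^2 + (iy - 1L) * n + ix
        full <- conv_axis_cplx(axy, d, gabor_carrier_1d(ns, fax[iz]), 1L, m)
        r <- Re(full[sidx])
        if (bank$normalized && bank$norms[i] > 0) r <- r / bank$norms[i]
        stds[i] <- sd(r)
      }
    }
  }
  keep <- order(-stds, seq_along(stds))[seq_len(mout)]

  # pass 2: full-region responses for the selected filters only
  vals <- matrix(0, nreg, mout)
  grid_pos <- cbind(ix = (keep - 1L) %% n + 1L,
                    iy = ((keep - 1L) %/% n) %% n + 1L,
                    iz = (keep - 1L) %/% (n^2) + 1L)
  for (ix in unique(grid_pos[, "ix"])) {
    rows_x <- which(grid_pos[, "ix"] == ix)
    ax <- conv_axis_cplx(vol, d, gabor_carrier_1d(ns, fax[ix]), 3L, m)
    for (iy in unique(grid_pos[rows_x, "iy"])) {
      rows_xy <- rows_x[grid_pos[rows_x, "iy"] == iy]
      axy <- conv_axis_cplx(ax, d, gabor_carrier_1d(ns, fax[iy]), 2L, m)
      for (r2 in rows_xy) {
        iz <- grid_pos[r2, "iz"]
        full <- conv_axis_cplx(axy, d, gabor_carrier_1d(ns, fax[iz]), 1L, m)
        r <- Re(full[ridx])
        if (bank$normalized && bank$norms[keep[r2]] > 0)
          r <- r / bank$norms[keep[r2]]
        vals[, r2] <- r
      }
    }
  }
  feature_volume(vals, "gabor", t, ns, rdim,
                 selected_filter_indices = keep)
}

#' Compute features in a named mode
#'
#' @param t A (preprocessed) [tomogram()].
#' @param mode `"intensities"`, `"fft"` or `"gabor"`.
#' @param config Feature settings, see [default_config()]`$features`.
#' @param seed Seed for the Gabor selection subsample.
#' @return A `feature_volume`.
#' @export
compute_features <- function(t, mode = c("intensities", "fft", "gabor"),
                             config = default_config()$features, seed = 1L) {
  mode <- match.arg(mode)
  switch(mode,
    intensities = intensity_features(t, config$ns),
    fft = fft_features(t, config$ns),
    gabor = {
      bank <- build_gabor_bank(config$ns, config$n_per_axis,
                               include_zero = config$include_zero_freq,
                               normalize = config$normalize_filters)
      gabor_features(t, bank, mout = config$mout,
                     selection_max_voxels = config$selection_max_voxels,
                     seed = seed)
    })
}
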