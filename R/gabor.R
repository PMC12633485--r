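#' Build a 3D Gabor filter bank
#'
#' Each filter is the product of an isotropic 3D Gaussian envelope and a
#' plane-wave sinusoid, evaluated on the integer grid `[0, ns)^3`:
#' \deqn{G(x,y,z) = N_{\mu,\sigma}(x,y,z) \cos(2\pi(x f_x + y f_y + z f_z) + \psi)}
#' with the envelope mean at the filter center
#' `(floor(ns/2), floor(ns/2), floor(ns/2))`, standard deviation
#' `floor(ns/2)/3` and phase `psi = 0`. Frequencies are taken from a
#' per-axis grid of `n_per_axis` values spaced uniformly over
#' `[0, 0.5]` cycles/voxel (DC through Nyquist), giving
#' `m = n_per_axis^3` filters; with the defaults `ns = 5`,
#' `n_per_axis = 10` the bank holds 1000 filters. Filters are
#' L2-normalized after construction (configurable) so that
#' response-variance filter selection compares filters on an equal
#' energy footing.
#'
#' Filter `i` carries the frequency triple with the x-axis frequency
#' varying fastest: `i = iz * n^2 + iy * n + ix + 1` over 0-based grid
#' positions `(ix, iy, iz)`.
#'
#' @param ns Odd filter edge length in voxels (>= 3; default 5).
#' @param n_per_axis Number of frequencies per axis (default 10).
#' @param include_zero If `TRUE` (default) the frequency grid includes 0
#'   (a pure low-pass envelope filter); if `FALSE` it spans
#'   `(0, 0.5]` in `n_per_axis` steps.
#' @param normalize L2-normalize every filter (default `TRUE`).
#' @return A `gabor_bank` object with elements `filters` (list of
#'   `ns^3` arrays indexed `(z, y, x)`), `freqs` (`m x 3` matrix of
#'   `fx, fy, fz`), `norms`, `ns`, `n_per_axis`, `sigma`, `mu`, `psi`.
#' @export
build_gabor_bank <- function(ns = 5L, n_per_axis = 10L, include_zero = TRUE,
                             normalize = TRUE) {
  ns <- as.integer(ns)
  if (ns < 3L || ns %% 2L == 0L) stop("`ns` must be an odd integer >= 3")
  if (n_per_axis < 1L) stop("`n_per_axis` must be >= 1")
  mu <- ns %/% 2L
  sigma <- mu / 3
  freqs_axis <- if (include_zero) {
    if (n_per_axis == 1L) 0 else seq(0, 0.5, length.out = n_per_axis)
  } else {
    seq(0.5 / n_per_axis, 0.5, length.out = n_per_axis)
  }
  env1 <- exp(-((0:(ns - 1)) - mu)^2 / (2 * sigma^2)) /
    (sigma * sqrt(2 * pi))
  grid <- expand.grid(fx = freqs_axis, fy = freqs_axis, fz = freqs_axis,
                      KEEP.OUT.ATTRS = FALSE)
  m <- nrow(grid)
  x <- 0:(ns - 1)
  filters <- vector("list", m)
  norms <- numeric(m)
  # envelope as the product of three 1D profiles; array is (z, y, x)
  env3 <- outer(outer(env1, env1), env1)   # dims (z, y, x) by symmetry
  for (i in seq_len(m)) {
    fx <- grid$fx[i]; fy <- grid$fy[i]; fz <- grid$fz[i]
    ph <- outer(outer(x * fz, x * fy, `+`), x * fx, `+`)  # (z, y, x)
    g <- env3 * cos(2 * pi * ph)
    nrm <- sqrt(sum(g^2))
    norms[i] <- nrm
    filters[[i]] <- if (normalize && nrm > 0) g / nrm else g
  }
  structure(
    list(filters = filters, freqs = as.matrix(grid), norms = norms,
         ns = ns, n_per_axis = as.integer(n_per_axis),
         mu = rep(mu, 3), sigma = sigma, psi = 0,
         normalized = normalize, include_zero = include_zero,
         m = m),
    class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf(paste0("<gabor_bank> m = %d filters (%d per axis), ns = %d, ",
                     "sigma = %.4g, psi = %g, %sL2-normalized\n"),
              x$m, x$n_per_axis, x$ns, x$sigma, x$psi,
              if (x$normalized) "" else "not "))
  invisible(x)
}

# 1D complex carrier for the separable evaluation of a Gabor filter:
# env1[j] * exp(2i*pi*f*j). The product over the three axes has the
# filter as its real part, so one complex separable correlation per
# axis replaces a dense 3D correlation.
gabor_carrier_1d <- function(ns, f) {
  mu <- ns %/% 2L
  sigma <- mu / 3
  j <- 0:(ns - 1)
  env <- exp(-(j - mu)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  env * exp(2i * pi * f * j)
}
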