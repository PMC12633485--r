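# Synthetic tomogram phantoms with known ground truth, emulating the
# appearance a particle picker faces: dark (or bright) particles of
# varied geometry on a noisy uniform background, optionally corrupted
# by an idealized missing wedge.

#' Phantom configuration
#'
#' @param shape Volume dimensions `(z, y, x)` in voxels.
#' @param voxel_size Voxel size in Angstrom per voxel.
#' @param n_particles Number of particles to place.
#' @param shape_mix Named proportions over `sphere`, `ellipsoid`,
#'   `rod`, `torus` (normalized internally). Elongated and toroidal
#'   shapes are the geometries hardest for centroid-based picking.
#' @param radius_range Min/max characteristic radius in voxels.
#' @param contrast Signed intensity offset added inside particles;
#'   negative (default) gives the dark-on-bright density convention of
#'   cryo-ET.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param min_separation Minimum distance between particle centers, voxels.
#' @param missing_wedge_deg Optional half-angle (degrees) of a Fourier
#'   wedge around the Z axis to zero out, mimicking the limited tilt
#'   range; `NULL` disables.
#' @param margin Exclusion border in voxels: particles are kept fully
#'   inside the volume minus this border (covers the feature margin).
#' @param seed Integer seed; the phantom is bit-reproducible given it.
#' @param max_attempts Rejection-sampling attempt budget for placement.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64L, 128L, 128L), voxel_size = 10,
                           n_particles = 40L,
                           shape_mix = c(sphere = 0.4, ellipsoid = 0.3,
                                         rod = 0.2, torus = 0.1),
                           radius_range = c(4, 7), contrast = -0.25,
                           noise_sigma = 0.15, min_separation = 16,
                           missing_wedge_deg = NULL, margin = 4L,
                           seed = 1L, max_attempts = 20000L) {
  stopifnot(length(shape) == 3, all(shape >= 1),
            length(radius_range) == 2, radius_range[1] <= radius_range[2],
            all(names(shape_mix) %in% c("sphere", "ellipsoid", "rod",
                                        "torus")))
  structure(
    list(shape = as.integer(shape), voxel_size = voxel_size,
         n_particles = as.integer(n_particles),
         shape_mix = shape_mix / sum(shape_mix),
         radius_range = radius_range, contrast = contrast,
         noise_sigma = noise_sigma, min_separation = min_separation,
         missing_wedge_deg = missing_wedge_deg, margin = as.integer(margin),
         seed = as.integer(seed), max_attempts = as.integer(max_attempts)),
    class = "phantom_config")
}

# uniform random rotation matrix from a uniform unit quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# inside test for a canonical shape of characteristic radius r, on
# rows of body-frame coordinates p (columns p1, p2, p3)
shape_inside <- function(kind, p, r) {
  switch(kind,
    sphere = rowSums(p^2) <= r^2,
    ellipsoid = (p[, 1] / r)^2 + (p[, 2] / (0.7 * r))^2 +
      (p[, 3] / (0.55 * r))^2 <= 1,
    rod = abs(p[, 1]) <= 1.4 * r & p[, 2]^2 + p[, 3]^2 <= (0.5 * r)^2,
    torus = (sqrt(p[, 1]^2 + p[, 2]^2) - 0.75 * r)^2 + p[, 3]^2 <=
      (0.35 * r)^2,
    stop("unknown shape kind: ", kind))
}

# outermost extent of a shape, used for placement feasibility
shape_extent <- function(kind, r) {
  switch(kind, sphere = r, ellipsoid = r, rod = sqrt((1.4 * r)^2 +
         (0.5 * r)^2), torus = 1.1 * r)
}

apply_missing_wedge <- function(vol, half_angle_deg) {
  d <- dim(vol)
  fr <- function(n) {
    f <- seq(0, n - 1) / n
    ifelse(f > 0.5, f - 1, f)
  }
  kz <- array(fr(d[1]), d)
  kx <- aperm(array(fr(d[3]), d[c(3, 2, 1)]), c(3, 2, 1))
  ang <- atan2(abs(kx), abs(kz)) * 180 / pi   # angle from the kz axis
  wedge <- ang <= half_angle_deg & !(kz == 0 & kx == 0)  # keep DC
  F <- fft(vol)
  F[wedge] <- 0
  Re(fft(F, inverse = TRUE)) / length(vol)
}

#' Generate a synthetic tomogram with known ground truth
#'
#' Particles are placed by rejection sampling (centers at least
#' `min_separation` apart, shapes fully inside the volume minus
#' `margin`), rendered analytically with a random orientation for
#' anisotropic shapes, summed onto a uniform 0.5 background; Gaussian
#' noise is added and, optionally, a Fourier-domain missing wedge is
#' zeroed. Deterministic given `cfg$seed`.
#'
#' @param cfg A [phantom_config()].
#' @return List with `tomogram` (a [tomogram()]), `particles` (the
#'   exact [particle_set()] of analytic centers, labeled by shape) and
#'   `config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  d <- cfg$shape
  with_seed(cfg$seed, {
    kinds <- if (cfg$n_particles > 0)
      sample(names(cfg$shape_mix), cfg$n_particles, replace = TRUE,
             prob = cfg$shape_mix)
    else character(0)
    radii <- runif(cfg$n_particles, cfg$radius_range[1], cfg$radius_range[2])
    centers <- matrix(0, cfg$n_particles, 3)
    placed <- 0L
    attempts <- 0L
    stuck <- 0L
    while (placed < cfg$n_particles) {
      if (attempts >= cfg$max_attempts)
        stop("could not place ", cfg$n_particles, " particles with ",
             "min_separation ", cfg$min_separation, " after ",
             cfg$max_attempts, " attempts")
      if (stuck >= 500L) {
        # early placements can block a feasible packing; restart the
        # configuration rather than retrying against a dead layout
        placed <- 0L
        stuck <- 0L
      }
      attempts <- attempts + 1L
      i <- placed + 1L
      ext <- shape_extent(kinds[i], radii[i]) + 1
      lo <- rep(cfg$margin + ext, 3)
      hi <- d - 1 - cfg$margin - ext
      if (any(hi < lo)) stop("volume too small for the requested particles")
      p <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]),
             runif(1, lo[3], hi[3]))
      ok <- placed == 0L ||
        min(colSums((t(centers[seq_len(placed), , drop = FALSE]) - p)^2)) >=
          cfg$min_separation^2
      if (ok) {
        centers[i, ] <- p
        placed <- i
        stuck <- 0L
      } else {
        stuck <- stuck + 1L
      }
    }
    vol <- array(0.5, d)
    for (i in seq_len(cfg$n_particles)) {
      rot <- random_rotation()
      ext <- ceiling(shape_extent(kinds[i], radii[i]) + 1)
      zr <- max(1, floor(centers[i, 1] - ext) + 1):min(d[1],
             ceiling(centers[i, 1] + ext) + 1)
      yr <- max(1, floor(centers[i, 2] - ext) + 1):min(d[2],
             ceiling(centers[i, 2] + ext) + 1)
      xr <- max(1, floor(centers[i, 3] - ext) + 1):min(d[3],
             ceiling(centers[i, 3] + ext) + 1)
      g <- expand.grid(z = zr - 1, y = yr - 1, x = xr - 1)
      rel <- sweep(as.matrix(g), 2, centers[i, ])
      body <- rel %*% rot    # rotate into the body frame
      ins <- shape_inside(kinds[i], body, radii[i])
      if (any(ins)) {
        lin <- g$z[ins] + 1 + d[1] * (g$y[ins]) + d[1] * d[2] * (g$x[ins])
        vol[lin] <- vol[lin] + cfg$contrast
      }
    }
    if (cfg$noise_sigma > 0)
      vol <- vol + array(rnorm(length(vol), 0, cfg$noise_sigma), d)
    if (!is.null(cfg$missing_wedge_deg))
      vol <- apply_missing_wedge(vol, cfg$missing_wedge_deg)
    list(
      tomogram = tomogram(vol, cfg$voxel_size,
                          source = sprintf("synthetic phantom (seed %d)",
                                           cfg$seed)),
      particles = particle_set(centers, cfg$voxel_size, labels = kinds),
      config = cfg)
  })
}

#' Canned phantom presets
#'
#' Four fixed-seed regimes spanning the situations a picker meets:
#' `sparse` (isolated particles, clean), `crowded` (3.5x the particle
#' count at tighter packing), `low_snr` (sparse geometry under heavy
#' noise) and `wedge` (sparse geometry plus a 30-degree missing
#' wedge).
#'
#' @param presets Subset of `c("sparse", "crowded", "low_snr", "wedge")`.
#' @return Named list of [generate_phantom()] results.
#' @export
phantom_suite <- function(presets = c("sparse", "crowded", "low_snr",
                                      "wedge")) {
  presets <- match.arg(presets, several.ok = TRUE)
  cfgs <- list(
    sparse = phantom_config(
      shape = c(48L, 96L, 96L), n_particles = 20L,
      shape_mix = c(sphere = 0.5, ellipsoid = 0.3, rod = 0.15,
                    torus = 0.05),
      radius_range = c(4, 7), noise_sigma = 0.1, min_separation = 18,
      seed = 101L),
    crowded = phantom_config(
      shape = c(48L, 96L, 96L), n_particles = 70L,
      shape_mix = c(sphere = 0.5, ellipsoid = 0.3, rod = 0.15,
                    torus = 0.05),
      radius_range = c(4, 6), noise_sigma = 0.15, min_separation = 11,
      seed = 202L),
    low_snr = phantom_config(
      shape = c(48L, 96L, 96L), n_particles = 20L,
      shape_mix = c(sphere = 0.5, ellipsoid = 0.3, rod = 0.15,
                    torus = 0.05),
      radius_range = c(4, 7), noise_sigma = 0.5, min_separation = 18,
      seed = 303L),
    wedge = phantom_config(
      shape = c(48L, 96L, 96L), n_particles = 20L,
      shape_mix = c(sphere = 0.5, ellipsoid = 0.3, rod = 0.15,
                    torus = 0.05),
      radius_range = c(4, 7), noise_sigma = 0.1, min_separation = 18,
      missing_wedge_deg = 30, seed = 404L))
  lapply(cfgs[presets], generate_phantom)
}
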