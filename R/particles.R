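#' Particle coordinate sets
#'
#' A `particle_set` stores predicted or ground-truth particle centroids
#' as 0-based voxel coordinates `(z, y, x)` in the full-tomogram frame,
#' together with the voxel size so that Angstrom coordinates are always
#' derivable as `voxel coordinate * voxel size`. A centroid at the
#' center of voxel `(0, 0, 0)` is `(0, 0, 0)`.
#'
#' @param centroids_voxel Numeric matrix with columns `z, y, x`
#'   (0-based voxel coordinates), one row per particle.
#' @param voxel_size Voxel size in Angstrom per voxel.
#' @param labels Optional character vector of per-particle type labels.
#' @return A `particle_set` object.
#' @export
particle_set <- function(centroids_voxel, voxel_size, labels = NULL) {
  if (is.null(centroids_voxel) || length(centroids_voxel) == 0)
    centroids_voxel <- matrix(numeric(0), ncol = 3)
  centroids_voxel <- as.matrix(centroids_voxel)
  if (ncol(centroids_voxel) != 3)
    stop("`centroids_voxel` must have 3 columns (z, y, x)")
  colnames(centroids_voxel) <- c("z", "y", "x")
  stop_if_not_scalar_number(voxel_size, "voxel_size", positive = TRUE)
  if (!is.null(labels) && length(labels) != nrow(centroids_voxel))
    stop("`labels` length must match the number of particles")
  structure(
    list(centroids_voxel = centroids_voxel,
         voxel_size = as.numeric(voxel_size),
         labels = labels),
    class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles, %.3g A/voxel\n",
              n_particles(x), x$voxel_size))
  if (n_particles(x) > 0) print(head(x$centroids_voxel, 5))
  invisible(x)
}

#' Number of particles in a set
#' @param p A [particle_set()].
#' @return Integer count.
#' @export
n_particles <- function(p) nrow(p$centroids_voxel)

#' Centroids in Angstrom
#' @param p A [particle_set()].
#' @return Numeric matrix with columns `z, y, x` in Angstrom.
#' @export
centroids_angstrom <- function(p) p$centroids_voxel * p$voxel_size

#' Read particle centroids from a CSV/TSV file
#'
#' The file must have a header row with columns `x`, `y` and `z` (the
#' annotation-portal column order); extra columns are ignored except an
#' optional `label` column. The `units` flag states whether the file's
#' coordinates are voxels or Angstrom -- annotation sources differ and
#' guessing silently corrupts every downstream distance.
#'
#' @param path CSV (`,`) or TSV (tab) file; the delimiter is chosen by
#'   file extension (`.tsv`/`.tab` means tab).
#' @param voxel_size Voxel size in Angstrom per voxel.
#' @param units `"voxel"` or `"angstrom"`: unit of the file's x/y/z.
#' @return A [particle_set()].
#' @export
read_particles <- function(path, voxel_size, units = c("voxel", "angstrom")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  stop_if_not_scalar_number(voxel_size, "voxel_size", positive = TRUE)
  df <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE))
    read.delim(path, check.names = FALSE) else read.csv(path, check.names = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop("coordinate file must have columns x, y, z (found: ",
         paste(names(df), collapse = ", "), ")")
  if (nrow(df) == 0)
    return(particle_set(NULL, voxel_size = voxel_size))
  for (cn in need) {
    v <- df[[cn]]
    if (!is.numeric(v)) stop("non-numeric entries in column ", cn)
    if (any(!is.finite(v))) stop("non-finite entries in column ", cn)
    if (any(v < 0)) stop("negative coordinates in column ", cn)
  }
  cv <- cbind(z = df$z, y = df$y, x = df$x)
  if (units == "angstrom") cv <- cv / voxel_size
  labels <- if ("label" %in% names(df)) as.character(df$label) else NULL
  particle_set(cv, voxel_size = voxel_size, labels = labels)
}

#' Write particle centroids to a CSV file
#'
#' Columns `x,y,z` hold 0-based voxel coordinates and `x_ang,y_ang,z_ang`
#' the same positions in Angstrom; a `label` column is added when the set
#' carries labels.
#'
#' @param p A [particle_set()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_particles <- function(p, path) {
  stopifnot(inherits(p, "particle_set"))
  cv <- p$centroids_voxel
  ca <- centroids_angstrom(p)
  df <- data.frame(x = cv[, "x"], y = cv[, "y"], z = cv[, "z"],
                   x_ang = ca[, "x"], y_ang = ca[, "y"], z_ang = ca[, "z"])
  if (!is.null(p$labels)) df$label <- p$labels
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
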