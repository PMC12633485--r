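#' Tomogram volumes
#'
#' A `tomogram` is a 3D scalar grid indexed `(z, y, x)` together with its
#' isotropic voxel size in Angstrom per voxel, the voxel offset of the
#' volume within its parent (non-zero for crops, so that coordinates can
#' always be reported in the full-tomogram frame), and free-text
#' provenance.
#'
#' @param data 3D numeric array indexed `(z, y, x)`.
#' @param voxel_size Voxel edge length in Angstrom (single positive number).
#' @param origin Integer `(z, y, x)` offset of this volume within its
#'   parent volume; `c(0, 0, 0)` for a full tomogram.
#' @param source Free-text provenance string.
#' @return A `tomogram` object.
#' @examples
#' t <- tomogram(array(rnorm(8 * 8 * 8), c(8, 8, 8)), voxel_size = 10)
#' dim(t)
#' @export
tomogram <- function(data, voxel_size, origin = c(0L, 0L, 0L), source = "") {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("`data` must be a 3D array indexed (z, y, x)", call. = FALSE)
  if (any(dim(data) < 1)) stop("all tomogram dimensions must be >= 1")
  stop_if_not_scalar_number(voxel_size, "voxel_size", positive = TRUE)
  if (length(origin) != 3 || any(origin < 0))
    stop("`origin` must be a non-negative (z, y, x) integer triple")
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.integer(origin), source = as.character(source)),
    class = "tomogram")
}

#' @export
dim.tomogram <- function(x) dim(x$data)

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tomogram> %d x %d x %d voxels (z,y,x), %.3g A/voxel",
              d[1], d[2], d[3], x$voxel_size))
  if (any(x$origin != 0))
    cat(sprintf(", origin (z,y,x) = (%d,%d,%d)", x$origin[1], x$origin[2],
                x$origin[3]))
  if (nzchar(x$source)) cat("\n  source: ", x$source, sep = "")
  cat("\n")
  invisible(x)
}

#' Read a tomogram from an MRC2014 file
#'
#' Axes are reordered to the internal `(z, y, x)` convention (MRC stores
#' x fastest). The voxel size is taken from the header cell dimensions
#' unless overridden. Anisotropic header voxel sizes are rejected unless
#' equal within 1%, in which case their mean is used: the downstream
#' distance thresholds assume a single scalar voxel size.
#'
#' @param path Path to an MRC/MRC2014 file.
#' @param voxel_size_override Optional positive number replacing the
#'   header voxel size (required when the header voxel size is absent or
#'   non-positive).
#' @return A [tomogram()].
#' @export
read_tomogram <- function(path, voxel_size_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- .mrc_read(path)
  if (length(dim(m$data)) != 3 || any(dim(m$data) < 1))
    stop("not a 3D volume: ", path)
  if (!is.null(voxel_size_override)) {
    stop_if_not_scalar_number(voxel_size_override, "voxel_size_override",
                              positive = TRUE)
    vs <- voxel_size_override
  } else {
    v <- m$voxel_size_xyz
    if (any(is.na(v)) || any(v <= 0))
      stop("MRC header has no usable voxel size; pass `voxel_size_override`")
    if ((max(v) - min(v)) / mean(v) > 0.01)
      stop(sprintf(paste0("anisotropic voxel size (%.4g, %.4g, %.4g) A ",
                          "differs by more than 1%%; only isotropic voxels ",
                          "are supported"), v[1], v[2], v[3]))
    vs <- mean(v)
  }
  tomogram(m$data, voxel_size = vs,
           origin = rev(m$origin_voxel_xyz),
           source = normalizePath(path))
}

#' Write a tomogram to an MRC2014 file
#'
#' Volumes are written as 32-bit float by default; semantic masks fit
#' `mode = "int8"` and instance labels `mode = "int16"`. The crop origin
#' is recorded both as `nxstart/nystart/nzstart` (voxels) and in the
#' header origin fields (Angstrom).
#'
#' @param t A [tomogram()].
#' @param path Destination path.
#' @param mode One of `"float32"`, `"int8"`, `"int16"`.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(t, path, mode = "float32") {
  stopifnot(inherits(t, "tomogram"))
  .mrc_write(t$data, t$voxel_size, t$origin, path, mode = mode)
  invisible(path)
}
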