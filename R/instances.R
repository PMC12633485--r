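# Instance segmentation: binary particle mask -> labeled particle
# instances -> centroid predictions.

# Relabel raw instance labels contiguously 1..K in descending size
# order (ties by lower original label), dropping instances smaller than
# min_size voxels.
relabel_by_size <- function(labels_vec, min_size) {
  if (length(labels_vec) == 0 || max(labels_vec) == 0)
    return(list(labels = labels_vec, k = 0L))
  sizes <- tabulate(labels_vec)
  keep <- which(sizes >= max(1L, min_size))
  keep <- keep[order(-sizes[keep], keep)]
  map <- integer(length(sizes))
  map[keep] <- seq_along(keep)
  pos <- labels_vec > 0L
  labels_vec[pos] <- map[labels_vec[pos]]
  list(labels = labels_vec, k = length(keep))
}

instance_segmentation <- function(labels, k, algorithm, min_size, s) {
  structure(
    list(labels = labels, k = as.integer(k), algorithm = algorithm,
         min_size_voxels = as.integer(min_size),
         voxel_size = s$voxel_size, origin = s$origin),
    class = "instance_segmentation")
}

#' @export
print.instance_segmentation <- function(x, ...) {
  cat(sprintf("<instance_segmentation> %s: %d instances (min size %d)\n",
              x$algorithm, x$k, x$min_size_voxels))
  invisible(x)
}

#' Connected-component instance segmentation
#'
#' Labels maximal connected foreground components of the semantic mask.
#' Components smaller than `min_size_voxels` are removed (suppressing
#' single-voxel "dust"), and labels are renumbered contiguously in
#' descending size order so outputs are deterministic and diff-able.
#'
#' @param s A `semantic_segmentation`.
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners; default).
#' @param min_size_voxels Minimum instance size; 0 disables (default 5).
#' @return An `instance_segmentation`.
#' @export
connected_components <- function(s, connectivity = 26L, min_size_voxels = 5L) {
  stopifnot(inherits(s, "semantic_segmentation"))
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  d <- dim(s$mask)
  raw <- label_components_cpp(as.integer(s$mask), d, as.integer(connectivity))
  rl <- relabel_by_size(raw, min_size_voxels)
  instance_segmentation(array(rl$labels, d), rl$k, "cc", min_size_voxels, s)
}

# Local maxima of the distance map (>= all neighbors, 26-neighborhood),
# thinned greedily in descending height so accepted seeds within one
# connected component are at least min_sep apart. Each component always
# retains its strongest seed.
watershed_seeds <- function(dist, comp, d, min_sep) {
  arr <- array(dist, d)
  nb_max <- array(-Inf, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    z <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
    y <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    x <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
    sh <- arr[z, y, x, drop = FALSE]
    # clamped (self) samples at the faces can only tie, never exceed
    nb_max <- pmax(nb_max, sh)
  }
  cand <- which(dist > 0 & as.vector(arr >= nb_max))
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(-dist[cand], cand)]
  coords <- arrayInd(cand, d)
  ccomp <- comp[cand]
  acc <- logical(length(cand))
  min_sep2 <- min_sep^2
  for (cid in unique(ccomp)) {
    rows <- which(ccomp == cid)
    kept <- integer(0)
    for (r in rows) {
      p <- coords[r, ]
      if (length(kept) == 0 ||
          all(colSums((t(coords[kept, , drop = FALSE]) - p)^2) >= min_sep2)) {
        acc[r] <- TRUE
        kept <- c(kept, r)
      }
    }
  }
  cand[acc]
}

#' Watershed instance segmentation
#'
#' Separates touching particles: seeds are local maxima of the
#' Euclidean distance transform of the mask, thinned so that seeds
#' within one connected component are at least
#' `min_seed_separation_voxels` apart, then the negated distance map is
#' flooded from the seeds. Flooding is confined to each connected
#' component, so watershed refines, and never merges, the
#' connected-component partition. Size filtering and descending-size
#' relabeling as in [connected_components()].
#'
#' @param s A `semantic_segmentation`.
#' @param min_seed_separation_voxels Minimum seed spacing; a sensible
#'   choice is the expected particle radius in voxels (default 3).
#' @param min_size_voxels Minimum instance size (default 5).
#' @param connectivity Neighborhood connectivity (default 26).
#' @return An `instance_segmentation`.
#' @export
watershed_instances <- function(s, min_seed_separation_voxels = 3,
                                min_size_voxels = 5L, connectivity = 26L) {
  stopifnot(inherits(s, "semantic_segmentation"))
  d <- dim(s$mask)
  mask_vec <- as.integer(s$mask)
  comp <- label_components_cpp(mask_vec, d, as.integer(connectivity))
  if (max(comp) == 0)
    return(instance_segmentation(array(0L, d), 0L, "ws", min_size_voxels, s))
  dist <- edt3d_cpp(mask_vec, d)
  seeds <- watershed_seeds(dist, comp, d, min_seed_separation_voxels)
  raw <- watershed_flood_cpp(dist, comp, seeds, d, as.integer(connectivity))
  rl <- relabel_by_size(raw, min_size_voxels)
  instance_segmentation(array(rl$labels, d), rl$k, "ws", min_size_voxels, s)
}

#' Extract instance centroids as particle predictions
#'
#' Computes the geometric (unweighted mean) centroid of every instance
#' in the full-tomogram frame (crop offsets added). When `z_bounds` is
#' given, instances whose centroid falls outside the half-open
#' `[zmin, zmax)` slab are dropped -- used to limit picks to the
#' lamella.
#'
#' @param i An `instance_segmentation`.
#' @param z_bounds Optional full-frame voxel Z bounds.
#' @return A [particle_set()] (0-based voxel coordinates).
#' @export
extract_centroids <- function(i, z_bounds = NULL) {
  stopifnot(inherits(i, "instance_segmentation"))
  if (i$k == 0)
    return(particle_set(NULL, voxel_size = i$voxel_size))
  idx <- which(i$labels > 0L)
  lab <- i$labels[idx]
  co <- arrayInd(idx, dim(i$labels)) - 1   # 0-based (z, y, x)
  cnt <- tabulate(lab, nbins = i$k)
  cen <- rowsum(co, lab) / cnt
  cen <- sweep(cen, 2, as.numeric(i$origin), `+`)
  colnames(cen) <- c("z", "y", "x")
  if (!is.null(z_bounds)) {
    if (length(z_bounds) != 2 || z_bounds[1] >= z_bounds[2])
      stop("`z_bounds` must be an increasing pair")
    cen <- cen[cen[, "z"] >= z_bounds[1] & cen[, "z"] < z_bounds[2], ,
               drop = FALSE]
  }
  particle_set(cen, voxel_size = i$voxel_size)
}
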