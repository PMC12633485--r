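# The sparse-preset benchmark run is expensive; compute it once and
# share it across test files. The watershed seed spacing is set to the
# phantom's known particle radius (radius range 4-7 voxels), which is
# how the tool is meant to be configured when the particle size is
# known.
.sparse_cache <- new.env(parent = emptyenv())

sparse_benchmark <- function() {
  if (!is.null(.sparse_cache$eval)) return(as.list(.sparse_cache))
  ph <- phantom_suite("sparse")$sparse
  cfg <- default_config()
  cfg$instances$min_seed_separation <- 5
  out <- run_all(ph$tomogram, cfg, seed = 3L)
  eval <- evaluate_run(out, ph$particles, threshold_angstrom = 100,
                       seed = 7L)
  .sparse_cache$phantom <- ph
  .sparse_cache$out <- out
  .sparse_cache$eval <- eval
  as.list(.sparse_cache)
}
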