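## Shared phantom builders used across test files.

## straight tube along +x on an isotropic grid
tube_scene <- function(n = 32L, radius = 2, dispersion = 0, voxel = 1) {
  grid <- voxel_grid(rep(n, 3), voxel)
  mid <- (n / 2 - 0.5) * voxel
  sc <- make_scene(list(bundle_spec(
    "tube",
    centreline_line(c(4, mid, mid) * voxel / 1, c((n - 5) * voxel, mid, mid)),
    radius = radius, dispersion = dispersion)), grid, rng_seed = 1L)
  sc
}

## two orthogonal straight bundles crossing at the grid centre
crossing_scene <- function(n = 20L) {
  grid <- voxel_grid(rep(n, 3), 1)
  mid <- n / 2 - 0.5
  make_scene(list(
    bundle_spec("bx", centreline_line(c(3, mid, mid), c(n - 4, mid, mid)),
                radius = 1.5, dispersion = 0),
    bundle_spec("by", centreline_line(c(mid, 3, mid), c(mid, n - 4, mid)),
                radius = 1.5, dispersion = 0)),
    grid, rng_seed = 1L)
}

## quick tracking parameters for small phantoms
quick_params <- function(n_streams = 50L, seed = 1L, ...) {
  tracking_params(step_size = 0.5, max_steps = 200L,
                  streamlines_per_seed_voxel = n_streams, rng_seed = seed, ...)
}

## independent termwise evaluation of the symmetric KL divergence (test
## oracle: a plain loop, kept separate from the package implementation)
skl_oracle <- function(m, h, delta = 1e-6) {
  total <- 0
  for (k in seq_along(m)) {
    mk <- m[k] + delta
    hk <- h[k] + delta
    total <- total + mk * log2(mk / hk) + hk * log2(hk / mk)
  }
  total
}
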