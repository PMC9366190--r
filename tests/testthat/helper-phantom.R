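# Small, fast phantom specifications shared across tests.

small_spec <- function(defects = list(), seed = 1L, n_frames = 6L,
                       contraction = 0.8, grid = 40L, vox = 2.5) {
  phantom_spec(grid_shape = rep(grid, 3L), voxel_size = rep(vox, 3L),
               n_frames = n_frames, base_radii = c(22, 38),
               global_contraction = contraction, noise_sd = 20,
               defects = defects, seed = seed)
}

# a voxelised sphere mask of the given radius (mm), centred in the grid
sphere_mask <- function(radius_mm, grid = 48L, vox = 1.5) {
  ctr <- (grid - 1) * vox / 2
  ax <- (seq_len(grid) - 1) * vox - ctr
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  array(r2 <= radius_mm^2, rep(grid, 3L))
}

# seeded feature matrices for two well-separated Gaussian classes
separable_features <- function(n, delta = 0.3, seed = 2L) {
  withr::with_seed(seed, {
    mats <- lapply(seq_len(n), function(i) {
      cls <- i <= n / 2
      m <- matrix(stats::rnorm(4 * 2048, mean = if (cls) delta else -delta),
                  4, 2048)
      structure(m, class = c("feature_matrix", "matrix"))
    })
    list(mats = mats, labels = rep(c(TRUE, FALSE), each = n / 2))
  })
}
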