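# Shared fixtures: kept deliberately small so the default test run stays
# fast; scenes are built once per session and memoised here.

fixture_env <- new.env(parent = emptyenv())

# Default-geometry scene with a light cohort (3 subjects, shorter scan).
small_scene <- function() {
  if (is.null(fixture_env$small_scene)) {
    cfg <- scene_config(n_subjects = 3L, n_timepoints = 120L,
                        planned_window_tp = 55L, seed = 42L)
    fixture_env$small_scene <- build_scene(cfg)
  }
  fixture_env$small_scene
}

small_spec <- function() window_spec(55L, 1L)

# A tiny isotropic grid for geometry-level tests.
tiny_grid <- function(n = 12L, vox = 2) vox_grid(rep(n, 3L), voxel_size_mm = vox)

# Random streamlines inside a grid (world mm), for oracle comparisons.
random_streamlines <- function(n, grid, n_pts = 6L, seed = 1L,
                               margin_mm = 2) {
  lims <- t(voxel_to_world(grid, rbind(rep(1, 3), grid$dim)))
  lo <- pmin(lims[, 1], lims[, 2]) - margin_mm
  hi <- pmax(lims[, 1], lims[, 2]) + margin_mm
  twdfc:::with_seed(seed, lapply(seq_len(n), function(i) {
    cbind(runif(n_pts, lo[1], hi[1]),
          runif(n_pts, lo[2], hi[2]),
          runif(n_pts, lo[3], hi[3]))
  }))
}

# Independent dense-sampling voxelizer used as the traversal oracle.
oracle_voxelize <- function(s, grid, step_frac = 0.05) {
  step <- step_frac * min(grid$voxel_mm)
  pts <- list()
  for (i in seq_len(nrow(s) - 1L)) {
    a <- s[i, ]; b <- s[i + 1L, ]
    m <- max(1L, ceiling(sqrt(sum((b - a)^2)) / step))
    tt <- seq(0, 1, length.out = m + 1L)
    pts[[i]] <- cbind(a[1] + tt * (b[1] - a[1]),
                      a[2] + tt * (b[2] - a[2]),
                      a[3] + tt * (b[3] - a[3]))
  }
  idx <- world_to_voxel(grid, do.call(rbind, pts))
  idx <- idx[!is.na(idx[, 1]), , drop = FALSE]
  if (nrow(idx) == 0L) return(integer(0))
  sort(unique(twdfc:::voxel_linear(grid, idx)))
}
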