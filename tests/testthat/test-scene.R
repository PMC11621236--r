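test_that("scene construction is bit-reproducible for a fixed seed", {
  cfg <- scene_config(n_subjects = 2L, n_timepoints = 110L, seed = 5L)
  a <- build_scene(cfg)
  b <- build_scene(cfg)
  expect_identical(a$bold, b$bold)
  expect_identical(unclass(a$streamlines), unclass(b$streamlines))
  expect_identical(a$truth_left, b$truth_left)
  expect_identical(a$wm_mask, b$wm_mask)
})

test_that("configuration invariants are enforced", {
  expect_error(scene_config(k_true = 1), "k_true")
  expect_error(scene_config(n_timepoints = 100, planned_window_tp = 55),
               "twice")
  expect_error(scene_config(coupling_amplitude = 1.2), "coupling_amplitude")
  expect_error(scene_config(coupling_amplitude = 0.9,
                            right_coupling_scale = 2), "right")
  expect_error(scene_config(grid_shape = c(16, 24, 24)), "grid_shape")
  expect_error(scene_config(noise_sd = -1), "noise_sd")
  # too few streamlines to cover every seed voxel
  expect_error(build_scene(scene_config(n_streamlines_per_cluster = 10L)),
               "streamlines_per_cluster")
})

test_that("planted geometry satisfies the scene contract", {
  scene <- small_scene()
  cfg <- scene$config
  grid <- scene$grid
  # truth labels cover every ROI voxel exactly once
  expect_true(all(scene$truth_left[scene$roi_left] %in% seq_len(cfg$k_true)))
  expect_true(all(scene$truth_left[!scene$roi_left] == 0L))
  expect_setequal(unique(scene$truth_left[scene$roi_left]),
                  seq_len(cfg$k_true))
  # mirrored hemispheres
  expect_identical(scene$truth_right, mirror_x(scene$truth_left))
  expect_identical(scene$roi_right, mirror_x(scene$roi_left))
  # every streamline starts in its cluster's seed block and ends in its
  # designated target territory
  for (i in seq_along(scene$streamlines)) {
    s <- scene$streamlines[[i]]
    h <- scene$streamline_hemi[i]; c <- scene$streamline_cluster[i]
    truth <- scene[[paste0("truth_", h)]]
    first <- world_to_voxel(grid, s[1, , drop = FALSE])
    last <- world_to_voxel(grid, s[nrow(s), , drop = FALSE])
    expect_equal(truth[first], c, ignore_attr = TRUE)
    expect_true(scene$target_regions[[h]][[c]][last])
  }
})

test_that("white-matter mask excludes the dilated seed", {
  scene <- small_scene()
  grid <- scene$grid
  roi_idx <- rbind(which(scene$roi_left, arr.ind = TRUE),
                   which(scene$roi_right, arr.ind = TRUE))
  wm_idx <- which(scene$wm_mask, arr.ind = TRUE)
  # distance-transform style check: no in-mask voxel centre within the
  # dilation radius (2 voxels = 4 mm) of any seed voxel centre
  vox <- grid$voxel_mm
  mind <- min(vapply(seq_len(nrow(wm_idx)), function(r) {
    min(colSums((t(roi_idx) - wm_idx[r, ])^2 * vox^2))
  }, numeric(1)))
  expect_gt(sqrt(mind), 4)
  expect_gt(sum(scene$wm_mask), 0)
})

test_that("zero coupling leaves endpoint correlations at noise level", {
  cfg <- scene_config(n_subjects = 1L, n_timepoints = 110L,
                      coupling_amplitude = 0, seed = 6L)
  scene <- build_scene(cfg)
  spec <- window_spec(55L, 1L)
  tw <- subject_twdfc(scene, 1, spec)
  # per-streamline mean windowed FC stays below 3/sqrt(window length)
  ep <- scene$index$endpoints
  picked <- seq(1, nrow(ep), by = 17)
  for (i in picked) {
    fc <- windowed_endpoint_fc(scene$bold[[1]], ep[i, ], spec)
    expect_lt(abs(mean(fc)), 3 / sqrt(spec$length_tp))
  }
})

test_that("noise-free scenes track the planted coupling profile", {
  cfg <- scene_config(n_subjects = 1L, noise_sd = 0, seed = 7L)
  scene <- build_scene(cfg)
  spec <- window_spec(55L, 1L)
  W <- make_windows(cfg$n_timepoints, spec)
  wmean <- function(r) vapply(seq_len(nrow(W)),
                              function(w) mean(r[W[w, 1]:W[w, 2]]),
                              numeric(1))
  bm <- matrix(scene$bold[[1]], nrow = prod(scene$grid$dim))
  A <- t(bm[scene$index$endpoints[, 1], , drop = FALSE])
  B <- t(bm[scene$index$endpoints[, 2], , drop = FALSE])
  fc <- twdfc:::rolling_cor(A, B, spec)
  cors <- vapply(seq_len(ncol(fc)), function(i) {
    h <- scene$streamline_hemi[i]; c <- scene$streamline_cluster[i]
    cor(fc[, i], wmean(scene$r_profiles[[h]][c, ]))
  }, numeric(1))
  # each windowed series has only ~T/L independent windows, so individual
  # tracking estimates scatter around ~0.93; the cohort as a whole must
  # track tightly and no streamline may decouple
  expect_gte(stats::median(cors), 0.9)
  expect_gte(min(cors), 0.8)
})

test_that("Gaussian smoothing preserves constants, mass and the identity case", {
  grid <- tiny_grid(12, 2)
  arr <- array(twdfc:::with_seed(8, rnorm(prod(grid$dim))), grid$dim)
  expect_identical(smooth_bold(arr, 0, grid), arr)
  expect_error(smooth_bold(arr, -1, grid), "non-negative")
  const <- array(2.5, grid$dim)
  expect_equal(smooth_bold(const, 6, grid), const, tolerance = 1e-12)
  # interior impulse keeps its mass with fwhm = 2 voxels (grid large
  # enough that the kernel support stays clear of the boundary zone)
  big <- tiny_grid(20, 2)
  imp <- array(0, big$dim)
  imp[10, 10, 10] <- 1
  sm <- smooth_bold(imp, 2 * big$voxel_mm[1], big)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # 4D smoothing operates frame by frame
  arr4 <- array(rnorm(prod(grid$dim) * 2), c(grid$dim, 2))
  sm4 <- smooth_bold(arr4, 4, grid)
  expect_equal(sm4[, , , 1], smooth_bold(arr4[, , , 1], 4, grid))
})

test_that("scene export writes readable NIfTI, TCK and sidecar files", {
  dir <- withr::local_tempdir()
  cfg <- scene_config(n_subjects = 2L, n_timepoints = 110L, seed = 9L)
  scene <- build_scene(cfg)
  write_scene(scene, dir)
  expect_true(file.exists(file.path(dir, "bold_sub01.nii")))
  bold <- read_image(file.path(dir, "bold_sub01.nii"))
  expect_equal(dim(bold$data), c(scene$grid$dim, cfg$n_timepoints))
  expect_equal(bold$tr_s, cfg$tr_s, tolerance = 1e-6)
  expect_equal(bold$data, scene$bold[[1]], tolerance = 1e-5)
  ss <- read_tck(file.path(dir, "streamlines.tck"))
  expect_length(ss, length(scene$streamlines))
  side <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  expect_equal(side$config$seed, 9)
  expect_equal(side$truth_left,
               as.integer(scene$truth_left[scene$roi_left]))
  roi <- read_image(file.path(dir, "roi_left.nii"))
  expect_equal(array(roi$data > 0, dim = scene$grid$dim), scene$roi_left)
})
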