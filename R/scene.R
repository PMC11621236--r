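#' Configuration of a synthetic tw-dFC scene
#'
#' Defines a multi-subject synthetic dataset with the statistical structure
#' the tw-dFC parcellation pipeline assumes: two mirrored seed ROIs, each
#' partitioned into `k_true` planted clusters, streamlines connecting every
#' cluster to its own target territory, and BOLD whose endpoint coupling is
#' modulated in time by a cluster-specific sinusoid
#' `r_c(t) = amplitude * (1 + sin(2*pi*t/period + phi_c)) / 2`
#' with distinct phases `phi_c`, plus i.i.d. Gaussian voxel noise.
#'
#' @param grid_shape voxels per axis; each axis must be >= 24 so the
#'   mirrored layout fits. Default 24^3.
#' @param voxel_size_mm isotropic voxel edge, mm.
#' @param tr_s repetition time, seconds.
#' @param n_timepoints BOLD length; must be at least twice
#'   `planned_window_tp`.
#' @param n_subjects number of simulated subjects.
#' @param k_true planted cluster count (>= 2).
#' @param n_streamlines_per_cluster streamlines per cluster per hemisphere;
#'   must reach the largest planted cluster's voxel count so every seed
#'   voxel is traversed.
#' @param coupling_amplitude peak endpoint correlation, in [0, 1].
#' @param coupling_period_s period of the coupling modulation, seconds.
#' @param noise_sd voxel noise standard deviation, in units of the
#'   unit-variance latent signals.
#' @param right_coupling_scale multiplier on the right-hemisphere coupling
#'   amplitude (asymmetry knob for lateralization experiments); the scaled
#'   amplitude must stay within [0, 1].
#' @param planned_window_tp sliding-window length (timepoints) the scene is
#'   sized for; used for validation only.
#' @param seed integer seed; the scene is bit-reproducible given the
#'   configuration.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(grid_shape = c(24L, 24L, 24L),
                         voxel_size_mm = 2,
                         tr_s = 0.72,
                         n_timepoints = 450L,
                         n_subjects = 20L,
                         k_true = 4L,
                         n_streamlines_per_cluster = 54L,
                         coupling_amplitude = 0.9,
                         coupling_period_s = 140,
                         noise_sd = 0.5,
                         right_coupling_scale = 1,
                         planned_window_tp = 55L,
                         seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm,
              tr_s = tr_s,
              n_timepoints = as.integer(n_timepoints),
              n_subjects = as.integer(n_subjects),
              k_true = as.integer(k_true),
              n_streamlines_per_cluster = as.integer(n_streamlines_per_cluster),
              coupling_amplitude = coupling_amplitude,
              coupling_period_s = coupling_period_s,
              noise_sd = noise_sd,
              right_coupling_scale = right_coupling_scale,
              planned_window_tp = as.integer(planned_window_tp),
              seed = as.integer(seed))
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 24L)) {
    stop("grid_shape must be three values >= 24")
  }
  if (cfg$k_true < 2L) stop("k_true must be >= 2")
  if (cfg$n_timepoints < 2L * cfg$planned_window_tp) {
    stop("n_timepoints must be at least twice the planned window length")
  }
  if (cfg$coupling_amplitude < 0 || cfg$coupling_amplitude > 1) {
    stop("coupling_amplitude must be in [0, 1]")
  }
  amp_r <- cfg$coupling_amplitude * cfg$right_coupling_scale
  if (amp_r < 0 || amp_r > 1) {
    stop("right-hemisphere coupling amplitude out of [0, 1]; ",
         "reduce coupling_amplitude or right_coupling_scale")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1")
  if (cfg$tr_s <= 0 || cfg$coupling_period_s <= 0 || cfg$voxel_size_mm <= 0) {
    stop("tr_s, coupling_period_s and voxel_size_mm must be positive")
  }
  structure(cfg, class = "scene_config")
}

# Fixed scene layout in 0-based voxel coordinates, mirrored about the
# mid-sagittal plane. The left seed ROI is a 6x6x6 block; planted clusters
# tile its (y, z) cross-section; each cluster's target territory is a 4x4
# column near the left x-face, positioned by scaling the cluster's (y, z)
# centre away from the ROI centre so the territories are disjoint.
scene_layout <- function(cfg) {
  n <- cfg$grid_shape
  k <- cfg$k_true
  roi_i <- 5:10
  roi_j <- (floor((n[2] - 6) / 2)):(floor((n[2] - 6) / 2) + 5)
  roi_k <- (floor((n[3] - 6) / 2)):(floor((n[3] - 6) / 2) + 5)
  g_j <- floor(sqrt(k)); g_k <- ceiling(k / g_j)
  bin_of <- function(vals, g) {
    # split a contiguous index range into g near-equal bins
    cuts <- round(seq(0, length(vals), length.out = g + 1L))
    findInterval(seq_along(vals) - 1L, cuts[-length(cuts)])
  }
  jb <- bin_of(roi_j, g_j); kb <- bin_of(roi_k, g_k)
  vox <- expand.grid(i = roi_i, j = roi_j, k = roi_k)
  cell <- (kb[match(vox$k, roi_k)] - 1L) * g_j + jb[match(vox$j, roi_j)]
  cluster <- pmin(cell, k)
  # target centres: cluster (y, z) centres pushed away from the ROI centre
  cy <- (n[2] - 1) / 2; cz <- (n[3] - 1) / 2
  tctr <- t(vapply(seq_len(k), function(c) {
    sel <- cluster == c
    c(mean(vox$j[sel]), mean(vox$k[sel]))
  }, numeric(2)))
  tj <- floor(cy + 3.5 * (tctr[, 1] - cy) + 0.5)
  tk <- floor(cz + 3.5 * (tctr[, 2] - cz) + 0.5)
  tj <- pmin(pmax(tj, 3L), n[2] - 4L)
  tk <- pmin(pmax(tk, 3L), n[3] - 4L)
  targets <- lapply(seq_len(k), function(c) {
    list(i = 1:3, j = (tj[c] - 2L):(tj[c] + 1L), k = (tk[c] - 2L):(tk[c] + 1L))
  })
  # synthetic "atlas nuclei": an offset second partition of the ROI,
  # slabs along z, so atlas-overlap code sees non-trivial values
  nb <- bin_of(roi_k, k)
  nucleus <- nb[match(vox$k, roi_k)]
  list(roi = vox, cluster = cluster, targets = targets, nucleus = nucleus,
       mirror_i = function(i0) n[1] - 1L - i0)
}

#' Build a synthetic scene
#'
#' Generates the full multi-subject dataset described by a
#' [scene_config()]: BOLD volumes, mirrored seed ROIs with planted cluster
#' labels, per-cluster target territories, streamlines connecting each
#' cluster to its territory, a white-matter mask consistent with the
#' parcellation contract, a synthetic atlas partition, and the planted
#' coupling profiles.
#'
#' @param cfg a [scene_config()].
#' @return object of class `synthetic_scene`; see Details.
#' @details The returned list contains `config`, `grid`, `bold` (list of
#'   4D arrays, one per subject), `roi_left`/`roi_right` (logical),
#'   `truth_left`/`truth_right` (integer labels, 0 = background),
#'   `atlas_labels`, `wm_prob` (white-matter probability map),
#'   `wm_mask` (after thresholding and seed-dilation subtraction),
#'   `streamlines` ([streamline_set()]), `streamline_cluster`,
#'   `streamline_hemi`, `target_regions` (`$left`/`$right`, lists of
#'   logical arrays per cluster), `r_profiles` (`$left`/`$right`, k x T
#'   matrices of planted coupling), and `index` (traversal index).
#' @export
build_scene <- function(cfg) {
  if (!inherits(cfg, "scene_config")) stop("cfg must be a scene_config")
  grid <- vox_grid(cfg$grid_shape, voxel_size_mm = cfg$voxel_size_mm)
  lay <- scene_layout(cfg)
  k <- cfg$k_true
  Tn <- cfg$n_timepoints

  as_mask <- function(ijk0) {
    m <- array(FALSE, dim = grid$dim)
    m[as.matrix(ijk0) + 1L] <- TRUE
    m
  }
  roi_left_idx0 <- as.matrix(lay$roi)
  roi_right_idx0 <- roi_left_idx0
  roi_right_idx0[, 1] <- lay$mirror_i(roi_left_idx0[, 1])
  roi_left <- as_mask(roi_left_idx0)
  roi_right <- as_mask(roi_right_idx0)

  lab_arr <- function(idx0, labels) {
    a <- array(0L, dim = grid$dim)
    a[idx0 + 1L] <- as.integer(labels)
    a
  }
  truth_left <- lab_arr(roi_left_idx0, lay$cluster)
  truth_right <- lab_arr(roi_right_idx0, lay$cluster)
  atlas_labels <- lab_arr(rbind(roi_left_idx0, roi_right_idx0),
                          c(lay$nucleus, lay$nucleus))

  target_block <- function(tg, mirror = FALSE) {
    g <- expand.grid(i = tg$i, j = tg$j, k = tg$k)
    if (mirror) g$i <- lay$mirror_i(g$i)
    as.matrix(g)
  }
  targets_left <- lapply(lay$targets, target_block)
  targets_right <- lapply(lay$targets, target_block, mirror = TRUE)
  target_regions <- list(left = lapply(targets_left, as_mask),
                         right = lapply(targets_right, as_mask))

  # geometric consistency: seed ROIs and target territories must be
  # pairwise disjoint
  all_regions <- c(list(roi_left, roi_right),
                   target_regions$left, target_regions$right)
  counts <- Reduce(`+`, lapply(all_regions, function(m) m * 1L))
  if (any(counts > 1L)) stop("scene configuration error: regions overlap")

  seeds <- spawn_seeds(cfg$seed, 3L)

  # --- streamlines -------------------------------------------------------
  # Left-hemisphere bundles are generated; the right hemisphere is their
  # exact reflection, so the two hemispheres are geometrically homotopic
  # (a prerequisite for a well-calibrated lateralization null). Each
  # cluster's streamlines funnel through two waypoints - one at the seed's
  # target-facing border, one at the territory's near face - so they form
  # a compact bundle rather than a broad fan, as converging fiber tracts
  # do.
  streamlines <- list(); sl_cluster <- integer(); sl_hemi <- character()
  with_seed(seeds[1], {
    for (c in seq_len(k)) {
      src <- roi_left_idx0[lay$cluster == c, , drop = FALSE]
      if (cfg$n_streamlines_per_cluster < nrow(src)) {
        stop("n_streamlines_per_cluster (", cfg$n_streamlines_per_cluster,
             ") is below cluster ", c, " size (", nrow(src),
             "); every seed voxel needs a streamline")
      }
      tgt <- lay$targets[[c]]
      w1 <- c(min(src[, 1]) - 1, mean(src[, 2]), mean(src[, 3]))
      w2 <- c(max(tgt$i) + 0.5, mean(tgt$j), mean(tgt$k))
      for (m in seq_len(cfg$n_streamlines_per_cluster)) {
        s0 <- src[((m - 1L) %% nrow(src)) + 1L, ]
        t0 <- targets_left[[c]][((m - 1L) %% nrow(targets_left[[c]])) + 1L, ]
        streamlines[[length(streamlines) + 1L]] <-
          jittered_path(s0, t0, grid, waypoints0 = rbind(w1, w2))
        sl_cluster <- c(sl_cluster, c)
        sl_hemi <- c(sl_hemi, "left")
      }
    }
  })
  n_left <- length(streamlines)
  mirror_world <- function(s) { s[, 1] <- -s[, 1]; s }
  streamlines <- c(streamlines, lapply(streamlines, mirror_world))
  sl_cluster <- c(sl_cluster, sl_cluster)
  sl_hemi <- c(sl_hemi, rep("right", n_left))
  ss <- streamline_set(streamlines)
  index <- build_traversal_index(ss, grid)
  stopifnot(index$n_excluded == 0L)

  # --- white matter mask -------------------------------------------------
  wm_prob <- array(0, dim = grid$dim)
  wm_prob[unique(unlist(index$streamline_voxels, use.names = FALSE))] <- 1
  for (m in c(target_regions$left, target_regions$right)) wm_prob[m] <- 1
  wm_mask <- make_wm_mask(list(wm_prob), list(roi_left, roi_right),
                          grid, dilation_mm = 2 * cfg$voxel_size_mm)

  # --- planted coupling profiles ----------------------------------------
  tt <- (seq_len(Tn) - 1L) * cfg$tr_s
  phi <- 2 * pi * (seq_len(k) - 1L) / k
  amp <- c(left = cfg$coupling_amplitude,
           right = cfg$coupling_amplitude * cfg$right_coupling_scale)
  r_profiles <- lapply(amp, function(a) {
    t(vapply(seq_len(k), function(c) {
      a * 0.5 * (1 + sin(2 * pi * tt / cfg$coupling_period_s + phi[c]))
    }, numeric(Tn)))
  })
  names(r_profiles) <- names(amp)

  # --- BOLD --------------------------------------------------------------
  roi_lin <- list(left = voxel_linear(grid, roi_left_idx0 + 1L),
                  right = voxel_linear(grid, roi_right_idx0 + 1L))
  tg_lin <- list(left = lapply(targets_left,
                               function(x) voxel_linear(grid, x + 1L)),
                 right = lapply(targets_right,
                                function(x) voxel_linear(grid, x + 1L)))
  nxyz <- prod(grid$dim)
  bold <- with_seed(seeds[2], {
    lapply(seq_len(cfg$n_subjects), function(s) {
      bm <- matrix(stats::rnorm(nxyz * Tn), nrow = nxyz)
      for (hemi in c("left", "right")) {
        for (c in seq_len(k)) {
          u <- stats::rnorm(Tn)
          w <- stats::rnorm(Tn)
          r <- r_profiles[[hemi]][c, ]
          v <- r * u + sqrt(pmax(0, 1 - r^2)) * w
          rv <- roi_lin[[hemi]][lay$cluster == c]
          tv <- tg_lin[[hemi]][[c]]
          bm[rv, ] <- matrix(u, length(rv), Tn, byrow = TRUE) +
            cfg$noise_sd * stats::rnorm(length(rv) * Tn)
          bm[tv, ] <- matrix(v, length(tv), Tn, byrow = TRUE) +
            cfg$noise_sd * stats::rnorm(length(tv) * Tn)
        }
      }
      array(bm, dim = c(grid$dim, Tn))
    })
  })

  structure(list(config = cfg, grid = grid, bold = bold,
                 roi_left = roi_left, roi_right = roi_right,
                 truth_left = truth_left, truth_right = truth_right,
                 atlas_labels = atlas_labels,
                 wm_prob = wm_prob, wm_mask = wm_mask,
                 streamlines = ss,
                 streamline_cluster = sl_cluster,
                 streamline_hemi = sl_hemi,
                 target_regions = target_regions,
                 r_profiles = r_profiles,
                 index = index),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("synthetic_scene:", x$config$n_subjects, "subjects,",
      x$config$k_true, "planted clusters,",
      length(x$streamlines), "streamlines on a",
      paste(x$grid$dim, collapse = "x"), "grid\n")
  invisible(x)
}

# A gently jittered piecewise-linear path from a seed voxel to a target
# voxel (0-based indices), optionally routed through waypoints given in
# 0-based continuous voxel coordinates. Control points are ~1 voxel
# apart; the endpoints are snapped inside their voxels.
jittered_path <- function(src0, dst0, grid, waypoints0 = NULL) {
  vx <- min(grid$voxel_mm)
  a <- as.numeric(voxel_to_world(grid, matrix(src0 + 1L, 1))) +
    stats::runif(3, -0.3, 0.3) * vx
  b <- as.numeric(voxel_to_world(grid, matrix(dst0 + 1L, 1))) +
    stats::runif(3, -0.3, 0.3) * vx
  knots <- rbind(a)
  if (!is.null(waypoints0)) {
    wp <- t(grid$affine %*% rbind(t(waypoints0), 1))[, 1:3, drop = FALSE]
    wp <- wp + matrix(stats::runif(length(wp), -0.2, 0.2) * vx,
                      nrow(wp), 3)
    knots <- rbind(knots, wp)
  }
  knots <- rbind(knots, b)
  segs <- list()
  for (i in seq_len(nrow(knots) - 1L)) {
    p <- knots[i, ]; q <- knots[i + 1L, ]
    n <- max(2L, ceiling(sqrt(sum((q - p)^2)) / vx) + 1L)
    tt <- seq(0, 1, length.out = n)
    if (i < nrow(knots) - 1L) tt <- tt[-n]
    segs[[i]] <- cbind(p[1] + tt * (q[1] - p[1]),
                       p[2] + tt * (q[2] - p[2]),
                       p[3] + tt * (q[3] - p[3]))
  }
  pts <- do.call(rbind, segs)
  n <- nrow(pts)
  if (n > 2L) {
    jit <- matrix(stats::rnorm(3 * (n - 2L), sd = 0.15 * vx), ncol = 3)
    pts[2:(n - 1L), ] <- pts[2:(n - 1L), ] + jit
  }
  pts
}

#' Write a scene to disk
#'
#' Exports the scene in the formats the pipeline consumes: per-subject 4D
#' BOLD NIfTI, mask/label NIfTIs, a TCK streamline file and a JSON sidecar
#' with the configuration and planted labels.
#'
#' @param scene a [build_scene()] result.
#' @param dir output directory (created if needed).
#' @param datatype NIfTI storage type for BOLD (default `"float"` for
#'   compactness).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, datatype = "float") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- scene$grid
  for (s in seq_along(scene$bold)) {
    write_image(scene$bold[[s]],
                file.path(dir, sprintf("bold_sub%02d.nii", s)),
                grid = g, tr_s = scene$config$tr_s, datatype = datatype)
  }
  vols <- list(roi_left = scene$roi_left * 1, roi_right = scene$roi_right * 1,
               truth_left = scene$truth_left, truth_right = scene$truth_right,
               atlas_labels = scene$atlas_labels,
               wm_prob = scene$wm_prob, wm_mask = scene$wm_mask * 1)
  for (nm in names(vols)) {
    write_image(array(as.numeric(vols[[nm]]), dim = g$dim),
                file.path(dir, paste0(nm, ".nii")), grid = g)
  }
  write_tck(scene$streamlines, file.path(dir, "streamlines.tck"))
  sidecar <- list(config = unclass(scene$config),
                  streamline_cluster = scene$streamline_cluster,
                  streamline_hemi = scene$streamline_hemi,
                  truth_left = as.integer(scene$truth_left[scene$roi_left]),
                  truth_right = as.integer(scene$truth_right[scene$roi_right]))
  jsonlite::write_json(sidecar, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
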