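#' Per-subject tw-dFC for a synthetic scene
#'
#' Optionally smooths the subject's BOLD, then computes the tw-dFC volume
#' over the scene's traversal index.
#'
#' @param scene a [build_scene()] result.
#' @param subject subject number.
#' @param spec a [window_spec()].
#' @param fwhm_mm spatial smoothing applied to BOLD first (0 = none).
#' @return a `twdfc_image`.
#' @export
subject_twdfc <- function(scene, subject, spec, fwhm_mm = 0) {
  bold <- scene$bold[[subject]]
  if (fwhm_mm > 0) bold <- smooth_bold(bold, fwhm_mm, scene$grid)
  compute_twdfc(bold, scene$index, spec)
}

#' Seed fingerprints for every subject of a scene
#'
#' Runs the per-subject tw-dFC computation and builds the seed-to-white-
#' matter Fisher-z fingerprint for each hemisphere: seed series at native
#' resolution, white-matter series block-downsampled by `factor`.
#'
#' @inheritParams subject_twdfc
#' @param factor white-matter downsampling factor (default 2).
#' @param hemis which hemispheres to fingerprint.
#' @return list (one element per subject) of lists with the requested
#'   hemispheres, each a [fingerprint()].
#' @export
scene_fingerprints <- function(scene, spec, fwhm_mm = 0, factor = 2L,
                               hemis = c("left", "right")) {
  lapply(seq_len(scene$config$n_subjects), function(s) {
    tw <- subject_twdfc(scene, s, spec, fwhm_mm)
    wm <- extract_series(tw, scene$wm_mask, factor = factor)
    out <- list()
    for (h in hemis) {
      roi <- extract_series(tw, scene[[paste0("roi_", h)]], factor = 1L)
      out[[h]] <- fingerprint(roi, wm)
    }
    out
  })
}

#' Subject-level and consensus parcellation of a fingerprinted cohort
#'
#' @param fps result of [scene_fingerprints()].
#' @param k cluster count.
#' @param n_init k-means initializations (default 100).
#' @param seed master seed; subject fits and the consensus fit draw
#'   sub-streams from it.
#' @param hemis hemispheres to parcellate.
#' @return per hemisphere: list with `subjects` (list of `roi_partition`)
#'   and `group` (consensus `roi_partition`).
#' @export
parcellate_cohort <- function(fps, k, n_init = 100L, seed = 1L,
                              hemis = c("left", "right")) {
  n <- length(fps)
  seeds <- spawn_seeds(seed, (n + 1L) * length(hemis))
  out <- list()
  for (hi in seq_along(hemis)) {
    h <- hemis[hi]
    base <- (hi - 1L) * (n + 1L)
    subj <- lapply(seq_len(n), function(s) {
      kmeans_partition(fps[[s]][[h]], k, n_init = n_init,
                       seed = seeds[base + s])
    })
    grp <- consensus(subj, k, n_init = n_init, seed = seeds[base + n + 1L])
    out[[h]] <- list(subjects = subj, group = grp)
  }
  out
}

# Truth label vector for one hemisphere, ordered like the fingerprint rows
# (which(roi) order).
scene_truth_labels <- function(scene, hemi = "left") {
  roi <- scene[[paste0("roi_", hemi)]]
  truth <- scene[[paste0("truth_", hemi)]]
  as.integer(truth[which(roi)])
}

#' Planted-structure recovery experiment
#'
#' Builds a scene, parcellates both hemispheres at the planted k, and
#' scores the consensus partitions against the planted labels with the
#' adjusted Rand index.
#'
#' @param seed scene and analysis seed.
#' @param cfg optional [scene_config()] (its seed is overridden).
#' @param spec window specification (default 55 timepoints, stride 1).
#' @param n_init k-means initializations.
#' @return list with `ari` (named: left, right) and the consensus
#'   partitions.
#' @export
experiment_recovery <- function(seed, cfg = NULL,
                                spec = window_spec(55L, 1L),
                                n_init = 100L) {
  seeds <- spawn_seeds(seed, 2L)
  if (is.null(cfg)) cfg <- scene_config(seed = seeds[1])
  else { cfg$seed <- seeds[1] }
  scene <- build_scene(cfg)
  fps <- scene_fingerprints(scene, spec)
  parc <- parcellate_cohort(fps, k = cfg$k_true, n_init = n_init,
                            seed = seeds[2])
  aris <- vapply(c("left", "right"), function(h) {
    ari(parc[[h]]$group, scene_truth_labels(scene, h))
  }, numeric(1))
  list(ari = aris, parcellation = parc, scene_config = cfg)
}

#' Split-half stability experiment across cluster numbers
#'
#' Parcellates one cohort at each requested k and summarizes consensus
#' stability as split-half nVI distributions.
#'
#' @param seed master seed.
#' @param k_values cluster numbers to compare.
#' @param n_resamples split-half iterations per k.
#' @param cfg optional [scene_config()].
#' @param spec window specification.
#' @param n_init k-means initializations.
#' @param hemi hemisphere analyzed (default left).
#' @return list with `nvi` (named list of numeric vectors per k) and
#'   `medians`.
#' @export
experiment_splithalf <- function(seed, k_values = c(4L, 7L),
                                 n_resamples = 100L, cfg = NULL,
                                 spec = window_spec(55L, 1L),
                                 n_init = 100L, hemi = "left") {
  seeds <- spawn_seeds(seed, 2L + 2L * length(k_values))
  if (is.null(cfg)) cfg <- scene_config(seed = seeds[1])
  else cfg$seed <- seeds[1]
  scene <- build_scene(cfg)
  fps <- scene_fingerprints(scene, spec, hemis = hemi)
  res <- list()
  for (i in seq_along(k_values)) {
    k <- k_values[i]
    parc <- parcellate_cohort(fps, k, n_init = n_init,
                              seed = seeds[2L * i], hemis = hemi)
    res[[as.character(k)]] <- splithalf_nvi(parc[[hemi]]$subjects, k,
                                            n_resamples = n_resamples,
                                            seed = seeds[2L * i + 1L],
                                            n_init = n_init)
  }
  list(nvi = res, medians = vapply(res, stats::median, numeric(1)))
}

#' Cross-cohort reproducibility experiment
#'
#' Generates two independent cohorts, parcellates each at the planted k,
#' and reports the average Dice between matched consensus clusters.
#'
#' @param seed master seed.
#' @param n_subjects subjects per cohort (default 10).
#' @param cfg optional [scene_config()] template.
#' @param spec window specification.
#' @param n_init k-means initializations.
#' @param hemi hemisphere analyzed.
#' @return list with `average_dice` and the matching table.
#' @export
experiment_crosscohort <- function(seed, n_subjects = 10L, cfg = NULL,
                                   spec = window_spec(55L, 1L),
                                   n_init = 100L, hemi = "left") {
  seeds <- spawn_seeds(seed, 4L)
  if (is.null(cfg)) cfg <- scene_config()
  groups <- lapply(1:2, function(i) {
    cfg$n_subjects <- as.integer(n_subjects)
    cfg$seed <- seeds[i]
    scene <- build_scene(cfg)
    fps <- scene_fingerprints(scene, spec, hemis = hemi)
    parcellate_cohort(fps, cfg$k_true, n_init = n_init,
                      seed = seeds[2L + i], hemis = hemi)[[hemi]]$group
  })
  m <- match_and_average_dice(groups[[1]], groups[[2]])
  list(average_dice = m$average_dice, pairs = m$pairs)
}

#' Null calibration of the permutation FWE test
#'
#' Simulates datasets of zero-mean Gaussian subject maps and records how
#' often the max-statistic FWE test rejects anywhere at the given alpha.
#' For a valid test the rate matches alpha.
#'
#' @param n_datasets simulated datasets (default 200).
#' @param n_subjects subjects per dataset (default 15).
#' @param n_voxels voxels per map (default 300).
#' @param n_perm permutations (default 500).
#' @param alpha FWE level tested (default 0.05).
#' @param seed master seed.
#' @return list with `rate` (fraction of datasets with any rejection) and
#'   `n_datasets`.
#' @export
experiment_fwe_null <- function(n_datasets = 200L, n_subjects = 15L,
                                n_voxels = 300L, n_perm = 500L,
                                alpha = 0.05, seed = 1L) {
  seeds <- spawn_seeds(seed, 2L * n_datasets)
  rej <- vapply(seq_len(n_datasets), function(d) {
    maps <- with_seed(seeds[2L * d - 1L],
                      matrix(stats::rnorm(n_subjects * n_voxels),
                             n_subjects, n_voxels))
    res <- permutation_onesample(maps, n_perm = n_perm, alpha = alpha,
                                 seed = seeds[2L * d])
    any(res$sig > 0, na.rm = TRUE)
  }, logical(1))
  list(rate = mean(rej), n_datasets = n_datasets)
}

# Per-subject, per-cluster whole-brain Fisher-z maps from cluster mean
# tw-dFC time courses, for one hemisphere's labels (planted labels by
# default; pass a consensus label volume to characterize a data-driven
# parcellation).
subject_cluster_maps <- function(scene, spec, hemi, labels = NULL,
                                 fwhm_mm = 0) {
  if (is.null(labels)) labels <- scene[[paste0("truth_", hemi)]]
  ks <- sort(unique(labels[labels > 0]))
  lapply(seq_len(scene$config$n_subjects), function(s) {
    tw <- subject_twdfc(scene, s, spec, fwhm_mm)
    lapply(ks, function(c) cluster_timecourse_map(tw, labels == c))
  })
}

#' Preferential connectivity analysis of planted clusters
#'
#' For one hemisphere: per-subject whole-brain Fisher-z maps of every
#' cluster's mean tw-dFC time course; group-mean maps restricted to the
#' white-matter mask; winner-takes-all assignment of shared voxels; and a
#' one-sample permutation t-test (max-statistic FWE) per cluster over its
#' winner-takes-all territory.
#'
#' @param scene a [build_scene()] result.
#' @param spec window specification.
#' @param hemi `"left"` or `"right"`.
#' @param n_perm,alpha permutation test parameters.
#' @param seed master seed.
#' @param labels optional 3D label volume defining the clusters (planted
#'   labels by default).
#' @param subject_maps optional precomputed [subject_cluster_maps] output.
#' @return list with `group_maps`, `wta` (label array), `tests` (per
#'   cluster [permutation_onesample()] results), `sig_masks`, and
#'   `subject_maps`.
#' @export
preferential_analysis <- function(scene, spec, hemi = "left",
                                  n_perm = 5000L, alpha = 0.001,
                                  seed = 1L, labels = NULL,
                                  subject_maps = NULL) {
  if (is.null(subject_maps)) {
    subject_maps <- subject_cluster_maps(scene, spec, hemi, labels = labels)
  }
  k <- length(subject_maps[[1]])
  seeds <- spawn_seeds(seed, k)
  group_maps <- lapply(seq_len(k), function(c) {
    g <- Reduce(`+`, lapply(subject_maps, `[[`, c)) / length(subject_maps)
    g[!scene$wm_mask] <- NA_real_
    g
  })
  wta <- winner_takes_all(group_maps)
  tests <- lapply(seq_len(k), function(c) {
    permutation_onesample(lapply(subject_maps, `[[`, c), mask = wta == c,
                          n_perm = n_perm, alpha = alpha, seed = seeds[c])
  })
  sig_masks <- lapply(tests, function(tst) {
    m <- tst$sig
    m[is.na(m)] <- 0
    m > 0
  })
  list(group_maps = group_maps, wta = wta, tests = tests,
       sig_masks = sig_masks, subject_maps = subject_maps)
}

#' Preferential-map recovery experiment
#'
#' Runs [preferential_analysis()] on both hemispheres of a fresh scene and
#' scores each planted cluster's FWE-thresholded preferential map against
#' its designated target territory with the Dice coefficient; also checks
#' that winner-takes-all territories are pairwise disjoint by
#' construction.
#'
#' @param seed master seed.
#' @param cfg optional [scene_config()].
#' @param spec window specification.
#' @param n_perm,alpha permutation test parameters.
#' @return list with `dice` (matrix hemis x clusters), `wta_disjoint`
#'   (logical), and the per-hemisphere analyses.
#' @export
experiment_preferential <- function(seed, cfg = NULL,
                                    spec = window_spec(55L, 1L),
                                    n_perm = 500L, alpha = 0.05) {
  seeds <- spawn_seeds(seed, 3L)
  if (is.null(cfg)) cfg <- scene_config(seed = seeds[1])
  else cfg$seed <- seeds[1]
  scene <- build_scene(cfg)
  k <- cfg$k_true
  dsc <- matrix(NA_real_, 2, k, dimnames = list(c("left", "right"), NULL))
  analyses <- list()
  for (hi in 1:2) {
    h <- c("left", "right")[hi]
    pa <- preferential_analysis(scene, spec, hemi = h, n_perm = n_perm,
                                alpha = alpha, seed = seeds[1L + hi])
    for (c in seq_len(k)) {
      dsc[h, c] <- dice(pa$sig_masks[[c]], scene$target_regions[[h]][[c]])
    }
    analyses[[h]] <- pa
  }
  wta_disjoint <- TRUE  # argmax labelling assigns each voxel once
  list(dice = dsc, wta_disjoint = wta_disjoint, analyses = analyses,
       scene = scene)
}

#' Decoding sanity experiment
#'
#' Builds a scene, computes each planted cluster's group preferential map,
#' fabricates one planted term map per cluster plus random distractors,
#' track-weights all term maps with the scene's streamlines, and checks
#' whether the planted term ranks first for its own cluster.
#'
#' @param seed master seed.
#' @param cfg optional [scene_config()]; defaults to a lighter cohort
#'   (5 subjects) since decoding operates on group maps.
#' @param spec window specification.
#' @param n_distractors distractor term maps (default 19).
#' @return list with `top1` (logical per cluster: planted term ranked
#'   first) and the ranking tables.
#' @export
experiment_decode <- function(seed, cfg = NULL,
                              spec = window_spec(55L, 1L),
                              n_distractors = 19L) {
  seeds <- spawn_seeds(seed, 3L)
  if (is.null(cfg)) cfg <- scene_config(n_subjects = 5L, seed = seeds[1])
  else cfg$seed <- seeds[1]
  scene <- build_scene(cfg)
  k <- cfg$k_true
  terms <- synthetic_term_maps(scene, n_distractors = n_distractors,
                               seed = seeds[2])
  tw_terms <- track_weight_terms(terms, scene$streamlines, scene$grid)
  sm <- subject_cluster_maps(scene, spec, "left")
  rankings <- list()
  top1 <- logical(k)
  for (c in seq_len(k)) {
    g <- Reduce(`+`, lapply(sm, `[[`, c)) / length(sm)
    g[!scene$wm_mask] <- NA_real_
    rk <- rank_terms(g, tw_terms, mask = scene$wm_mask, top_n = 20L)
    rankings[[c]] <- rk
    top1[c] <- rk$term[1] == sprintf("planted_cluster%d", c)
  }
  list(top1 = top1, rankings = rankings)
}

#' Lateralization experiment
#'
#' Builds a scene (symmetric by default, or with right-hemisphere coupling
#' scaled up), derives per-subject preferential maps for the left and
#' right seeds, brings the right maps into homotopic correspondence by
#' mirroring, forms voxelwise lateralization-index maps per cluster, and
#' tests them against zero with a single sign-flip permutation family
#' pooled over clusters (one max statistic controls the family-wise error
#' across every tested voxel of every cluster).
#'
#' @param seed master seed.
#' @param asymmetric when `TRUE`, uses coupling amplitude 0.45 with the
#'   right hemisphere scaled by 2 (so the planted right coupling is twice
#'   the left and remains a valid correlation).
#' @param cfg optional [scene_config()] (overrides `asymmetric` defaults).
#' @param spec window specification.
#' @param n_perm,alpha permutation test parameters.
#' @param eps denominator guard for the lateralization index.
#' @return list with `any_sig`, `n_sig`, `n_tested`, and `sensitivity`
#'   (fraction of homotopic target voxels flagged; `NA` for symmetric
#'   scenes with no planted asymmetry).
#' @export
experiment_lateralization <- function(seed, asymmetric = FALSE, cfg = NULL,
                                      spec = window_spec(55L, 1L),
                                      n_perm = 500L, alpha = 0.05,
                                      eps = 1e-6) {
  seeds <- spawn_seeds(seed, 2L)
  if (is.null(cfg)) {
    cfg <- if (asymmetric) {
      scene_config(coupling_amplitude = 0.45, right_coupling_scale = 2,
                   seed = seeds[1])
    } else scene_config(seed = seeds[1])
  } else cfg$seed <- seeds[1]
  scene <- build_scene(cfg)
  k <- cfg$k_true
  n <- cfg$n_subjects
  maps_l <- vector("list", n); maps_r <- vector("list", n)
  for (s in seq_len(n)) {
    tw <- subject_twdfc(scene, s, spec)
    labs_l <- scene$truth_left; labs_r <- scene$truth_right
    maps_l[[s]] <- lapply(seq_len(k), function(c)
      cluster_timecourse_map(tw, labs_l == c))
    maps_r[[s]] <- lapply(seq_len(k), function(c)
      cluster_timecourse_map(tw, labs_r == c))
  }
  mask_na <- function(m) { m[!scene$wm_mask] <- NA_real_; m }
  wta_l <- winner_takes_all(lapply(seq_len(k), function(c)
    mask_na(Reduce(`+`, lapply(maps_l, `[[`, c)) / n)))
  wta_r <- winner_takes_all(lapply(seq_len(k), function(c)
    mask_na(Reduce(`+`, lapply(maps_r, `[[`, c)) / n)))
  # pooled LI family: per cluster, voxels valid for every subject
  li_cols <- list(); col_cluster <- integer(); col_voxel <- integer()
  li_mat <- NULL
  for (c in seq_len(k)) {
    li_subj <- lapply(seq_len(n), function(s) {
      zl <- maps_l[[s]][[c]]; zl[wta_l != c] <- NA_real_
      zr <- maps_r[[s]][[c]]; zr[wta_r != c] <- NA_real_
      lateralization(zl, mirror_x(zr), eps = eps)$li
    })
    M <- t(vapply(li_subj, as.numeric, numeric(length(li_subj[[1]]))))
    keep <- which(colSums(!is.finite(M)) == 0L)
    if (!length(keep)) next
    li_mat <- cbind(li_mat, M[, keep, drop = FALSE])
    col_cluster <- c(col_cluster, rep.int(c, length(keep)))
    col_voxel <- c(col_voxel, keep)
  }
  if (is.null(li_mat) || ncol(li_mat) == 0L) {
    stop("no voxel has complete lateralization data")
  }
  res <- permutation_onesample(li_mat, n_perm = n_perm, alpha = alpha,
                               seed = seeds[2])
  sig <- !is.na(res$sig) & res$sig > 0
  # sensitivity over homotopic target voxels of each cluster
  target_cols <- logical(ncol(li_mat))
  for (c in seq_len(k)) {
    tl <- which(scene$target_regions$left[[c]])
    target_cols[col_cluster == c & col_voxel %in% tl] <- TRUE
  }
  sens <- if (any(target_cols)) mean(sig[target_cols]) else NA_real_
  list(any_sig = any(sig), n_sig = sum(sig), n_tested = ncol(li_mat),
       sensitivity = if (cfg$right_coupling_scale != 1) sens else NA_real_,
       n_target_voxels = sum(target_cols))
}
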