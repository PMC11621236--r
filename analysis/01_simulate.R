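#!/usr/bin/env Rscript
# Build the synthetic cohort: 20 subjects, mirrored seed ROIs with four
# planted connectivity clusters, streamline bundles to disjoint target
# territories, and BOLD with sinusoidally modulated endpoint coupling.
# Exports one subject's volumes plus masks/streamlines to scratch/ (to
# exercise the on-disk formats) and a cohort summary to results/.

source("analysis/00_common.R")

scene <- default_scene()
cfg <- scene$config
message(sprintf("scene: %d subjects, %d timepoints, k_true = %d, %d streamlines",
                cfg$n_subjects, cfg$n_timepoints, cfg$k_true,
                length(scene$streamlines)))

# export a single-subject miniature of the scene for format round-trips
mini <- scene
mini$bold <- mini$bold[1]
mini$config$n_subjects <- 1L
write_scene(mini, file.path(SCRATCH_DIR, "scene_sub01"))

sizes <- table(scene$truth_left[scene$roi_left])
summary <- data.frame(
  cluster = as.integer(names(sizes)),
  seed_voxels = as.integer(sizes),
  target_voxels = vapply(seq_len(cfg$k_true), function(c)
    sum(scene$target_regions$left[[c]]), integer(1)),
  streamlines = as.integer(table(scene$streamline_cluster[
    scene$streamline_hemi == "left"])),
  peak_coupling = round(apply(scene$r_profiles$left, 1, max), 4))
write_tsv(summary, "01_scene_summary.tsv")
message(sprintf("white-matter mask: %d voxels; traversal index: %d voxels",
                sum(scene$wm_mask), length(scene$index$voxels)))
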