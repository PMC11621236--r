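# Shared settings for the analysis workflow. Every driver sources this
# file, rebuilds what it needs deterministically from the seeds below, and
# writes text tables under results/. Bulky intermediates (NIfTI volumes,
# TCK files) go to scratch/, which is disposable.

library(twdfc)

RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch"
dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create(SCRATCH_DIR, showWarnings = FALSE)

SCENE_SEED <- 20260924L          # cohort used throughout the workflow
ANALYSIS_SEED <- 7L
WINDOW <- window_spec(55L, 1L)   # ~40 s windows at TR 0.72 s, stride 1
K_RANGE <- 2:9
N_INIT <- 100L

default_scene <- function() build_scene(scene_config(seed = SCENE_SEED))

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  path
}
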