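#!/usr/bin/env Rscript
# Term-map decoding of the preferential connectivity maps: fabricate one
# planted term per cluster (from its target territories) plus 19 random
# distractors, track-weight all of them with the scene's streamlines, and
# rank terms by spatial correlation with each cluster's group map.

source("analysis/00_common.R")

scene <- default_scene()
terms <- synthetic_term_maps(scene, n_distractors = 19L,
                             seed = ANALYSIS_SEED + 500L)
tw_terms <- track_weight_terms(terms, scene$streamlines, scene$grid)
sm <- twdfc:::subject_cluster_maps(scene, WINDOW, "left")

rows <- list()
for (c in seq_len(scene$config$k_true)) {
  g <- Reduce(`+`, lapply(sm, `[[`, c)) / length(sm)
  g[!scene$wm_mask] <- NA_real_
  rk <- rank_terms(g, tw_terms, mask = scene$wm_mask, top_n = 20L)
  rk$cluster <- c
  rows[[c]] <- rk
  message(sprintf("cluster %d: top term = %s (r = %.3f)",
                  c, rk$term[1], rk$r[1]))
}
write_tsv(do.call(rbind, rows)[, c("cluster", "rank", "term", "r")],
          "06_decoding.tsv")
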