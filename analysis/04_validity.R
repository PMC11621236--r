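#!/usr/bin/env Rscript
# Cluster-number selection criteria across k = 2..9: subject-level and
# group-level silhouette, split-half nVI (50 resamples per k), one-way
# ANOVA with Tukey HSD across k, and cross-cohort reproducibility (average
# Dice between two independent 10-subject cohorts) at the planted k.

source("analysis/00_common.R")

scene <- default_scene()
fps <- readRDS(file.path(SCRATCH_DIR, "fingerprints.rds"))
parc_all <- readRDS(file.path(SCRATCH_DIR, "parcellations.rds"))

sil_rows <- list(); nvi_by_k <- list(); sil_by_k <- list(); sum_rows <- list()
for (k in K_RANGE) {
  parc <- parc_all[[as.character(k)]]
  sil <- vapply(seq_along(fps), function(s)
    silhouette_score(fps[[s]]$left, parc$left$subjects[[s]]), numeric(1))
  sv <- splithalf_nvi(parc$left$subjects, k, n_resamples = 50L,
                      seed = ANALYSIS_SEED + 100L + k)
  sil_by_k[[as.character(k)]] <- sil
  nvi_by_k[[as.character(k)]] <- sv
  sil_rows[[as.character(k)]] <- data.frame(
    k = k, subject = seq_along(sil), silhouette = round(sil, 4))
  sum_rows[[as.character(k)]] <- data.frame(
    k = k,
    silhouette_mean = round(mean(sil), 4),
    silhouette_sd = round(sd(sil), 4),
    silhouette_group = round(silhouette_score(parc$left$group$q,
                                              parc$left$group), 4),
    nvi_median = round(median(sv), 4),
    nvi_mean = round(mean(sv), 4))
}
write_tsv(do.call(rbind, sil_rows), "04_subject_silhouette.tsv")
write_tsv(do.call(rbind, sum_rows), "04_validity_by_k.tsv")

an_sil <- compare_k(sil_by_k)
an_nvi <- compare_k(nvi_by_k)
write_tsv(an_sil$tukey, "04_tukey_silhouette.tsv")
write_tsv(an_nvi$tukey, "04_tukey_nvi.tsv")
message(sprintf("ANOVA across k: silhouette F = %.2f (p = %.3g), nVI F = %.2f (p = %.3g)",
                an_sil$anova$F, an_sil$anova$p, an_nvi$anova$F, an_nvi$anova$p))

cc <- experiment_crosscohort(ANALYSIS_SEED + 200L, n_subjects = 10L)
write_tsv(cc$pairs, "04_crosscohort_pairs.tsv")
message("cross-cohort average Dice at planted k: ", round(cc$average_dice, 3))
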