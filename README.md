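# twdfc — track-weighted dynamic functional connectivity parcellation

Structural and functional brain connectivity are usually analyzed apart:
diffusion tractography reconstructs white-matter pathways as streamlines,
while resting-state fMRI yields correlations between grey-matter signals.
Track-weighted dynamic functional connectivity (tw-dFC) fuses them into
one 4D signal. The BOLD series at a streamline's two endpoints are
correlated inside partially overlapping sliding windows, giving that
streamline a connectivity time series FC_i(t); every white-matter voxel
then carries the average over the streamlines traversing it,

    tw-dFC(v, t) = (1 / N_v) * sum_i FC_i(t),

so dynamic coupling between two territories is propagated along the
pathways that connect them. On top of this signal the package implements
a complete connectivity-based parcellation workflow for a seed region
(built with the pulvinar, the large associative thalamic nucleus, in
mind, but agnostic to the seed):

* **tw-dFC** — exact streamline voxelization, traversal indexing,
  windowed endpoint correlation, and the voxel-level average, with an
  undefined-value discipline for zero-variance windows;
* **parcellation** — seed-to-white-matter Fisher-z fingerprints,
  subject-level k-means (best of 100 random initializations, fully
  deterministic given a seed), and group consensus clustering of averaged
  voxel-pair co-assignment matrices;
* **cluster-number selection** — silhouette, split-half normalized
  variation of information, one-way ANOVA with Tukey HSD across k, and
  cross-cohort Dice reproducibility;
* **characterization** — atlas overlap tables, maximum probability maps,
  preferential connectivity with winner-takes-all masking and one-sample
  permutation t-tests under max-statistic family-wise error control, and
  voxelwise lateralization indices with homotopic (mirrored)
  correspondence;
* **decoding** — track-weighting of scalar term maps with a template
  tractogram and correlation ranking against cluster connectivity maps;
* **synthetic scenes** — a first-class generator of multi-subject
  datasets (BOLD + streamlines + masks + ground truth) with planted
  cluster structure and sinusoidally modulated endpoint coupling, so the
  entire pipeline is testable end to end without any acquisition.

File formats: NIfTI-1 volumes (via RNifti) and MRtrix-dialect `.tck`
streamline files (native reader/writer).

## Worked example

Six synthetic subjects, four planted clusters per seed, parcellated back
out of the data:

```r
library(twdfc)

cfg   <- scene_config(n_subjects = 6, n_timepoints = 180, seed = 1)
scene <- build_scene(cfg)
scene
#> synthetic_scene: 6 subjects, 4 planted clusters, 432 streamlines on a 24x24x24 grid

spec <- window_spec(55, 1)                  # ~40 s windows, stride 1
fps  <- scene_fingerprints(scene, spec)     # per-subject Fisher-z fingerprints
parc <- parcellate_cohort(fps, k = 4, n_init = 50, seed = 2)
parc$left$group
#> roi_partition: k = 4 over 216 voxels; sizes: 54, 54, 54, 54

truth <- scene$truth_left[scene$roi_left]
ari(parc$left$group, truth)
#> [1] 1
median(splithalf_nvi(parc$left$subjects, 4, n_resamples = 25, seed = 3))
#> [1] 0
```

The consensus partition reproduces the planted labels exactly (adjusted
Rand index 1) and is perfectly stable under split-half resampling
(median nVI 0): at the planted k the subject fingerprints agree on where
the cluster boundaries lie.

## Analysis workflow

The study itself lives in `analysis/` as numbered drivers over the
package functions; each writes text tables under `results/`:

| driver | what it does |
| --- | --- |
| `01_simulate.R` | builds the 20-subject default cohort, exports one subject's volumes/streamlines |
| `02_twdfc.R` | computes tw-dFC and checks corridor series track the planted coupling |
| `03_parcellate.R` | subject k-means + consensus for k = 2..9, both hemispheres |
| `04_validity.R` | silhouette, split-half nVI, ANOVA/Tukey, cross-cohort Dice |
| `05_characterize.R` | atlas overlap, MPMs, preferential maps + permutation FWE, lateralization |
| `06_decode.R` | track-weighted term-map ranking per cluster |

Run them from the repository root, in order:
`Rscript analysis/01_simulate.R` … `Rscript analysis/06_decode.R`.
On the default cohort the validity table peaks cleanly at the planted
k = 4 (subject silhouette 0.88 ± 0.01 versus ≤ 0.75 at other k; median
split-half nVI 0), every thresholded preferential map covers its planted
territory (Dice 0.56–0.61 against 3×4×4-voxel targets at the end of
~110-voxel corridors), the symmetric cohort produces zero suprathreshold
lateralization voxels, and the planted term ranks first for all four
clusters in the decoding tables.

The methods vignette (`vignettes/twdfc-methods.Rmd`) documents the model,
the estimator conventions, the synthetic-scene design and its
limitations, and every numerically consequential default.

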