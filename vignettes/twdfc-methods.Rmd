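---
title: "Track-weighted dynamic functional connectivity: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Track-weighted dynamic functional connectivity: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twdfc)
```

## The hybrid signal

Track-weighted dynamic functional connectivity (tw-dFC) fuses two
modalities. Diffusion tractography supplies streamlines — polylines in
world millimetres approximating white-matter pathways. Resting-state BOLD
supplies a time series per voxel. For a streamline $i$ with endpoint
voxels $A_i$ and $B_i$, the endpoint coupling inside a rectangular sliding
window $t$ is the Pearson correlation

$$\mathrm{FC}_i(t) = \mathrm{corr}\big(x_{A_i}, x_{B_i}\big)\Big|_{\text{window } t},$$

and the tw-dFC value of a white-matter voxel $v$ is the average over the
$N_v$ streamlines traversing it:

$$\text{tw-dFC}(v, t) = \frac{1}{N_v} \sum_{i=1}^{N_v} \mathrm{FC}_i(t).$$

The defining property is propagation: when the coupling between two grey
matter territories fluctuates, every voxel along the streamlines
connecting them fluctuates with it. A voxel traversed by a single
streamline carries that streamline's coupling series bit-for-bit. Windows
in which an endpoint series has zero variance yield an undefined
correlation; these are excluded from the voxel average rather than set to
zero, because zero is a data value, not a missing one.

Windows are rectangular, `length_tp` timepoints long, advanced by
`stride_tp` (default 1, the maximal temporal resolution); a series of $n$
timepoints yields $\lfloor (n - L)/s \rfloor + 1$ windows, all fully
inside the series. The default window of 55 timepoints at TR 0.72 s is
about 40 s, inside the 30–60 s range where sliding-window connectivity
estimates are commonly considered stable. Window length is a free
parameter of the pipeline, not derived from a rule: sensible values
depend on TR and scan length.

## Streamline geometry

A point belongs to the voxel whose centre cell contains it, with the
half-open cell boundaries resolved by rounding half up; world and voxel
coordinates are related by the NIfTI affine. Traversed voxels are
enumerated exactly: each polyline segment's crossings of cell-boundary
planes are computed analytically and the containing cell of every
interval midpoint is collected. An earlier draft discretized by
supersampling at half-voxel steps; that provably misses cells a segment
clips near a corner (the sliver can be arbitrarily shorter than any fixed
step), so the tests compare the exact traversal against dense sampling at
0.05-voxel steps and re-confirm sliver cells at 1000× finer sampling.

Endpoint BOLD is sampled from the single containing voxel of the first
and last polyline points. Partial-volume compensation is the job of the
Gaussian pre-smoothing stage (`smooth_bold()`, 6 mm FWHM on real data);
the kernel is truncated at four standard deviations and renormalized at
the volume boundary, so constants are preserved exactly and an interior
impulse keeps its mass.

`track_weight_scalar_map()` generalizes the construction to any scalar
volume: the per-streamline statistic is the mean of the map sampled
(nearest voxel) along the polyline's own points, and each traversed voxel
averages that statistic over its streamlines. The along-track statistic
is not uniquely determined by the track-weighted imaging literature; the
mean is the conventional default and the one used here.

## Parcellation

For each subject and each seed (left and right separately), the
connectivity fingerprint is the matrix of Fisher r-to-z transformed
correlations between every seed voxel's tw-dFC series (native resolution)
and every white-matter voxel's series (block-mean downsampled by a factor
of 2, e.g. 2 mm to 4 mm, to cut the feature dimension). The white-matter
mask is the subject-average white-matter probability map thresholded at
50%, minus the seed ROIs dilated by a 4 mm ball, so seed signal and its
immediate neighbourhood cannot enter the feature space. Correlations are
clamped to $|r| \le 1-10^{-7}$ before `atanh`; zero-variance series
produce z = 0 and are counted.

Subject-level clustering is Lloyd k-means on Euclidean distance between
fingerprint rows. Four conventions make it deterministic and are fixed in
compiled code: centroids initialize from k distinct data rows drawn
uniformly; the best of 100 initializations by within-cluster sum of
squares wins; assignment ties go to the lowest centroid index; an empty
cluster is re-seeded at the point farthest from its current centroid, so
solutions always have exactly k clusters. Euclidean distance is chosen to
match the variance-minimizing objective; correlation distance would be a
reasonable sensitivity analysis but is not implemented.

Group parcellation is consensus clustering: each subject's partition
becomes a binary voxel-pair co-assignment matrix ($q_{ij} = 1$ iff voxels
share a cluster), the matrices are averaged across subjects, and k-means
with the same conventions runs on the rows of the group matrix. The raw
co-assignment rows are used directly, without any similarity transform.

## Choosing k

No single criterion fixes the number of clusters; the package surfaces
four and leaves the decision to the analyst:

* **Silhouette** (segregation): mean over points of $(b-a)/\max(a,b)$;
  singletons and the all-degenerate case contribute 0. Individual-level
  scores use fingerprint rows; group-level scores use group co-assignment
  rows, matching the feature space each clustering actually ran on.
* **Split-half nVI** (stability): 100 random disjoint half-splits of the
  cohort, consensus per half, normalized variation of information between
  the halves. VI uses natural logarithms and is normalized by $\ln N$
  ($N$ = seed voxel count), which makes the distance between the
  one-cluster and all-singleton partitions exactly 1. With an odd cohort
  the larger half takes the extra subject.
* **ANOVA + Tukey HSD** across k on either score, flagging pairs at
  p < 0.05 (`stats::aov`, `stats::TukeyHSD`).
* **Cross-cohort Dice** (reproducibility): clusters of two independently
  parcellated cohorts are matched greedily on descending pairwise Dice
  (bijective, ties to the lowest index pair) and the matched values are
  averaged. Greedy matching can in principle be beaten by the exhaustive
  assignment; on pairs of similar parcellations it almost never is, and
  the tests quantify exactly that.

## Characterization and inference

Atlas overlap is the percentage of each nucleus' volume captured by each
cluster; nuclei trimmed to the seed make rows sum to 100. Maximum
probability maps relabel every individual cluster to its best-Dice group
cluster (many-to-one allowed; zero-Dice clusters are dropped and counted)
and average the binarized masks across subjects.

Preferential connectivity: each cluster's mean tw-dFC time course is
correlated with every indexed voxel's series (Fisher z); shared voxels go
to the cluster with the higher group-mean z in a winner-takes-all
labelling (ties to the lowest index, non-positive maxima stay
background); subject z-maps masked by the winner-takes-all territories
enter a one-sample permutation t-test. The null is built by sign-flipping
whole subject maps; family-wise error is controlled with the
max-statistic construction (the standard permutation FWE mechanism), and
the unpermuted labelling is included in the null so p-values are exact
with floor $1/(n_{\text{perm}}+1)$. Zero-variance voxels are excluded.

Lateralization divides the difference by the sum of left- and right-seed
z values, $LI = (Z_L - Z_R)/(Z_L + Z_R)$, wherever $|Z_L + Z_R|$ exceeds
a guard (default $10^{-6}$). Before the ratio, the right-seed map is
mirrored about the mid-sagittal plane so homotopic locations are
compared. This homotopic-flip correspondence is a deliberate design
choice: in a mirrored geometry the two seeds' corridors occupy different
voxels, so comparing left and right maps at the *same* voxel is
structurally asymmetric and would flag voxels even under a perfectly
symmetric cohort; the mirrored comparison makes the sign-flip null exact
under symmetry, which the specificity experiments verify. Group inference
on LI pools all clusters' tested voxels into a single permutation family
(one max statistic), controlling the family-wise error across the entire
lateralization analysis rather than per cluster.

## Decoding

Term maps (externally supplied activation-style volumes; the synthetic
generator fabricates stand-ins) are track-weighted with a template
streamline set and ranked by Pearson correlation with a cluster's
connectivity map over an analysis mask, descending, ties broken by name.
Ranking is invariant to positive affine rescaling of a term map. Terms
with zero variance in the mask are excluded with a message —
a term map disjoint from the template tractogram carries no decodable
signal.

## The synthetic scene

Real acquisitions are out of scope; every experiment runs on a generated
cohort whose structure matches the assumptions above.

* **Geometry** (24³ voxels of 2 mm, mirrored about the mid-sagittal
  plane): two 6×6×6 seed ROIs; the planted k clusters tile the seed's
  (y, z) cross-section; each cluster owns a disjoint 3×4×4 target
  territory near the x-face, positioned by scaling the cluster's
  cross-section centre away from the seed centre. A second, offset
  partition of the seed (slabs along z) serves as synthetic "atlas
  nuclei", so overlap tables have non-trivial entries.
* **Streamlines**: one per seed voxel (54 per cluster by default),
  cycling through the target voxels so both ends are fully covered. Each
  bundle funnels through two waypoints (seed border, territory face), so
  it forms a compact tract rather than a broad fan — as converging fiber
  bundles do, and necessary for thresholded preferential maps to resemble
  their territories rather than a diffuse cone. The right hemisphere is
  the exact reflection of the left: with a shared tractogram, any
  left/right geometric difference would be a fixed effect across
  subjects, and the lateralization null would be false for structural
  rather than physiological reasons.
* **BOLD**: per subject, cluster and hemisphere, a unit-variance seed
  latent $u$ and a target latent $v = r_c(t)\,u + \sqrt{1-r_c(t)^2}\,w$
  with planted instantaneous coupling
  $r_c(t) = a \cdot \tfrac12\big(1 + \sin(2\pi t/P + \phi_c)\big)$,
  distinct phases $\phi_c = 2\pi(c-1)/k$; seed/target voxels receive
  their latent plus i.i.d. Gaussian noise (sd 0.5), background voxels
  are white noise. Defaults: amplitude $a = 0.9$, period $P = 140$ s,
  TR 0.72 s, 450 timepoints, 20 subjects.
* **Defaults as study conditions.** The window (55 tp ≈ 40 s) matches
  common practice. The period was chosen at design time as the best
  compromise between window-mean attenuation (long periods track better)
  and the number of observed cycles (short periods give more); 100, 120
  and 160 s all track the planted profile worse. The scan length (450 tp
  ≈ 5.4 min, unremarkable for resting state) was sized by a design-phase
  power analysis: subject-level Fisher-z maps rest on roughly $T/L$
  independent windows, and shorter scans leave the group lateralization
  test underpowered against its pooled max-statistic threshold for the
  planted 2× asymmetry. Lateralization experiments use amplitude 0.45
  with the right hemisphere scaled by 2, so the scaled coupling remains a
  valid correlation.
* **What the scene does not model**: no hemodynamic response function, no
  physiological or scanner noise spectra, no head motion, no partial
  volume (hence smoothing defaults to off for synthetic runs — its
  purpose is partial-volume compensation in real data), no per-subject
  tractogram variability, and coupling that varies per timepoint rather
  than per neural event. Passing tests therefore demonstrate the
  *mechanics* of the pipeline — recovery of planted structure under
  realistic noise — not performance on real acquisitions.

### A note on the tracking property

With noise-free BOLD, a streamline's windowed correlation series tracks
the window-mean of its planted coupling profile. The per-streamline
tracking *estimate*, however, is a correlation computed over heavily
overlapping windows — only about $T/L \approx 8$ of them are independent
— so individual estimates scatter around ≈ 0.93 with a spread of a few
hundredths. The detectability test asserts a median of at least 0.9 with
every streamline above 0.8; demanding 0.9 of the worst of ~900 such
estimates would test the luck of a seed, not a property of the
generator.

## Numerical and degenerate-input conventions

* Correlations clamp at $|r| = 1 - 10^{-7}$ before Fisher z.
* Rolling correlations guard negative variances from cancellation;
  zero-variance windows are `NA` throughout.
* Voxel assignment rounds half up (`floor(x + 0.5)`), so cell membership
  is platform-stable.
* k-means ties and empty clusters resolve as described above; all
  randomized stages consume explicit seeds derived from a master seed,
  and no stage reads or leaves global RNG state behind.
* Winner-takes-all ties go to the lowest cluster index; all-`NA` or
  non-positive voxels stay background.
* Empty-vs-empty Dice is 1 (identical sets); empty-vs-non-empty is 0.
* Permutation p-values include the unpermuted labelling,
  so $p \ge 1/(n_{\text{perm}}+1)$ and the test is exact.

## Problem sizes used by the shipped experiments

The analysis drivers and the acceptance checks run, by choice, at desk
scale: the default 20-subject scene; oracle comparisons on a 12³ grid
with 50 streamlines and 200 timepoints; 100 split-half resamples;
permutation tests at 500–1000 permutations (the real-data default is
5000); 200 simulated datasets for the null-calibration study; 20 seeded
runs for decoding and lateralization specificity. These sizes give the
statistics stable denominators while keeping a full run in minutes on one
CPU core.

## Known limitations

* The pipeline assumes one shared tractogram per scene; per-subject
  tractograms (as in real studies) would add geometric variability the
  generator does not emulate.
* Hemispheres are parcellated independently; no joint bilateral model.
* Greedy Dice matching is not the exhaustive optimum in rare adversarial
  cases (documented and quantified in the tests).
* The decoding module operates on supplied term maps only; no database
  client or term curation is included.
* No tapered windows, no phase-randomized surrogate nulls, no
  cluster-extent or threshold-free inference.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  scene = scene_config(n_subjects = 6, n_timepoints = 180, seed = 1),
  k_range = 2:5, n_init = 25, n_resamples = 20, n_perm = 200,
  alpha = 0.05, seed = 2, out_dir = "twdfc_demo")
report <- run_pipeline(cfg)
```

The run writes consensus label volumes per k, validity tables, overlap
tables, permutation-thresholded preferential maps, mean lateralization
maps, decoding rankings, and a JSON manifest with a checksum per output;
re-running the same configuration reproduces the checksums bit for bit.
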