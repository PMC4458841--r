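---
title: "Mapping functional connectivity topography of the entorhinal cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping functional connectivity topography of the entorhinal cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

The entorhinal cortex (EC) is the main gateway between neocortex and
hippocampus. In rodents its lateral and medial subdivisions receive
dissociable input streams — item-like information relayed via perirhinal
cortex (PRC) and spatial/contextual information relayed via
parahippocampal cortex (PHC) — and project along the transverse axis of
the hippocampus, with proximal subiculum preferentially tied to one
stream and distal subiculum to the other. Whether the human homologue is
organized the same way is a question about *intrinsic functional
connectivity topography*: does the correlation structure of spontaneous
BOLD fluctuations subdivide the human EC into an anterior-lateral
(PRC-coupled, "al-EC") and a posterior-medial (PHC-coupled, "pm-EC")
functional subregion, and do these subregions show a proximo-distal
gradient in the subiculum?

`ectopo` implements the complete analysis chain needed to answer that
question at sub-millimeter resolution, together with a synthetic-cohort
generator that plants a known topography so every stage can be validated
by parameter recovery:

1. **Synthetic cohorts** (`make_atlas()`, `plant_topography()`,
   `simulate_subject()`, `simulate_cohort()`) — 4-D BOLD runs on a
   common-space atlas with EC, PRC, PHC, subiculum, WM and CSF regions.
2. **Preprocessing** (`detect_spikes()`, `gaussian_smooth()`,
   `build_task_design()`, `remove_task_effects()`,
   `threshold_roi_intensity()`, `erode_seed_border()`).
3. **First-level connectivity** (`seed_to_voxel_map()` and friends) —
   nuisance regression, 0.01–0.1 Hz band-pass, Pearson correlation,
   Fisher z, Z-standardization.
4. **Group maps** (`one_sample_t()`, `paired_t()`,
   `cluster_threshold()`, `preference_map()`,
   `derive_subregion_seeds()`).
5. **Gradient statistics** (`section_assignment()`, `rm_anova_2x2x2()`,
   `slice_profiles()`, `end_slices_contrast()`, `delta_interaction()`).
6. **Coordinate classifier** (`assemble_samples()`, `loso_svm()`,
   `permutation_null()`, `consistency_map()`, `predicted_parcels()`).

## The generative model

All subjects are generated in one common space — the atlas stands in for
a study-specific template, so cross-subject registration is out of scope
by construction and the statistics under test are isolated from
registration error. Axis conventions follow the hippocampal long axis:
x runs lateral to medial, y posterior to anterior, z ventral to dorsal;
coronal slices are fixed-y planes. The default grid is 40 x 60 x 24
voxels at 0.8 mm isotropic, on which the EC strip spans 26 coronal
slices — the slice count a high-resolution template yields for the human
EC.

Each run is built from band-limited latent signals (white noise low-pass
filtered at 0.1 Hz, the upper edge of the analyzed band):

* PRC and PHC carry distinct latents $\ell_P(t)$, $\ell_H(t)$.
* An EC voxel $v$ carries the convex mixture
  $(1-w(v))\,\ell_P + w(v)\,\ell_H$ with
  $w(v) = \mathrm{logistic}\{\alpha \langle v - \bar v, g\rangle\}$,
  where $g$ points anterior-lateral to posterior-medial and $\alpha$
  (`mixing_steepness`, default 0.3 per voxel) controls how sharp the
  transition is. The ground-truth label is PHC-preferring where
  $w > 0.5$, PRC-preferring otherwise; the tie $w = 0.5$ goes to PRC so
  labeling is deterministic.
* Subiculum voxels mix al-EC-like and pm-EC-like signals along each
  slice's transverse (proximo-distal) axis with a logistic weight
  (`sub_transverse_steepness`, default 0.8 per transverse voxel).
* The most anterior / most posterior `end_slices` subiculum slices
  additionally receive *direct* PRC / PHC coupling. Each neocortical
  seed's signal is split into a shared component (relayed through the
  EC) and a private component (`direct_pathway_weight`, default 0.6)
  that reaches only the subiculum ends (`end_coupling`, default 0.8 in
  latent-SD units). This is the generative expression of a direct
  (non-EC-mediated) pathway: it gives PRC/PHC seeds an end-slice
  connectivity effect in the subiculum while leaving the EC-subregion
  seeds' longitudinal profile flat — the double dissociation the
  analysis must be able to detect and must not hallucinate.

On top of the signal: AR(1) voxel noise (coefficient 0.3, marginal SD
equal to the latent SD), slow drift (linear plus half-cycle cosine),
random-walk motion with occasional jumps and a per-voxel
motion-coupling, WM/CSF compartment signals that leak globally (the
shared physiological confound the WM/CSF nuisance regressors are meant
to remove), HRF-convolved task events (canonical double-gamma, 5 s peak,
15 s undershoot, 1:6 ratio), global intensity spikes, and a baseline of
100 with mild spatial variation. The defaults put single-voxel
seed-to-EC correlations around 0.4–0.7 at 370 volumes — the regime in
which high-resolution 7T connectivity mapping operates. Empirical SNR
and autocorrelation of real 7T residuals are not published for this
setting; the noise defaults are conventional rather than fitted, which
is precisely why every downstream claim is phrased as parameter
*recovery* rather than absolute realism.

What the generator deliberately does not emulate: susceptibility
distortion and dropout geometry, k-space artifacts, slice timing,
between-subject anatomical variability, and registration error. Passing
tests therefore demonstrate that the statistical machinery is correct
and calibrated, not that it is robust to registration failure or
artifact structure beyond the modeled kinds.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `voxel_size` | 0.8 mm | isotropic grid resolution |
| `tr` | 2 s | repetition time |
| `n_volumes` | 370 | run length (12.3 min) |
| `fwhm_mm` | 1.5 mm | smoothing kernel (< 2 voxels, preserving anatomical detail) |
| `intensity_pct` / `motion_mm` | 1.3 % / 0.3 mm | spike-flagging thresholds |
| `band` | 0.01–0.1 Hz | intrinsic-fluctuation band |
| `gap_voxels` | 2 | seed-border erosion (about 1 mm) |
| `z_thresh` / `alpha` | 2.3 / 0.05 | cluster-forming and cluster-level thresholds |
| `n_perm`, `n_iter` | 1000 | permutation counts (cluster / classifier) |
| `svm_cost` | 1 | linear SVM cost |
| `end_slices` | 8 | directly coupled subiculum end slices |

## Numerical and design choices

**Processing order.** Nuisance regression, then band-pass, then
correlation, each step explicit. Toolboxes often fold the band-limit
into a simultaneous regression; the sequential order was chosen for
transparency and testability, and the band-pass is validated against
its analytic frequency response (pass-band within 5%, half-band and
double-band attenuated below 10%).

**Filter realization.** Second-order Butterworth applied
forward-backward (zero phase; squared magnitude response) with
odd-reflection padding. DC is removed exactly.

**Degenerate correlations.** |r| is clipped to 1 − 1e−7 before `atanh`;
zero-variance voxels get z = 0 and are recorded in a QC list rather
than propagating NaN.

**Standardization domain.** Subject maps are Z-standardized over the
voxels the map is computed on (EC plus subiculum by default); the
original acquisition literature does not state its standardization
domain, so the package makes the domain an explicit argument.

**Cluster inference.** Nonparametric sign-flip maximum-cluster-size
permutation (paired contrasts flip the per-subject difference maps,
which is identical to swapping condition labels within subject).
Components are 26-connected; one-sided maps are thresholded separately
per direction; `p_fwe` respects the `1/(1+n_perm)` floor. A
Gaussian-random-field alternative was rejected because it is not exact
at these smoothness levels and cannot be validated at desk scale.

**Partition rules.** Longitudinal splits cut between whole coronal
slices minimizing voxel-count imbalance (ties give the anterior side
more slices). Transverse splits order each slice along its first
principal axis, oriented lateral to medial, with remainder voxels
assigned to the most lateral bins one each. Every rule is deterministic
so section assignments are reproducible.

**Within-subject ANOVA.** In an all-within 2x2x2 design every effect
has one numerator df, so each F equals the squared one-sample t of the
per-subject contrast score. The implementation uses that identity and
is tested to 1e-8 against a full `aov()` error-stratum decomposition.

**Classifier.** A linear SVM on centered voxel coordinates. Because all
chunks (subjects) label the same coordinate set, a training fold's
stacked samples collapse exactly into per-point label counts; the
solver (dual coordinate descent on the reduced dual, in C++) exploits
this, which is what makes 500-iteration permutation nulls affordable.
It agrees with `e1071::svm` (libsvm) on matched fixtures. Ties in the
decision score predict PRC; exact vote ties in the predicted parcels
stay unassigned.

**Permutation scheme.** Training-chunk labels are permuted within
chunk, preserving each chunk's label counts; the full LOSO scheme is
rerun each iteration and tested against the unpermuted labels.

## Calibration studies and their problem sizes

The package's acceptance suite runs four simulation studies, sized so
the full suite stays fast while keeping the power the designs need
(sizes chosen once from a small design pilot):

1. **Planted-gradient recovery**: one 15-subject cohort, 40 x 60 x 24
   grid, 370 volumes, 500 permutations for cluster and classifier
   nulls. Expected: seed-by-longitudinal interaction p well below
   0.001, significant paired-t clusters of both signs, classification
   accuracy above 0.8 with the permutation p at its floor.
2. **Null calibration**: 200 ten-subject null cohorts (flat mixing
   weight 0.5 everywhere), 20 x 30 x 12 grid, 50 volumes. The
   family-wise cluster error sits at the nominal 5%.
3. **ANOVA oracle equivalence**: 100 random cell-means tables against
   `aov()`.
4. **Subiculum dissociation**: 100 twelve-subject cohorts, 80 volumes,
   with 5 directly coupled end slices (scaled from 8 in proportion to
   the 16-slice subiculum of the reduced grid).

### What the null calibration does and does not show

Cluster-extent inference calibrates exactly: the sign-flip permutation
is exchangeable at the map level, and the observed family-wise rate of
null cohorts matches nominal alpha. Two classical oracles for the
*classifier* null, however, presuppose that voxel preference labels are
independent coin flips, and seed-correlation maps violate that by
construction: all voxels of a subject share the same seed time series,
so the sampling errors of their correlations — and hence the signs that
become labels — are positively correlated (label correlation of a few
percent even without smoothing; more with it). As a result, the spread
of null classification accuracies exceeds the binomial interval with
n = voxels x folds, and the permutation p-value distribution under the
null deviates from uniform because spatially structured true labels are
not exchangeable with within-chunk-permuted training labels. The
package keeps both checks in the acceptance suite at their idealized
form — they document the size of this dependence effect rather than a
defect in the inference — and the cluster-level calibration, which is
the inference actually used for mapping claims, is the one that holds.

## A scripted end-to-end analysis

```{r pipeline}
library(ectopo)

atlas <- make_atlas(atlas_spec(c(40L, 60L, 24L)))
truth <- plant_topography(atlas)
fl <- run_first_level(15, atlas, truth, n_volumes = 370L, seed = 42L)
ga <- run_gradient_analysis(fl, n_perm = 500L, n_iter = 500L, seed = 42L)

ga$anova                      # 2x2x2 within-subject ANOVA
ga$clusters_prc               # PRC>PHC clusters (size, peak z, p_fwe)
ga$loso$mean_accuracy         # LOSO classification accuracy
ga$perm$p                     # permutation p

# second stage: EC-subregion seeds into the subiculum
sp <- derive_subregion_seeds(ga$clusters_prc, ga$clusters_phc,
                             atlas_voxels(atlas, "EC"))
sm <- run_subregion_maps(fl, sp)
sub <- run_subiculum_analysis(sm$alEC, sm$pmEC, atlas, k = 8L)
sub$anova
```

## Known limitations

* The atlas geometry is stylized (box-like regions on smooth arcs); it
  preserves the topological relations the analysis depends on (EC
  elongation, PRC/PHC placement, the PRC–EC corridor, subiculum
  transverse axis) but not cortical folding.
* Subjects share one ground truth; between-subject variability enters
  only through noise, motion and events, so the cohort statistics test
  sampling behavior, not anatomical heterogeneity.
* The classifier's permutation null inherits the label-dependence
  caveat above; its p-value is best read as "observed accuracy versus
  relabeled-training accuracy", exactly as constructed.
* Hemispheres are processed independently; the bilateral atlas simply
  mirrors the geometry, it does not model interhemispheric asymmetry.
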