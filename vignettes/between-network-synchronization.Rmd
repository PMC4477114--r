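---
title: "Between-network synchronization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Between-network synchronization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question and the model

Resting-state fMRI signals fluctuate slowly (< 0.1 Hz) and coherently
within intrinsic connectivity networks. Beyond within-network coherence,
the *between*-network structure — which networks rise and fall together,
which anti-synchronize — carries clinical information: in geriatric
depression, the coordination of the affective network with executive,
attentional and salience systems is the quantity of interest, not any
single region's activity.

`netsync` treats a subject's preprocessed scan as a linear mixture

$$ y_v(t) \;=\; \sum_{k=1}^{K} m_k(v)\, s_k(t) \;+\; \varepsilon_v(t), $$

where $m_k$ are spatial network maps shared across subjects up to
amplitude, and $s_k$ are subject-specific network time courses. The
pipeline estimates the group maps by temporally concatenated spatial ICA,
names them by goodness-of-fit against binary templates, recovers
$s_k$ per subject by dual regression, and summarizes between-network
synchronization as the Pearson correlation matrix
$R_{jk} = \mathrm{cor}(s_j, s_k)$. Group inference is a pooled two-sample
t-test per network pair, with family-wise control on the *network-pair
graph*: supra-threshold pairs (p < `edge_alpha`) are clustered by shared
network nodes, a cluster's size is its edge count, and significance comes
from the Monte-Carlo null of the maximum cluster size under group-label
permutation — a network-based statistic.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_components` | 20 | — | group ICA model order; the published analysis used twenty to match the meta-analytic template set it compared against |
| `lowpass_hz` | 0.08 | Hz | frequencies below this are retained; resting-state network signal is concentrated here |
| `cluster_z` | 2.3 | z | voxel cluster-forming threshold for the voxelwise permutation test |
| `cluster_alpha`, `edge_alpha` | 0.05 | — | corrected cluster alpha; uncorrected edge-forming threshold |
| `n_mc_sims` | 10000 | — | Monte-Carlo permutations for the network cluster null |
| `n_perm_voxelwise` | 5000 | — | permutations for the voxelwise cluster-extent null |
| `gof_close_ratio` | 0.9 | — | keep a second-best component when its GOF is ≥ 90% of the best; the source procedure states only "close", so the full GOF matrix is always persisted for re-decision |
| `fisher_z` | off | — | edge tests on raw r by default (see below) |
| `variance_normalize_stage1` | on | — | unit-variance stage-1 time courses (the standard dual-regression `des_norm`); Pearson r is scale-invariant, so headline statistics are unchanged either way — asserted by test |
| `rng_seed` | 1 | — | one global seed; every stochastic stage derives a child seed from its own name, so stages are independently reproducible |

TR is read from the NIfTI time-step metadata (2 s in the emulated
acquisition); `lowpass_hz` must stay below Nyquist $1/(2\,\mathrm{TR})$.

# Numerical and procedural choices

**Preprocessing order.** Nuisance regression (six motion-like series plus
mean WM and CSF signals, estimated from tissue masks) precedes low-pass
filtering, following the stated order of the emulated protocol. Both
stages are linear projections, individually idempotent, and never increase
voxel variance.

**Filter realization.** "Retain < 0.08 Hz" is read as low-pass only. The
default is an ideal FFT-domain brick wall: exactly linear, exactly
idempotent, DC retained, and with an analytically testable attenuation
contract (a 0.2 Hz sinusoid at TR = 2 s keeps < 1% of its variance, a
0.02 Hz sinusoid > 95%). No filter family was named by the source
procedure; an order-4 Butterworth (forward-backward, closed-form bilinear
coefficients) is available via `filter_type = "butterworth"` for users who
object to ringing.

**ICA.** PCA reduction (exact eigendecomposition when the concatenated
time dimension is ≤ 2000, a seeded randomized SVD with two power
iterations otherwise) followed by symmetric fixed-point ICA with the
logcosh contrast, tolerance 1e-4, up to 5 restarts on derived seeds. Two
conventions make results deterministic and comparable: component sign is
oriented so each map's in-mask skewness is non-negative, and maps are
z-scored with the population (1/N) SD. When the model order exceeds the
true source rank, the surplus components live in a Gaussian subspace where
the fixed point provably oscillates; like packaged FastICA
implementations, `fit_spatial_ica()` then returns the lowest-delta iterate
with a warning rather than failing — the structured components are
unaffected, which the recovery tests assert. Subject blocks are voxelwise
variance-normalized before concatenation so high-variance subjects cannot
dominate; voxels whose variance is numerically zero (relative 1e-6) are
zeroed, not amplified.

**GOF.** The template-matching score is the mean z inside the template
minus the mean z outside (within the brain mask) — the classic
template-matching statistic. It is invariant to adding a constant to a map
and scales linearly with the map, so z-scored maps make matching
well-defined. Argmax ties break to the lowest component index. Whole-brain
(not gray-matter-restricted) masks are the default.

**Edge tests on raw r.** Group tests default to pooled-variance t-tests on
raw correlations, not Fisher z: the printed group means/SDs and p-values
of the study this pipeline emulates are mutually consistent under exactly
that test (the acceptance suite recomputes p ≈ 0.03 / 0.04 / 0.04 from the
printed summaries). Fisher z is available by flag; simulation at n = 32
with values in [−0.4, 0.4] puts the median |Δp| below 0.01 but the worst
case near 0.04, so the two analyses can occasionally disagree at the
margin — a bound the test suite asserts as measured, not as wished.

**Age adjustment.** "Age as a regressor" is implemented as residualization
with a common slope (estimated from a model with group intercepts, so the
group difference is not absorbed), applied before the t-test and before
the permutation machinery. Both adjusted and unadjusted statistics are
always emitted.

**Cluster correction on the network graph.** A cluster is a connected
component of supra-threshold edges under shared-network-node adjacency;
its size is its edge count. The null is the distribution of the *maximum*
cluster size over `n_mc_sims` random group-label permutations with the
full edge test and clustering recomputed each draw; corrected p uses +1
smoothing, $(1 + \#\{\text{null} \ge s\})/(1 + n_\mathrm{sims})$, so p is
never exactly zero. On a 5-node / 10-edge graph cluster sizes are small
integers, so the attained family-wise error sits below the nominal alpha
(measured ≈ 0.015–0.04 at alpha = 0.05 over 200 null studies) — the
correction is valid but conservative at this graph size, which is inherent
to the discrete statistic, not a tuning choice.

**Voxelwise test.** Two-sample t per in-mask voxel, monotonically mapped
to z through matching tail probabilities (log-space, stable in both
tails); clusters form at z > `cluster_z` with 26-connectivity (compiled
flood fill); the cluster-extent null uses the same *signed* statistic per
permutation — clustering |t| for the null while observing signed clusters
would inflate null extents and silently halve power. Subgroup contrasts
(e.g. remitted vs. active vs. control) are ordinary two-group runs on
relabeled designs.

# The synthetic world

The generator emulates the cohort the emulated study describes but did not
deposit: two groups of 32 subjects, 150 volumes at TR = 2 s, a 20³ voxel
grid, five disjoint spherical network templates plus WM/CSF tissue blobs
inside a brain mask.

* **Latent time courses.** i.i.d. Gaussian series → ideal low-pass below
  0.08 Hz → *empirical* decorrelation → multiplication by a symmetric
  square root of the target correlation matrix. The sample correlation of
  the output equals the target exactly, not just in expectation — at
  T = 150 the sampling error of r (~0.08 SD) would otherwise be
  comparable to the effects under study.
* **Group structure.** Controls: AN–CEN 0.30, AN–CAN −0.39, AN–SN −0.18;
  depression: 0.15, −0.22, −0.02; all other pairs 0. Per-subject matrices
  are drawn around the group matrix with between-subject SD 0.27 (the
  scale of the printed per-group SDs) and projected back to the nearest
  correlation matrix by eigenvalue clipping.
* **Nuisance structure.** Six smooth motion-like series (integrated white
  noise) leak weakly (amplitude 0.2) into every brain voxel; WM and CSF
  latent series live in their tissue masks. Only the motion series are
  written to the confound TSV — the tissue signals must be *estimated* by
  the pipeline from the masks, as in a real study.
* **Behavior.** `executive_score = β₀ + β₁·r(SN,AN) + ε` per group, with
  β₁ = −1.5 and ε SD ≈ 0.7 in the depression group (planting an
  association of r ≈ −0.5) and β₁ = 0 in controls; depression scores are
  drawn from group-specific clipped normals. Ages come from the published
  group profiles (68.3 ± 6.5 / 71.8 ± 8.2), which also gives the age
  covariate something real to do.
* **Noise.** White Gaussian voxel noise, default SD 1 against spatial
  loadings peaking at 1.

What the phantom does **not** emulate: hemodynamic response convolution,
physiological (cardiac/respiratory) noise spectra, motion-induced spatial
displacement (generation is aligned; registration is out of scope),
spatial autocorrelation of scanner noise, and anatomically shaped
networks. A green recovery test therefore establishes that the pipeline's
estimators are correct and well-calibrated on data satisfying its own
model — it does not establish robustness to registration error or
structured noise.

Model order for the recovery phantom is K = 5, matching the number of
planted networks; the K = 20 contract (exactly twenty z-scored maps on
demand) is exercised separately, where the surplus-component convergence
behavior documented above applies.

# Interpreting the recovery bounds

At T = 150, a single subject-edge correlation has irreducible sampling
noise even for a perfect estimator, so full-pipeline recovery on the noisy
phantom is asserted as: mean absolute per-subject-edge error < 0.1 *and*
every group-mean edge within ±0.1 (the group matrix is the scientific
quantity; measured values are ≈ 0.05 and ≈ 0.03). The strict ±0.02 bound
applies to the zero-noise, confound-free world: nuisance regression
projects the latents onto the confound-complement and thereby shifts
in-sample correlations by up to ~0.07 regardless of estimator quality, so
the exact-recovery claim is only meaningful without planted confounds
(measured error there: < 1e-6).

# Known limitations

* Inter-network correlations are pairwise; no partial-correlation or
  simultaneous multi-network model is provided.
* The network cluster correction is conservative on small graphs (discrete
  sizes), and its null assumes exchangeability of subjects under the
  two-group design.
* NIfTI support is a minimal NIfTI-1 reader/writer (single-file `.nii` /
  `.nii.gz`, common datatypes, scl slope/intercept, time-unit handling)
  validated against an independent reference implementation in the test
  suite; exotic header extensions and two-file images are not supported.
* No slice-timing, motion correction, registration, scrubbing or
  global-signal regression: inputs are assumed aligned and the confound
  model is regression-based only.
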