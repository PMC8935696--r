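---
title: "Models and methods behind psdflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind psdflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`psdflow` reconstructs, as reusable and tested code, the measurement chain
of a cross-sectional lifespan study of the parasagittal dural (PSD) space:
phase-contrast flowmetry through the cerebral aqueduct, semi-supervised PSD
segmentation on T2-weighted volumes, tissue volumetry on T1-weighted
volumes, and the cohort statistics tying PSD volume to age and CSF flow.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data experiments do and do not establish.

## Phase-contrast flow quantification

Phase-contrast MRI encodes through-plane velocity in the image phase,
`φ = π · v / venc`, so `venc` (here 12 cm/s, the protocol value for CSF in
the aqueduct) is the velocity mapped to a phase of π. Velocities beyond
±venc alias: the stored phase wraps into (−π, π] and a true `v` appears as
`v − 2·venc`. The analysis chain is:

1. **Aqueduct mask.** The time-averaged magnitude image is thresholded
   (Otsu by default, overridable) and the connected component closest to
   the image centre is kept. The mask area `A` (voxel count × in-plane
   voxel area) is the only geometric quantity that enters the flow.
2. **Velocity and flow.** `v = venc · φ / π` per voxel and bin; the profile
   is `Q(b) = v̄(b) · A` in mL/s (1 cm³ = 1 mL), with `v̄(b)` the in-mask
   mean velocity of cardiac bin `b`.
3. **Aliasing correction.** Cardiac gating identifies the systolic epoch,
   where aqueductal flow is known to be anterograde. Within the systolic
   window, any mean velocity below `−(venc − margin)` is treated as a
   single wrap and restored as `v + 2·venc`. The default window is the
   absolute-maximum |v| bin and its two cyclic neighbours (with aliasing
   the wrapped systolic peak *is* the largest-|v| bin); the default margin
   is 2 cm/s. Both are configurable: the margin must exceed
   `v_peak − venc`, so studies expecting peaks up to ~15 cm/s at venc 12
   should widen it to ~3.5 cm/s, and when the systolic timing is known
   from gating the window can be set to the full systolic fraction. The
   correction is idempotent, and a value still below the bound after one
   unwrap is flagged (possible double wrap) rather than altered again.
4. **Metrics.** With uniform bin width `Δt = T/n`, the anterograde and
   retrograde volumes per cycle are rectangle-rule sums of `max(Q, 0)` and
   `max(−Q, 0)`; net flow is their difference, absolute flow their sum, and
   the regurgitant fraction their ratio. Only 12 samples of the cycle
   exist, so higher-order quadrature would be spurious precision. The
   regurgitant fraction is defined on per-cycle volumes (a peak-flow ratio
   is available via `rf_mode = "peak"`); an all-retrograde profile yields
   `NA` with an explicit reason rather than a division error.

## PSD segmentation

T2-weighted contrast separates the parasagittal complex: the sinus lumen is
markedly hypointense, the PSD space hyperintense. The pipeline is
bias-correction → template alignment → envelope segmentation → mixture
labeling → native-space volumetry.

* **Bias correction** alternates a k-class intensity classification
  (quantile-seeded k-means, deterministic) with a least-squares fit of an
  order-2 3D polynomial to the log-intensity residual, and divides the
  resulting unit-mean field out. The field is estimated on bright voxels
  only, because additive noise on dark tissue is large and skewed on the
  log scale. This corrector targets the smooth polynomial family the
  phantom generator itself uses; it is a deliberate simplification of
  spline-based correctors, adequate because both the simulated field and
  typical scanner inhomogeneity are low-order. On bias-free noisy input
  the estimated field stays within roughly ±2%.
* **Registration** is an axis-aligned affine (translation + per-axis
  scale) optimised by Nelder–Mead on negative normalised cross-correlation
  over a 2×-decimated grid, initialised from intensity centroids. Full
  diffeomorphic registration is deliberately out of scope: phantoms are
  generated near-aligned, and the affine family recovers their offsets to
  sub-voxel accuracy. This is a known fidelity limit for clinical data,
  where nonlinear alignment of the parasagittal region is standard.
* **Envelope segmentation** uses a compact two-level 3D U-Net (two 3³
  convolution layers per level with leaky-rectifier activations — in a
  network this narrow standard rectifiers can die wholesale at unlucky
  initialisations — one 2× max-pool, nearest-neighbour upsampling with a
  skip concatenation, sigmoid output); a deterministic random-restart
  guard reinitialises training if the loss fails to leave chance level trained on
  synthetic (volume, truth-envelope) pairs with Adam on randomly sampled
  overlapping patches, half centred on foreground. Patch size 16,
  stride 8, 4 base channels, 24 epochs of 48 patches per volume,
  voxelwise binary cross-entropy (Dice loss available). Training pairs are
  built through the same bias-correction and registration path the
  deployed network sees — the study's training data was likewise
  template-aligned — because the interpolation smoothing that resampling
  introduces on a 2-voxel-thin shell is part of what the network must
  tolerate; truth envelopes are carried to template space by trilinear
  (soft) transfer thresholded at 0.5, which avoids nearest-neighbour label
  jitter. The network is intentionally tiny: phantom contrast is far
  easier than clinical data, and the aim is a faithful, testable
  implementation of the patch-CNN stage, not clinical-grade weights.
  Backpropagation is hand-written against the package's own convolution
  kernels and verified against numerical differentiation in the tests.
  Prediction averages patch probabilities over overlaps, thresholds at 0.5
  and keeps the largest connected component; an empty result is flagged,
  not fatal. A guard warns when inputs are coarser than 0.8 mm isotropic,
  where parasagittal delineation is known to degrade.
* **Mixture labeling.** The predicted envelope is first transformed back
  to the native grid (nearest-neighbour); the mixture is then fit on
  native intensities, where the PSD/venous contrast is crisp — fitting on
  resampled intensities is measurably less stable because interpolation
  mixes the thin PSD shell with its neighbours. Within the native-space
  envelope a 2-component univariate Gaussian mixture is fit by EM (initialised at the 25th/75th
  intensity percentiles, log-likelihood monotone by construction,
  convergence at gain < 1e−8). Each voxel takes its
  maximum-a-posteriori component; the higher-mean component is PSD, the
  lower-mean venous. Posterior ties go to venous — a voxel with no
  intensity evidence either way is not counted as dural space. Components
  with equal means cannot be oriented and raise an error. Point-mass
  clusters are legitimate (variances are floored, not failed); a
  vanishing component weight is a genuine collapse and errors with the
  component index.
* **Volumetry.** Volume is label count × voxel volume on the native grid;
  all reported PSD volumes are native-space. A label map produced in
  template space can equivalently be pulled back through the inverse
  affine with nearest-neighbour interpolation.

## Tissue volumetry

The brain mask is foreground threshold → morphological closing → largest
component. Otsu's threshold on a T1-like histogram separates the dominant
tissue modes, not air from tissue, so the mask uses half the Otsu value — a
standard brain-extraction heuristic. Tissue classification is a 3-class
univariate EM inside the mask, components ordered by mean and mapped
CSF < GM < WM for T1 contrast (inverted for T2-like inputs). Every in-mask
voxel is labeled, so class volumes sum exactly to the mask volume. No
Markov-random-field spatial prior is used (the reference method has one);
plain EM suffices at phantom contrast, and this is documented as a fidelity
gap for real data.

## Cohort statistics

The three model specifications regress (by default) PSD volume on
demographics + ICV (M1), demographics + CSF/GM/WM volumes (M2), and CSF
flow metrics + demographics (M3). "GLM" here is Gaussian-identity ordinary
least squares — the study reports linear fits with Wald bands and names no
other family. Wald 95% intervals use the 1.96 normal quantile (a t-quantile
switch exists), with matching two-sided Wald p-values. Sex is coded 0/1
with female = 0. q-values are Benjamini–Hochberg adjusted within each
model's non-intercept term family, and within the correlation panel for
Spearman tests; which term families entered the original corrections is not
stated, so this per-model convention is an explicit, configurable
assumption. Spearman correlation is the Pearson correlation of mid-ranks
with a t-approximation p-value, replaced by exhaustive permutation
enumeration at n ≤ 8; Kruskal–Wallis uses the tie-corrected H and
chi-square p (via `kruskal.test`), with an exact-permutation option at
total n ≤ 12. Age groups are young 20–39, middle 40–59, older 60–83,
boundaries inclusive. Summaries use sample (n−1) standard deviations; all
tests are two-sided.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated.

* **Head phantom.** Schematic geometry with analytically known volumes: an
  ellipsoidal cranial cavity (default semi-axes 19 × 22 × 18 mm at
  0.78 mm isotropic voxels — the T2 protocol resolution, at desk scale so
  that a full volume is 64³ voxels), concentric GM/WM shells, a
  ventricular CSF sphere, and at the vertex a sinus tube of radius 2.5 mm
  wrapped in a PSD shell of thickness 2 mm. The PSD is modeled as a full
  annulus rather than two lateral pockets so its truth volume is exactly
  `π((r+t)² − r²)L`; the downstream operators depend only on topology and
  contrast, not anatomical shape. Intensities are class mean × smooth
  multiplicative bias (random quadratic with exact peak-to-trough
  amplitude, default 10%) + Gaussian noise. On T2 the PSD shell (mean 120)
  is the brightest class and the sinus (mean 10) the darkest, mirroring
  the hyper-/hypointense anchors that make the complex separable; PSD/CSF
  contrast is idealised relative to clinical data, which is one reason
  phantom Dice scores should not be read as clinical accuracy.
* **Gated series.** Readouts every 50 ms over a five-minute acquisition
  are assigned to 12 cardiac bins by their phase within a jittered beat
  (retrospective gating) and averaged. The waveform is biphasic: an
  anterograde half-sine over the systolic fraction, a retrograde half-sine
  over the remainder. The study figures show only a schematic waveform, so
  this parametric form is a modeling choice. The default systolic fraction
  is 0.6: with the published peak flows (0.10 / −0.12 mL/s) this yields a
  net flow of ~0.45 mL/min, matching typical ventricular CSF production,
  and a regurgitant fraction below one. Phase wrapping is applied to the
  bin-averaged phase, which equals the physically correct circular
  (phasor) mean to second order in the within-bin spread and is exactly
  the unwrapped average below venc. Analytic truth is the per-bin mean of
  the continuous waveform; the realized noise-free profile of the actual
  readout times is also returned and round-trips through the
  quantification stage to float precision.
* **Cohort.** Subjects are drawn from a Gaussian copula whose latent
  Pearson correlations are adjusted (`ρ_P = 2 sin(π ρ_S / 6)`) so the rank
  correlations hit the published pairwise Spearman targets; cells the
  study does not report are filled with weak plausible values chosen once
  to keep the matrix positive definite. Marginals follow the published
  whole-cohort means and SDs; age is uniform on [20, 83]. Volumes are
  floored at small positive values and flows kept directional, a mild
  truncation only relevant in the far tails. Sex is an independent
  Bernoulli draw (42/65 female) with a configurable, mean-centred PSD
  offset for males (default +1.2 cm³ — no effect size is published, so
  this is a free parameter); the offset slightly attenuates realized rank
  correlations involving PSD, as any exogenous covariate would.
* **Study runner.** `run_synthetic_study()` maps each cohort row onto
  phantom geometry (semi-axes scale with the cube root of ICV, shell cuts
  solve the tissue fractions, the PSD shell thickness solves the annulus
  volume, mildly truncated at the geometric feasibility limit) and onto
  waveform peaks, runs every stage per subject, and fits the three models
  plus the correlation panel on the *measured* table. Degenerate
  covariates in tiny cohorts (e.g. a single-sex draw) are dropped from the
  model with a message. All outputs carry a provenance block (seed,
  package version, config hash), and the whole pipeline is a pure
  function of the global seed.

## Problem sizes and numerical choices

The shipped experiments use 64³ phantom volumes, 10 training + 5 held-out
phantoms for the network, 20 phantoms for end-to-end PSD recovery, 100
seeded series for flow recovery, 500 cohort replicates for Spearman
coverage, and 1000 permutations for the type-I calibration — sizes chosen
so the complete suite runs on a single desktop CPU core while keeping
Monte-Carlo error well below the tolerances being checked. Tie-breaks,
degenerate inputs and convergence guards are all explicit: EM tolerance
1e−8 on the log-likelihood, registration failure reported with the final
NCC, empty predicted masks flagged rather than fatal, and the aliasing
corrector warning on suspected double wraps.

## What passing tests do and do not show

The synthetic experiments establish internal correctness — that each stage
recovers the generator's ground truth under the stated noise, bias, and
misalignment, and that the statistics match independent oracles. They do
not establish clinical performance: phantom anatomy is schematic, PSD/CSF
contrast is idealised, registration is affine, the EM has no spatial
prior, and the network is far smaller than one trained on expert manual
segmentations. Reported group-level numbers (e.g. cohort marginals,
rank-correlation targets) reproduce the generator's calibration, not new
measurements on the original cohort, whose raw data is not publicly
deposited.
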