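---
title: "Multichannel feature-based diffeomorphic registration of longitudinal lung CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multichannel feature-based diffeomorphic registration of longitudinal lung CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lungreg)
```

## The problem

Radiation-induced lung damage (RILD) after thoracic radiotherapy manifests
on CT as consolidation, fibrotic distortion and lobar collapse. Studying how
the parenchyma evolves between a pre-treatment scan and follow-up scans
months or years later requires deformable registration of the two images —
but the damage itself destroys the assumption that corresponding tissue has
corresponding intensity. An intensity-driven registration happily stretches
an airway into a collapsed lobe because that is what makes the grey values
match. The approach implemented here discards the raw intensities and
registers only anatomical features that remain recognisable across
timepoints: the lung boundary, the main airways, and the vessel trees.

## The model

### Feature channels

Each timepoint is reduced to a three-channel feature image:

1. **Lung-boundary distance transform.** From a binary lung segmentation we
   compute the unsigned Euclidean distance $d$ to the structure boundary
   and compress it through $f(d) = s\,(1 - 1/(1+\min(d, c)))$ with sign
   $s=+1$ outside and $-1$ inside and cap $c = 12$ voxels. The profile has
   its steepest gradient at the boundary (where alignment matters), decays
   with distance, and is exactly flat beyond the cap, so far-away tissue
   exerts no pull. Distances are computed in mm and divided by the
   geometric-mean voxel size, which keeps the 12-voxel cap meaningful on
   anisotropic grids. Binary masks themselves would provide gradient only
   in a one-voxel shell; the compressed distance transform is what lets a
   badly misaligned boundary find its target.
2. **Airway distance transform**, identically constructed from the
   main-airway segmentation.
3. **Frangi vesselness** of the CT: the classical bright-tube likelihood
   from the eigenvalues $|\lambda_1|\le|\lambda_2|\le|\lambda_3|$ of the
   Gaussian-scale Hessian, maximised over scales (default 1–4 mm,
   $\alpha=\beta=0.5$, structureness scale set per scale to half the
   maximum Hessian norm in the region of interest). The response is
   restricted to the lung mask dilated by 10 mm so mediastinal clutter does
   not populate the channel.

The channels are stacked in that fixed order and tagged with a similarity
measure and weight each: SSD with weight 1 for both distance channels and
NMI with weight 2.5 for vesselness — the configuration that drives all
defaults in `reg_config()`.

### Transformation model

The deformation is a stationary velocity field (SVF) parameterised by cubic
B-spline coefficients on a control grid with final isotropic spacing 5 mm.
Exponentiating $+v$ and $-v$ by scaling-and-squaring yields mutually inverse
forward and backward maps, so one set of unknowns gives a symmetric,
topology-preserving registration: the objective sums the similarity of
(reference, warped floating) under $\exp(v)$ and (floating, warped
reference) under $\exp(-v)$, minus a bending-energy penalty. Landmarks are
mapped by integrating the velocity ODE directly with RK4 on the exact
spline, which makes the forward and backward point maps mutually inverse to
integrator accuracy rather than to the resolution of a resampled grid.

### Objective and optimisation

$$\mathcal{O}(v) = \sum_c w_c\, \mathrm{sim}_c(R_c, F_c\circ\exp(v))
                 + \sum_c w_c\, \mathrm{sim}_c(F_c, R_c\circ\exp(-v))
                 - 2\,w_{\mathrm{be}}\, \mathrm{BE}(v)$$

* SSD is the negated mean squared difference (optimum 0).
* NMI is $(H(R)+H(W))/H(R,W)$ from a 64-bin joint histogram in which the
  reference axis is hard-binned and the warped axis is spread with a
  bin-integrated cubic-B-spline Parzen window. The window bandwidth (in
  bins) is exposed: at the `sim_nmi()` default of 0.25 an intensity at a
  bin centre contributes to a single bin, so the identity NMI(A, A) = 2
  holds exactly for bin-quantised images while the measure remains
  differentiable; the engine default (`reg_config()$nmi_bandwidth = 1`)
  uses the conventional full-width kernel, which we found converges to
  better optima on the phantom. Similarity is evaluated inside the lung
  mask dilated by 20 mm so background does not dominate the histograms.
* LNCC is implemented behind the same interface (Gaussian-window local
  correlation) for parity with the measures considered during the original
  parameter search, but is not a default anywhere.
* The bending energy is the mean over the image domain of all squared
  second spatial derivatives of the velocity spline (mixed terms counted
  twice), analytic via B-spline second-derivative kernels, and zero exactly
  for affine fields. `bending_energy()` reports it per mm — the form a
  finite-difference oracle can verify on the dense field. The reference
  weight 0.001, however, belongs to the FFD convention in which derivatives
  are taken per control-grid unit; for isotropic spacing $s$ the two
  conventions differ by the factor $s^4$, so the engine scales the
  configured weight by $s^4$. With the per-mm reading the penalty would be
  hundreds of times weaker than intended and the optimiser drifts into
  near-folding solutions.

Optimisation is conjugate-gradient ascent (Polak–Ribière with restarts)
over a three-level pyramid: control spacing 20 → 10 → 5 mm (dyadic B-spline
subdivision between levels, exact for the represented field) with images
downsampled 4×/2×/1×. The gradient chains the per-voxel similarity
derivative with the spatial image gradient and the B-spline basis,
approximating $\partial\exp(v)/\partial v$ by the identity — standard for
SVF models; correctness of each analytic ingredient is verified against
finite differences, and monotone ascent is enforced by a backtracking line
search on the exact objective. Steps are expressed in mm of maximum
control-point motion and capped at one voxel of the current level. A step
is accepted only if it improves the objective *and* keeps the minimum
Jacobian determinant of the full-resolution forward map above 0.2 (or
improves it) — the same plausibility band the evaluation module flags as
extreme. Two details matter here. The guard must be evaluated at full
resolution: a coarse level grid can miss fine-scale folding, which then
silently locks the finer levels out. And the floor must sit at a
plausibility level rather than just above zero: with a floor of 0.01 the
optimiser happily rides the constraint into contractions of two orders of
magnitude, because (see below) the vesselness NMI rewards them. A level
stops when the gradient norm falls below $10^{-4}$ of its initial value,
the iteration cap (300) is reached, or the trailing ten accepted iterations
contribute less than 0.5% of the gain made so far — the long tail beyond
that point buys objective digits, not landmark accuracy.

Two further design choices protect the sparse vesselness channel from
pathological optima, both config-exposed:

* **Joint-support masking.** A vesselness map is ~99% exact zeros; its
  entropies are tiny, and NMI — a ratio of entropies — can then be
  *increased* by deformations that squeeze vessels of one image into
  regions where the other has none (we measured the wrong solution scoring
  above the ground truth on a consolidation phantom). The channel is
  therefore evaluated only where **both** timepoints contain structure
  (response above 0.05, dilated by 4 mm — the capture radius needed at the
  level where the channel activates). Regions where a structure exists in
  one image only carry no correspondence information, and excluding them
  restores the ground truth as the preferred optimum.
* **Channel level-schedule.** The vesselness channel enters at the finest
  pyramid level only. At 8 mm resolution vessels are smoothed into mush
  while the boundary and airway channels are still crisp, so the coarse
  levels are best driven by the large-scale structures — the same
  observation that led to the channel weighting in the first place — and
  the vessels then refine an already sub-voxel-accurate alignment.

The intensity-only baseline (`register_intensity()`) is the identical
engine with a single NMI channel on raw HU, sharing spacing, penalty and
pyramid — the comparison that motivates the multichannel design.

### Rigid initialisation

`rigid_block_matching()` matches high-variance 4³ reference blocks against
the floating image by exhaustive integer NCC search and fits the rigid
transform by a trimmed Kabsch fit (best 50% of residuals), iterating up to
five times. Block selection uses bone-windowed intensities (clamp to
[100, 1500] HU); when the window leaves too few usable blocks — as on the
bone-free phantom — selection falls back to the full intensity range before
giving up. The pipeline folds the rigid stage into the floating stack (one
resampling) and into the target landmark coordinates, so the deformable
stage and the evaluation both operate on a common grid.

## The synthetic phantom

No public dataset accompanies the clinical cohort, so the package ships a
generator whose output exercises every stage:

* soft-tissue background (+40 HU), two ellipsoidal lungs (−800 HU), a
  trachea with two bronchial generations (lumen −1000 HU), and two
  recursive binary vessel trees per lung (0 HU, four bifurcation
  generations, radius shrinking per generation). Bifurcation coordinates
  are recorded analytically as landmarks — the 96³ @ 2 mm default yields
  59, comfortably above the ~40–65 per-case counts typical of manual
  placement. Masks come from the same analytic geometry, with the airway
  lumen excluded from the lung mask.
* the ground-truth deformation is itself an SVF (40 mm control spacing), a
  Gaussian coefficient draw plus a random bulk drift, rescaled so the
  exponentiated forward map's maximum displacement hits the requested value
  within 5% and verified diffeomorphic. The drift emulates the
  posture/inspiration offset that dominates real longitudinal pairs and
  makes the mean landmark displacement a substantial fraction of the
  maximum (≈ 9.7 mm mean for a 15 mm maximum), so the recovery experiment
  starts from a genuinely misaligned state.
* RILD-like appearance change: an ellipsoidal consolidation patch covering
  a configurable fraction (default 25%) of one lung is pulled toward
  −50 HU with a smooth border — intensities change, geometry and landmark
  truth do not. An optional atelectasis mode adds a contractive velocity
  component instead. Because follow-up masks are deformed baseline masks,
  the distance channels are exactly edit-invariant; the vesselness channel
  is not (vessels inside the patch vanish, as they do in real
  consolidation), which is precisely what makes the robustness experiment
  non-trivial.

The phantom is a caricature by design: no cavitation, pleural effusion,
breathing artefacts, scanner noise or segmentation error. Passing its tests
demonstrates that the machinery recovers smooth deformations under feature
consistency and degrades gracefully under intensity-only change; it does
not certify clinical accuracy on real RILD cohorts.

## Evaluation protocol

`landmark_distance_pre()` is the Euclidean distance between paired
landmarks with no deformable transform; `landmark_distance_reg()` maps each
set through the opposite direction of the symmetric result and averages the
two distances per landmark before any summary — the bidirectional average.
`summarize_case()` reports mean/median/SD (sample convention) per case;
`transform_quality()` adds Jacobian statistics with an "implausible" flag
for any non-positive determinant. Two anchors bracket every real result:
the ground-truth transform gives D_reg at integrator accuracy (< 10⁻³ mm)
and the identity gives D_reg = D_pre exactly.

## Problem sizes and numerical choices

The shipped experiments run on one CPU: the 96³ phantom builds in ~15 s,
the feature stack in ~10 s per timepoint, a multichannel registration in a
few minutes and the intensity baseline in about two. Tolerances that matter:
squaring steps are chosen so the scaled velocity moves < 0.25 voxel
(bounded to 4–10); compositions interpolate displacement linearly with
edge-clamped extrapolation; out-of-volume resampling pads with −1000 HU for
CT, the saturation value for distance channels, and 0 for masks and
vesselness; degenerate (constant) images define NMI = 1 with zero gradient;
the control grid is padded three nodes beyond the image. Determinism: every
stochastic element (phantom geometry, truth field) flows from one integer
seed, and the optimiser is deterministic, so a seed + config pair
reproduces convergence logs bitwise.

## Known limitations

* The registration engine requires axis-aligned voxel-to-world affines
  (general orientations are read and written, but not registered).
* $\partial\exp(v)/\partial v \approx I$ biases the gradient direction at
  large velocities; the line search guarantees ascent but convergence can
  slow for displacements far beyond the control spacing.
* The rigid stage assumes comparable fields of view; it does not handle
  the stitched or truncated scans seen in multi-centre data.
* Vesselness inside dense consolidation is uninformative in both real and
  synthetic data; accuracy there rests on the boundary/airway channels and
  the smoothness of the model, and per-landmark errors inside an edited
  patch remain larger than outside it.
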