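---
title: "Hybrid FFD + viscous-fluid registration: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid FFD + viscous-fluid registration: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In adaptive radiotherapy a planning CT (pCT) must be aligned to an in-room
cone-beam CT (CBCT) so that contours and annotated points drawn on the
planning scan can be propagated to the treatment-day anatomy.  Rigid
alignment cannot follow neck flexion, organ filling or tumour change, so a
deformable registration (DIR) is needed; and because CBCT intensities are
not on the CT Hounsfield scale (nonlinear detector response, cupping and
shading artifacts, noise), the similarity measure must tolerate an unknown,
spatially varying intensity relationship.  Mutual information (MI) is the
standard answer.

`hybridreg` implements a hybrid DIR: a cubic B-spline free-form deformation
(FFD) on a sparse control lattice supplies a smooth initial estimate of the
warp, and a viscous-fluid stage — with the Navier–Stokes solve simplified
to a Gaussian convolution of an MI-derived force field — refines it into a
dense per-voxel displacement.  An FFD-only mode provides the ablation
baseline, mirroring the comparison design of the clinical literature this
package's evaluation battery is modelled on (TRE of annotated points, Dice
coefficient and Hausdorff distance of propagated organs at risk, paired
t-tests between methods).

## The model

**Geometry.** An `image3d` is a 3D intensity array with voxel spacing
`s` (mm) and origin `o` (mm); voxel index `i` (0-based) sits at
`x = o + i*s`.  All displacements are stored in mm.  Warping is backward:
a `displacement_field` `u` lives on the fixed grid, and the warped moving
image is `m(x + u(x))`, trilinearly interpolated, with out-of-extent
samples set to the moving image's minimum (air in CT-like volumes).

**Similarity.** For reporting, MI is computed from a hard-binned joint
histogram over each image's `[min, max]` range, in nats
(`MI = sum p log p/(p_f p_m)`); the log base is an internal convention (the
source literature does not state one).  For *optimization* the histogram
uses Parzen binning in the Mattes convention — a tent kernel along the
fixed axis and a cubic B-spline kernel along the moving axis, so MI is
smooth in the moving intensities and its derivative vanishes at kernel
peaks — optionally Gaussian-smoothed
with a 1-bin Parzen kernel, over percentile-clamped intensity ranges
([0.5, 99.5] by default) that are frozen per pyramid level.  Partial-volume
binning is what makes the objective effectively C^1 in the displacements:
with hard binning MI is piecewise-constant in intensity and every line
search stalls on bin-crossing noise (we measured a correlation of only
~0.07 between the analytic gradient and finite differences under hard
binning, vs ~0.96 for the per-sample intensity derivative under PV
binning).

**Force field.** The fluid stage is driven by
`F(x) = L'(f(x), m(x)) * grad m(x)`, where `L'` is the exact derivative of
the PV-binned, Parzen-smoothed MI with respect to the moving intensity
(the marginal-in-f term cancels; the Parzen kernel transfers onto the
log-ratio lookup table by symmetry of the bilinear form), and `grad m` is
the central-difference spatial gradient of the warped moving image.  The
force therefore points in the direction of locally increasing MI and
vanishes where the moving image is flat.  A sum-of-squared-difference
force (`(f - m) grad m`) is available behind a flag for mono-modal tests.

**FFD stage.** A cubic B-spline lattice (`ceil(extent/spacing) + 3` points
per axis) is optimized by gradient ascent on MI; the gradient with respect
to each control displacement is the B-spline-weighted aggregation of the
per-voxel force.  Steps use an Armijo-style backtracking line search
(initial step 0.4x the control spacing), stopping at `max_iter` (default
30 per level, the conventional multi-scale setting), when no backtracked
step improves MI, or when the relative MI improvement over 5 accepted
iterations falls below 1e-4.

**Fluid stage.** Each iteration computes the force, convolves it with an
isotropic unit-sum Gaussian (`sigma_fluid`, default 4 mm) into a velocity,
forms the increment `u <- u + dt (v - J_u v)` (the material transport term
`-J_u v` can be disabled; the source description is ambiguous on it),
smooths the field (`sigma_field`, default 2 mm), re-warps, and re-evaluates
MI.  The time step is normalized so the fastest voxel moves at most
`0.4 * min(spacing)` mm.  A trial update is kept only if it improves the
objective; rejections halve an adaptive step scale (which recovers on
acceptance).  The stage returns the best-objective field encountered
*including the initial one*, so an already-registered pair comes back
unchanged — this is what makes the clean null-registration property
exact.  A demons-style
per-voxel force normalization is available (`normalize = "demons"`); it
converges faster on clean mono-modal pairs but chases noise on degraded
ones, so the default keeps the raw force magnitude as an evidence weight.

**Topology safeguard.** `det(I + grad u)` is monitored; if the residual
field's minimum Jacobian falls below `jac_min = 0.5`, the current warped
image becomes the new template and the residual resets (regridding), with
fields composed so the total warp is preserved.  The returned total field
on the synthetic suite always satisfies `min det > 0`.

**Acceptance rule (both optimizers).**  Binned MI estimators can be
inflated by deformations that exploit the estimator rather than the
alignment: hard binning rewards overfitting one bin grating / noise
realization, partial-volume binning rewards pulling samples toward bin
centres.  On a degraded/clean pair of identical geometry these artifact
gains let a perfectly registered pair creep 1–3 mm if every positive
`dMI` is accepted.  Two guards are shipped: a trial step must improve
*both* the hard-binned and the PV-binned Parzen-smoothed MI (each
artifact family inflates only its own estimator), and the improvement
must exceed `accept_k * bins^2 / n` nats — the statistical resolution of
an `n`-sample, `bins^2`-cell histogram — with `accept_k = 0.05`.  This is
the accuracy-optimal point: raising `accept_k` to 0.2–2 shrinks the
residual cross-modal null drift from ~0.7 voxel to ~0.2–0.4 voxel but
measurably worsens ground-truth recovery.  A genuinely displaced MI
optimum remains (see limitations); no acceptance rule can remove it.

**Multi-scale pipeline.** A Gaussian pyramid (default 3 levels, halved per
level) is processed coarse to fine.  In both modes every level runs an FFD
stage whose control spacing follows a ladder (5 mm at full resolution,
doubled per coarser level); in hybrid mode a fluid stage follows at every
level.  The hybrid is therefore a strict superset of the FFD-only
baseline, and disabling the fluid (`fluid_config(max_iter = 0)`)
reproduces `ffd_only` bit for bit.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `bins` | adaptive: `n^(1/3)` clamped to [16, 64] | — | 64 bins at full resolution is the CT/CBCT convention; coarse pyramid levels have too few samples for 64 bins |
| `parzen_sigma_bins` | 1 | bins | stabilizes sparse joint histograms; exact gradient transfer |
| `cp_spacing_mm` | 5 (x 2 per coarser level) | mm | "sparse" relative to voxels but dense enough to express neck flexion |
| `ffd_max_iter`, `fluid max_iter` | 30 / level | — | the one iteration cap stated in the source parameterization |
| `sigma_fluid_mm` | 4 | mm | force-to-velocity kernel; below ~2 mm the fluid chases degradation noise (measured: it *worsened* endpoint error) |
| `sigma_field_mm` | 2 | mm | keeps the field continuous between increments |
| `max_step_mm` | 0.4 x min spacing | mm | explicit-flow stability |
| `jac_min` | 0.5 | — | standard regridding threshold |
| plateau rule | rel. improvement < 1e-4 over 5 iter | — | the "cannot be further minimized" stopping disjunct |

## The synthetic world

`make_phantom()` builds a head-and-neck-like digital phantom: a soft-tissue
body ellipsoid; a bright vertebral column of stacked blocks with a spinal
canal and cord; an airway with a larynx-like collar; an air-filled oral
cavity; a mandible-like bone bar; a parotid-like gland; and five bright
marker discs (P1–P5) on the column at distinct axial slices, mimicking
small-circle point annotations.  Soft tissue carries a smooth random
texture (sd 30 by default) so similarity metrics have structure, plus
faint noise.  Defaults are 64^3 voxels at isotropic 2 mm for test speed;
the clinical pCT grid (1.27 x 1.27 x 3 mm) is one `phantom_spec()`
argument away.

`make_ground_truth_warp()` draws control displacements uniformly from
`[-max_disp, max_disp]^3` on a 32 mm lattice with the diffeomorphism guard
`max_disp <= 0.4 * cp_spacing` and a verified positive Jacobian.
`degrade_to_cbct()` applies a strictly monotone gamma remap (0.5), a
multiplicative low-frequency shading field (±15%, ~32 mm scale) and
additive Gaussian noise (3% of the intensity range, ~50 HU — clinically
plausible CBCT noise).

**What a green test does and does not establish.**  The phantom has
piecewise-near-constant tissue classes, exactly diffeomorphic smooth
ground truth, and no scatter/beam-hardening physics, truncated
field-of-view, or anatomy change (tumour shrinkage, organ filling) — so
passing recovery tests demonstrates the machinery optimizes the right
objective, not clinical-grade accuracy.  Conversely the phantom is
*harder* than real anatomy in one respect: within-class intensity is
nearly uniform, so there is less texture for MI to grip than in real
tissue.

**A deliberate deviation: degradation strength.**  The original design
brief asked the degradation defaults to push NCC(clean, degraded) into
[0.6, 0.9] *and* to stay weak enough for MI registration to converge.  On
this phantom those goals are mutually exclusive: the intensity histogram
is nearly bimodal (air vs tissue), and any monotone remap of a two-cluster
distribution is almost affine on the clusters, so NCC barely drops; the
band is only reachable with noise ≥12% of the intensity range or shading
≥40%, and at that strength the *global optimum of MI itself* moves 1.7–2 mm
away from the ground truth (verified by evaluating MI along the straight
path from the recovered field to the truth: the recovered field has higher
MI than the truth).  No optimizer can fix an objective whose optimum is
elsewhere.  The shipped defaults therefore keep the spec's ±15% shading
and use realistic noise, landing at NCC ≈ 0.95–0.97; stronger settings
remain available through `degrade_config()`.

## Numerical choices and edge cases

- Intensity windowing ([0.5, 99.5] percentiles) and frozen bin edges per
  level prevent histogram drift between iterations.
- Constant images: histogram ranges are widened by one unit; NCC raises an
  error rather than returning a silent 0; `pre_translate` warns and
  returns a zero shift.
- Boundary handling: Gaussian kernels are renormalized where truncated
  (constants are exact fixed points); spatial gradients use one-sided
  differences at faces; B-spline lattice indices are clamped at the far
  image edge (the evaluation point then has local coordinate t = 1, still
  a partition of unity).
- Mask warping is nearest-neighbour by default (binarity without hidden
  smoothing); `linear_threshold` is available.
- Ties in `pre_translate`'s exhaustive NCC search resolve toward the
  smaller shift so an aligned pair returns zero.
- The t-test p-value uses the regularized incomplete beta function
  directly (`pbeta(df/(df + t^2), df/2, 1/2)`), verified in tests against
  `stats::t.test`.

## Design choices where the design was genuinely open

- **Optimizer family.**  Backtracking gradient ascent for the FFD.  We
  prototyped L-BFGS with the same analytic gradient: on degraded pairs it
  reaches higher MI and *worse* geometry (overfitting the objective's
  imperfection), so the conservative optimizer is the default.
- **Hybrid FFD lattice.**  An earlier draft used a single 32 mm lattice on
  the coarsest two levels only ("sparse control points" read literally);
  in paired 10-seed runs it lost to the FFD ladder on 6/10 cases, so the
  hybrid now shares the baseline's ladder and adds fluid refinement —
  which also makes the ablation comparison exactly nested.
- **Fluid kernel widths.**  2 mm / 1 mm (first draft) made the fluid a net
  negative under degradation (+0.03 mm endpoint error on average); 4 mm /
  2 mm removes the systematic penalty.  With the artifact-guarded
  acceptance rule in place, the fluid's remaining effect on this phantom
  is neutral-to-slightly-positive (it neither helps nor hurts beyond the
  FFD ladder at the phantom's information limit) — the clinical-scale
  advantage reported for hybrid-over-FFD does not reproduce at desk
  scale, and the package reports that outcome rather than tuning around
  it.
- **Transport term.**  Included by default; `transport = FALSE` gives the
  plain `u + dt v` reading.
- **Hausdorff convention.**  Computed between surface voxel sets (members
  with a non-member 6-neighbour) in mm; both directed values and the
  symmetric maximum are reported, the symmetric maximum being the headline
  number.
- **TRE distances** are 3D Euclidean (the in-plane reading is not
  distinguishable from the source material).

## Known limitations

- Marker TRE is quantized by nearest-neighbour mask propagation
  (~half a voxel); markers that start nearly aligned (pre-TRE below the
  quantization scale, including exactly 0, which a random warp can
  produce) cannot be strictly improved, so the "every marker improves"
  reading of the recovery criterion is not attainable in general.  The
  acceptance test states the strict form and reports the per-marker table.
- Accuracy on degraded pairs saturates around 1.5–2 mm mean endpoint error
  (sub-voxel at 2 mm spacing) — consistent with the 2–3 mm TREs reported
  for CT/CBCT DIR clinically, and an information limit of global MI on
  this phantom rather than an optimizer budget limit.
- On a degraded/clean pair of identical geometry the binned-MI optimum is
  genuinely displaced from zero deformation (every estimator variant we
  measured prefers a ~1 mm localized warp), so the cross-modal null test
  settles at ~0.7–0.8 voxel rather than the 0.1-voxel ideal; the clean
  self-pair null is exactly zero.
- No explicit bending-energy regularization by default (available behind a
  flag); smoothness comes from control sparsity, the fluid kernels, and
  the step caps.
- The rigid pre-alignment assumed by the pipeline is only approximated by
  the integer-voxel `pre_translate()` helper; full rigid/affine
  registration is out of scope, as are DICOM input and dose mapping.
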