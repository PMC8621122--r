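---
title: "Models and methods behind jointkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind jointkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(jointkin)
```

`jointkin` estimates per-bone rigid motion and joint cardan angles from
dynamic CT. This vignette explains the models the package implements, the
parameters that matter and their defaults, the numerical choices made
where the design was genuinely open, and what the synthetic phantom
studies do and do not demonstrate about real data.

## The estimation problem

A dynamic CT acquisition yields an ordered series of 3D volumes
$g_1,\dots,g_T$ of a moving joint, plus (conceptually) a static reference
volume $f$. Bones are rigid, but the joint as a whole is not: each bone
follows its own rigid trajectory, and soft tissue deforms and slides
around it. A single global registration therefore cannot describe the
motion; the workflow instead

1. segments each bone on the reference frame,
2. tracks each bone independently with a rigid transform per timeframe,
   restricted to the bone and its immediate neighbourhood, and
3. converts the per-bone trajectories into anatomically meaningful joint
   angles via landmark-defined, bone-embedded coordinate frames.

## Pairwise registration

All registrations minimize
$\hat\mu = \arg\min_\mu C\bigl(f(x),\, g(T_\mu(x))\bigr)$
over a transform family $T_\mu$, where the cost $C$ is a similarity
metric plus, for the deformable stage, a bending-energy penalty. A
registration result maps fixed-space world points into moving space (the
resampling convention), so propagating an atlas label map onto the target
needs no inverse; propagating atlas *points* onto the target uses the
numeric inverse.

**Stages.** Multi-atlas registration runs rigid → affine → cubic B-spline
free-form deformation, each stage initialized from the previous solution.
The affine stage re-optimizes the full matrix starting at the rigid
solution; the B-spline stage optimizes a displacement field $d(x)$ acting
before the frozen affine part, $T(x) = A(x + d(x))$, with the control
grid covering the fixed domain.

**Similarity metrics.** Mean squared intensity difference (MSD, suited to
monomodal CT-to-CT alignment and the default), Pearson normalized
cross-correlation (NCC, robust to linear intensity changes), and mutual
information from a 32×32-bin joint histogram (MI, for nonlinear intensity
relationships). MSD and NCC have analytic gradients; MI uses
central-difference gradients with perturbations equivalent to ~0.3 mm of
displacement (a hard-binned histogram is flat at smaller scales), which
is affordable for the 6–12 parameters of rigid/affine stages but not for
the thousands of a B-spline stage — the deformable stage therefore
accepts MSD or NCC only.

**Optimizer.** Stochastic gradient descent with 2000 random fixed-image
samples drawn fresh each iteration, per-level iteration caps of
2000/1000/1000 (rigid/affine/B-spline), four resolution levels (Gaussian
pyramid, smoothing $\sigma$ = half the downsampling factor), and the
decaying gain $a_t = a/(A + t)^{\alpha}$ with $\alpha = 0.602$, $A = 20$
and $a$ auto-scaled from a gradient-magnitude probe at the starting
point. Three engineering details matter for accuracy and are part of the
package's design:

* *Trust region.* The probe gain is arbitrarily large when the start is
  already near an optimum (tiny gradients), so every update is capped at
  a step length that begins at `step_mm` (default 1 mm) and decays on the
  same schedule as the gain. Without the cap, a warm-started registration
  can be catapulted out of its basin by the first few noisy gradients.
* *Random-coordinate sampling.* Samples are drawn at a random voxel plus
  a uniform jitter within its cell, and the fixed image is interpolated
  too. Sampling exactly at voxel centres makes only the moving image pay
  an interpolation penalty, and that penalty depends on the transform —
  the metric optimum then drifts toward lattice-aligned transforms.
* *Finest-level cubic interpolation.* At the final pyramid level the
  moving (and fixed) image is interpolated with a Catmull-Rom cubic
  kernel; the residual interpolation bias of trilinear interpolation is
  otherwise the accuracy floor for sub-degree rotation recovery. Rigid
  updates use the exponential map and are re-orthonormalized, so the
  rotation block stays in SO(3) to machine precision. Polyak averaging
  over the last quarter of iterations smooths the stochastic jitter of
  the final parameters.

**B-spline specifics.** Cubic tensor-product B-splines on an axis-aligned
world grid; per-level control spacing halves down to
`bspline_final_grid_spacing` (default 16 mm — about the scale of
inter-subject shape variation the atlas warps need to absorb), with exact
dyadic subdivision of the coefficients between levels (two-scale relation
with mask (1,4,6,4,1)/8; a unit test checks the refined field reproduces
the coarse one to 1e-9). The bending-energy penalty (squared second
derivatives of $d$, mixed terms counted twice) is averaged over a 500-
sample subset per iteration with weight 1 relative to the
variance-normalized metric; it discourages high-curvature fields without
measurably flattening 2–3 mm anatomical warps.

**Determinism.** All sampling uses a dedicated xorshift generator seeded
from the configuration; identical inputs and seeds give bit-identical
results, which the test suite asserts end to end.

## Multi-atlas segmentation and label fusion

Each atlas (intensity volume + label map + landmarks) is registered to
the target, its labels resampled with nearest-neighbour interpolation and
its intensities with trilinear interpolation. Fusion is a per-voxel
majority vote over the full label alphabet (background included, ties to
the smallest label — deterministic and order-independent):

* **MV** — all atlases vote;
* **GNCC** — only the $r$ atlases with the highest global NCC against the
  target (evaluated over the target's foreground bounding box, to avoid
  empty-air inflation) vote;
* **LNCC** — at each voxel, the $r$ atlases with the highest *local* NCC
  vote. Local means, variances and covariances come from Gaussian
  smoothing with $\sigma = k$ voxels (default; a boxcar cube of edge
  $2k+1$ is available, since "kernel size" admits either reading), with
  $k = 5$, $r = 3$ as defaults. Zero local variance gives weight 0;
  weights are clipped to $[-1, 1]$.

Joint fusion over the alphabet guarantees a partition of the volume;
per-label binary fusion would need an overlap-resolution rule. As the
kernel grows, the LNCC weight map flattens toward the global NCC, so LNCC
degenerates to GNCC — a property the tests check, as well as exact
agreement of all three fusers with a brute-force per-voxel voter.

Landmarks propagate by the same vote: each atlas contributes a candidate
(its landmark pulled through the registration's numeric inverse), and the
candidate whose atlas has the highest LNCC weight at that position wins.
Atlases whose candidate leaves the target domain abstain; a landmark with
no candidates is flagged missing rather than invented.

## Dynamic tracking

The fused segmentation provides one mask per bone, dilated with a
Euclidean ball of radius 3 voxels (in voxel units, matching how such
protocols state it) so the registration also sees the bone's immediate
surroundings. Tracking registers the *reference* image to every frame —
so $T_{bone,t}$ maps reference points into frame $t$, exactly what
landmark propagation needs — walking outward from the reference index in
both temporal directions and initializing each frame with its
neighbour's solution. Warm-starting is what keeps fast motion inside the
optimizer's capture range: the acceptance suite includes a case where
cold-started registration of late frames fails while the sequential walk
does not. A frame whose registration degenerates keeps the previous
transform and is flagged; downstream kinematics mark such frames invalid
instead of aborting the sequence. MSD is the tracking metric: the
problem is intrasubject and monomodal, where MSD is both adequate and
the cheapest choice.

## Kinematics

A frame definition names an origin landmark, a primary axis (from/to
landmarks, assigned to i, j or k), and a plane landmark with the axis it
closes. The remaining axis is the unit cross product, signed so the triad
is right-handed (det +1) with the plane landmark on the positive side of
its axis; a handedness switch and a per-definition angle sign mask allow
left/right mirror consistency. The rows of the resulting matrix are the
frame's unit vectors expressed in scanner coordinates — the row-vector
convention — and the joint rotation is
$R_{rel} = R_{distal} R_{proximal}^{-1}$ (orthogonal inverse =
transpose). Cardan angles are the intrinsic (mobile-axes) factorization
in ZXY or ZYX order with principal ranges
$(-180,180] \times [-90,90] \times (-180,180]$; near gimbal lock
(middle-angle sine within $10^{-9}$ of ±1) the third angle is set to 0
and a flag raised. Frame definitions are *data* (YAML files, editable per
joint and atlas), not code: the exact landmark-to-axis mapping differs
between joints, scanners and conventions, so the package ships example
definitions (knee, thumb base, and the synthetic phantom) that users are
expected to adapt.

Because the distal and proximal anatomical triads are generally not
aligned at the reference posture, the raw relative rotation is nonzero
there. The kinematic series is therefore referenced to the neutral pose
by default ($R_t R_{ref}^{-1}$, giving exactly (0,0,0) at the reference
frame); `zero_at_reference = FALSE` returns the raw anatomical angles.
Either way, applying one common rigid motion to both bones leaves the
series unchanged — the invariance the acceptance suite checks to
$10^{-9}$ degrees.

## Validation metrics

Overlap: Dice $2|A\cap B|/(|A|+|B|)$, false-positive fraction
$|B\setminus A|/|B|$ and false-negative fraction $|A\setminus B|/|A|$.
Surfaces are 6-connected boundary voxels; distances come from exact
Euclidean distance transforms (Felzenszwalb–Huttenlocher, anisotropic
spacing in mm) evaluated at the opposing surface's voxel centres; the
Hausdorff distance is the larger of the two directed maxima, and
mean/max/SD surface distances are computed over the pooled symmetric set
(the directionality of reported summary surface distances is otherwise
ambiguous, so both the Hausdorff and the pooled maximum are reported
separately even though they coincide by construction). Agreement between
angle series uses Bland–Altman bias ± 1.96·SD limits and the
average-measures absolute-agreement intraclass correlation ICC(2,k) from
the two-way ANOVA mean squares, $(MS_R - MS_E)/(MS_R + (MS_C - MS_E)/n)$;
the single-measures variant is exposed but not the default. All of these
are cross-checked against brute-force enumerations or `aov()` in the
tests.

## The synthetic phantom

No patient data ships with the package; every study runs on a parametric
joint phantom with exact ground truth.

* **Geometry.** Two (optionally three) bones — triaxial ellipsoids or
  capsules — with a dense cortical shell (default 2 mm, intensity 1200)
  around a trabecular core (300) on a soft-tissue background (50),
  additive Gaussian noise (default SD 20). The default joint is a
  64 mm cube at 1 mm spacing holding a tilted 11×8×8 mm proximal and a
  9×6.5×7 mm distal ellipsoid separated by a ~6 mm joint space. The
  tilts and unequal semi-axes make every rigid rotation observable —
  a capsule aligned with the rotation axis would make axial rotation
  recovery ill-posed — and the joint space keeps a 3-voxel-dilated
  tracking mask off the neighbouring bone's cortical edge.
* **Partial volume.** Surfaces are rasterized with a C¹ smoothstep ramp
  over the signed distance, default width 2.5 mm (the reconstructed
  slice thickness of clinical dynamic knee protocols). Hard binary
  rasterization (`pv_ramp_mm = 0`) is available but aliases: a staircase
  edge biases intensity-based registration by degrees, which is a
  property of the discretization, not of the estimator.
* **Landmarks.** Defined analytically (support points of the shapes along
  named directions, optionally inset a few millimetres so they sit inside
  the cortical shell, plus centroids), so ground truth is exact to
  machine precision.
* **Populations.** Atlas populations warp the base phantom with random
  cubic B-spline fields (control spacing 16 mm ≥ 4× voxel spacing,
  coefficient SD = the requested deformation amplitude); fields whose
  sampled Jacobian determinant drops below 0.05 are redrawn from the next
  substream. Images, labels and landmarks warp consistently; tests check
  warped landmarks stay inside their warped bones and that population
  diversity grows with the amplitude.
* **Dynamics.** Frame $t$ re-renders the scene analytically with each
  bone's geometry moved by its ground-truth rigid transform (linear ramps
  over 15 frames by default, mirroring the cine protocols this emulates),
  plus fresh noise. Analytic re-rendering means every frame is a faithful
  sample of the continuous scene; moving a voxelized bone by resampling
  (the fallback for non-parametric atlases) adds interpolation blur to
  the moved bone only and measurably biases tracking.

**What the phantom does not show.** No beam hardening, metal or motion
artifacts, no cropping at the field-of-view edge, no soft-tissue
structure or sliding, and inter-subject variation is a smooth invertible
warp — real anatomical variation includes topology-adjacent changes
(osteophytes, fused joints) that smooth warps cannot express. Passing
the phantom studies therefore demonstrates the correctness and numerical
accuracy of the estimation machinery under its own assumptions, not
clinical-grade performance on pathological anatomy.

## Problem sizes and known limitations

The shipped studies use 64³ volumes, 15-frame sequences and 6-atlas
populations; a full leave-one-out segmentation study runs in minutes on
one CPU, and the whole test suite in well under half an hour. Limitations
worth knowing:

* Single-candidate Dice on the desk-scale phantom saturates near 0.95:
  with bone radii of 7–9 voxels, two independently voxelized warped
  shapes disagree on ~4–5 % of foreground voxels even under a perfect
  transform. Fusion recovers most of this (leave-one-out Dice about 0.94–0.95
  at 3 mm warps); at clinical resolutions the ceiling is far higher.
* The B-spline stage's accuracy is information-limited in homogeneous
  regions; only edges drive it. Its residual on 2 mm warps is ~0.4 mm
  mean displacement error.
* MI is estimated with hard binning and finite differences; it is
  adequate for rigid/affine initialization across intensity remappings
  but is the least precise of the three metrics.
* The bilateral splitter assumes the two sides are separated along a
  known grid axis (configurable); scanner orientation conventions must
  be declared, not guessed.
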