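# jointkin

Automated estimation of in-vivo joint kinematics from dynamic (4D) CT
sequences.

Dynamic CT can image a moving joint as a time series of 3D volumes, but
turning those volumes into clinically useful kinematics normally requires
manual bone segmentation and manual placement of anatomical landmarks on
every dataset. `jointkin` implements a fully automated alternative for
researchers working with musculoskeletal dynamic CT:

1. **Multi-atlas segmentation (MAS)** of a reference frame: every annotated
   atlas is registered to the target by a three-stage intensity-based
   registration (rigid → affine → cubic B-spline free-form deformation),
   solving

   *μ̂ = argmin<sub>μ</sub> C(f(x), g<sub>n</sub>(T<sub>μ</sub>(x)))*

   with MSD, NCC or MI as the similarity C, multi-resolution Gaussian
   pyramids, random sampling (2000 samples per iteration) and stochastic
   gradient descent. Propagated atlas labels are fused per voxel by
   majority vote (MV), by vote among the globally best-correlated atlases
   (GNCC), or by vote among the locally best-correlated atlases within a
   kernel (LNCC, the default, with k = 5 voxels and r = 3 atlases).
2. **Landmark propagation**: each atlas's anatomical landmarks are pulled
   through its registration; an LNCC-weighted vote picks the winning
   position per landmark.
3. **Piecewise-rigid motion tracking**: each segmented bone, dilated by a
   3-voxel ball, defines the region of interest for a masked rigid MSD
   registration of the reference image to every timeframe, walking outward
   from the reference frame and warm-starting each frame with its
   neighbour's solution. The result is a series of rigid transforms
   T<sub>bone,t</sub> per bone.
4. **Cardan-angle kinematics**: landmarks propagated with
   T<sub>bone,t</sub> build bone-embedded reference frames (rows of R are
   the unit vectors i, j, k); the joint rotation is
   R<sub>rel,t</sub> = R<sub>distal,t</sub> R<sub>proximal,t</sub><sup>−1</sup>,
   decomposed into intrinsic cardan angles (ZXY or ZYX).

A validation suite (Dice, false positive/negative error fractions, exact
Euclidean surface distances and Hausdorff distance, target registration
error, Bland–Altman limits of agreement, ICC(2,k)) and a synthetic joint
phantom generator with exact ground truth (labels, landmarks, per-frame
rigid transforms) complete the package, so the whole workflow can be
exercised and validated without any patient data.

## Worked example

```r
library(jointkin)

# a two-bone joint phantom with known ground truth
ph  <- generate_joint_phantom(phantom_spec(noise_sd = 0), seed = 11)
mot <- motion_spec(15L, list(bone_motion(2L, axis = c(0, 0, 1),
                                         angle_total_deg = 28,
                                         translation_total = c(14, 0, 0))))
dyn <- generate_dynamic_sequence(ph, mot, seed = 12, noise_sd = 20)

# track both bones through the sequence
motion <- track_bones(dyn$sequence, ph$labels, dilation_radius = 3, seed = 13)

# accuracy against the exact ground-truth correspondences
lm2 <- ph$landmarks[ph$landmarks$label == 2, ]
tre <- compute_tre(lm2,
                   dyn$landmarks[[15]][dyn$landmarks[[15]]$label == 2, ],
                   motion$transforms[["2"]][[15]])
round(c(mean = tre$mean, max = tre$max), 3)
#>  mean   max
#> 0.025 0.029
```

The mean target registration error of about 0.03 mm (on a 1 mm grid, far
below a voxel) says the 15th frame's rigid pose of the distal bone —
after 28° of rotation and 14 mm of travel — was recovered almost exactly.
Cardan angles follow from the tracked transforms and a pair of
frame-definition files (shipped examples under `inst/extdata/frames/`):

```r
ddef <- read_frame_definition(system.file("extdata/frames",
                                          "phantom_distal.yaml",
                                          package = "jointkin"))
pdef <- read_frame_definition(system.file("extdata/frames",
                                          "phantom_proximal.yaml",
                                          package = "jointkin"))
ks <- kinematics_pipeline(motion, ph$landmarks, ddef, pdef, "ZYX")
head(round(ks[, 1:4], 2), 4)
#>   frame theta_Z theta_Y theta_X
#> 1     0    0.00    0.00    0.00
#> 2     1    1.85   -0.03    0.05
#> 3     2    3.79   -0.07    0.03
#> 4     3    5.86   -0.20    0.10
```

The first angle climbs by the prescribed 2° per frame to within about
0.2°, and the off-axis angles stay near the small values the tilted bone
axis induces (running the same pipeline on the exact ground-truth
transforms gives, e.g., θ = (4.00, −0.07, 0.00) at frame 2).

`run_pipeline()` drives the full workflow (segment → landmarks → track →
kinematics) from one YAML configuration, and
`inst/scripts/jointkin-cli.R` exposes `simulate`, `segment`, `track`,
`kinematics`, `evaluate` and `run` subcommands for shell use.

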