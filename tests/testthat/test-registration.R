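# Registration engine: stage recovery of known transforms, determinism,
# monotone refinement, masked registration, degenerate-overlap handling.
# Phantom pairs are rendered analytically so both images are faithful
# samples of the same continuous scene.

ref_atlas <- function() fixture("reg_ref", function()
  generate_joint_phantom(small_joint_spec(noise_sd = 10), seed = 31))

test_that("self-registration returns the identity", {
  ph <- ref_atlas()
  tf <- register_stage(ph$image, ph$image,
                       registration_stage("rigid", "MSD",
                                          n_resolution_levels = 3L),
                       seed = 32)
  expect_lt(max(abs(tf$matrix[1:3, 4])), 0.05)                  # mm
  expect_lt(rotation_angle_deg(tf$matrix[1:3, 1:3], diag(3)), 0.05)
})

test_that("a known rigid translation is recovered within 0.1 mm", {
  ph <- ref_atlas()
  true_tf <- rigid_from_axis_angle(c(0, 0, 1), 0, translation = c(4, -2, 1))
  spec_m <- small_joint_spec(noise_sd = 0)
  spec_m$bones <- lapply(spec_m$bones, function(b)
    jointkin:::transform_bone(b, true_tf))
  mov <- generate_joint_phantom(spec_m, seed = 33)
  mov$image$voxels <- mov$image$voxels +
    array(rnorm(length(mov$image$voxels), sd = 10),
          dim = dim(mov$image$voxels))
  tf <- register_stage(ph$image, mov$image,
                       registration_stage("rigid", "MSD"), seed = 34)
  expect_lt(max(abs(tf$matrix[1:3, 4] - c(4, -2, 1))), 0.1)
  expect_lt(rotation_angle_deg(tf$matrix[1:3, 1:3], diag(3)), 0.1)
})

test_that("registration is deterministic given the seed", {
  ph <- ref_atlas()
  st <- registration_stage("rigid", "MSD", max_iterations = 300L,
                           n_resolution_levels = 2L)
  a <- register_stage(ph$image, ph$image, st, seed = 35)
  b <- register_stage(ph$image, ph$image, st, seed = 35)
  expect_identical(a$matrix, b$matrix)
})

test_that("masked rigid registration recovers a single bone's rotation", {
  spec0 <- phantom_spec(noise_sd = 0)
  ph <- generate_joint_phantom(spec0, seed = 36)
  c2 <- spec0$bones[[2]]$center
  true_tf <- rigid_from_axis_angle(c(0, 0, 1), 5, center = c2)
  spec_m <- spec0
  spec_m$bones[[2]] <- jointkin:::transform_bone(spec_m$bones[[2]], true_tf)
  mov <- generate_joint_phantom(spec_m, seed = 36)
  mask <- dilate_mask(
    labelmap(array(as.numeric(ph$labels$voxels == 2),
                   dim = dim(ph$labels$voxels)), reference = ph$labels), 3)
  tf <- register_rigid_masked(ph$image, mov$image, mask, seed = 37)
  expect_lt(rotation_angle_deg(tf$matrix[1:3, 1:3],
                               true_tf$matrix[1:3, 1:3]), 0.2)
  expect_lt(max(abs(tf$matrix[1:3, 4] - true_tf$matrix[1:3, 4])), 0.3)
  # the other bone's content was ignored: double bone 1's shift, re-register
  spec_m2 <- spec_m
  spec_m2$bones[[1]]$center <- spec_m2$bones[[1]]$center + c(0, 0, 4)
  mov2 <- generate_joint_phantom(spec_m2, seed = 36)
  tf2 <- register_rigid_masked(ph$image, mov2$image, mask, seed = 37)
  expect_lt(rotation_angle_deg(tf2$matrix[1:3, 1:3],
                               tf$matrix[1:3, 1:3]), 0.1)
})

test_that("masked registration validates its mask", {
  ph <- ref_atlas()
  empty <- labelmap(array(0L, dim(ph$labels$voxels)), reference = ph$labels)
  expect_error(register_rigid_masked(ph$image, ph$image, empty), "empty")
})

test_that("insufficient overlap raises a degenerate-overlap failure", {
  ph <- ref_atlas()
  far <- ph$image
  far$origin <- far$origin + c(5000, 0, 0)
  # without an initialization nothing maps into the moving domain
  expect_error(register_stage(ph$image, far,
                              registration_stage("rigid", "MSD"),
                              seed = 38),
               class = "registration_failure")
  # a moving domain far smaller than the fixed one: fewer than half the
  # samples can ever be valid, and the stage error names its stage
  tiny <- volume(array(100, c(3, 3, 3)), origin = c(23, 23, 23))
  err <- tryCatch(register_pairwise(ph$image, tiny,
                                    registration_config(rng_seed = 38)),
                  error = function(e) e)
  expect_s3_class(err, "registration_failure")
  expect_match(conditionMessage(err), "stage 1")
})

test_that("three-stage registration aligns a warped phantom pair", {
  spec0 <- phantom_spec(noise_sd = 10)
  pop <- generate_atlas_population(spec0, 2, deformation_sd = 2, seed = 39)
  cfg <- registration_config(rng_seed = 40)
  tf <- register_pairwise(pop[[1]]$image, pop[[2]]$image, cfg)
  # ground-truth correspondence: both members are known warps of one base,
  # so the true map is T1 followed by the numeric inverse of T2
  clean <- spec0; clean$noise_sd <- 0
  base <- generate_joint_phantom(clean, seed = 39)
  gr <- jointkin:::bspline_grid_for(base$image, 16)
  draw_warp <- function(i) {
    old <- jointkin:::local_seed((39 + 1000L * i) %% .Machine$integer.max)
    coef <- array(rnorm(prod(gr$dim) * 3, sd = 2), dim = c(gr$dim, 3))
    jointkin:::restore_seed(old)
    bspline_transform(coef, gr$origin, gr$spacing)
  }
  fg <- which(pop[[1]]$labels$voxels > 0, arr.ind = TRUE) - 1
  pts <- index_to_world(pop[[1]]$labels, fg)
  ytrue <- jointkin:::invert_displacement_points(
    draw_warp(2), transform_points(draw_warp(1), pts))$points
  err <- sqrt(rowSums((transform_points(tf, pts) - ytrue)^2))
  # mean residual displacement on the foreground well below one voxel
  expect_lt(mean(err), 1)
  expect_lt(median(err), 0.5)
  # propagated-label overlap close to the voxelization ceiling (two
  # independently rasterized warped shapes cap single-candidate Dice
  # near 0.95 at these bone sizes)
  prop <- resample_labels(pop[[2]]$labels, tf, pop[[1]]$labels)
  fg_truth <- labelmap(array(as.integer(pop[[1]]$labels$voxels > 0),
                             dim = dim(prop$voxels)),
                       reference = pop[[1]]$labels)
  fg_prop <- labelmap(array(as.integer(prop$voxels > 0),
                            dim = dim(prop$voxels)),
                      reference = pop[[1]]$labels)
  expect_gte(overlap_scores(fg_truth, fg_prop, 1)$dice, 0.93)
})

test_that("refinement across stages does not degrade foreground alignment", {
  spec0 <- small_joint_spec(noise_sd = 10)
  pop <- generate_atlas_population(spec0, 2, deformation_sd = 2, seed = 41)
  fixed <- pop[[1]]$image; moving <- pop[[2]]$image
  stages <- list(registration_stage("rigid"), registration_stage("affine"),
                 registration_stage("bspline"))
  init <- identity_transform()
  dice <- c()
  for (st in stages) {
    tf <- register_stage(fixed, moving, st, init = init, seed = 42)
    prop <- resample_labels(pop[[2]]$labels, tf, pop[[1]]$labels)
    dice <- c(dice, mean(sapply(1:2, function(l)
      overlap_scores(pop[[1]]$labels, prop, l)$dice)))
    if (st$transform_kind != "bspline") init <- tf
  }
  expect_true(all(diff(dice) > -0.005))  # non-decreasing within jitter
})

test_that("MI-driven rigid registration recovers a translation", {
  spec0 <- small_joint_spec(noise_sd = 0)
  ph <- generate_joint_phantom(spec0, seed = 43)
  true_tf <- rigid_from_axis_angle(c(0, 0, 1), 0, translation = c(3, 1, -2))
  spec_m <- spec0
  spec_m$bones <- lapply(spec_m$bones, function(b)
    jointkin:::transform_bone(b, true_tf))
  mov <- generate_joint_phantom(spec_m, seed = 43)
  # nonlinear intensity remap: MI should still lock on
  mov$image$voxels <- sqrt(mov$image$voxels) * 40
  st <- registration_stage("rigid", "MI", max_iterations = 300L,
                           n_resolution_levels = 3L)
  tf <- register_stage(ph$image, mov$image, st, seed = 44)
  expect_lt(max(abs(tf$matrix[1:3, 4] - c(3, 1, -2))), 0.5)
})
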