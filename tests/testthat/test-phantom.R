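# Synthetic phantom generators: determinism, analytic landmarks, atlas
# populations, dynamic sequences with exact ground truth.

test_that("hard rasterization yields exactly the three tissue intensities", {
  spec <- phantom_spec(grid_dim = c(32, 32, 32), noise_sd = 0,
                       pv_ramp_mm = 0,
                       bones = list(phantom_bone(1L, "ellipsoid",
                                                 center = c(16, 16, 16),
                                                 semi_axes = c(8, 6, 7))))
  ph <- generate_joint_phantom(spec, seed = 1)
  expect_setequal(unique(as.vector(ph$image$voxels)), c(50, 300, 1200))
  expect_setequal(unique(as.vector(ph$labels$voxels)), c(0, 1))
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- phantom_spec(grid_dim = c(24, 24, 24), noise_sd = 15,
                       bones = list(phantom_bone(1L, "ellipsoid",
                                                 center = c(12, 12, 12),
                                                 semi_axes = c(6, 5, 5))))
  a <- generate_joint_phantom(spec, seed = 9)
  b <- generate_joint_phantom(spec, seed = 9)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$labels$voxels, b$labels$voxels)
  expect_identical(a$landmarks, b$landmarks)
})

test_that("extremal landmarks sit at the analytic support point", {
  rec <- data.frame(name = "apex", label = 1L, type = "extremal",
                    ux = 0, uy = 0, uz = 1, inset_mm = 0)
  spec <- phantom_spec(grid_dim = c(32, 32, 32), noise_sd = 0,
                       bones = list(phantom_bone(1L, "ellipsoid",
                                                 center = c(16, 16, 14),
                                                 semi_axes = c(8, 6, 9))),
                       landmarks = rec)
  ph <- generate_joint_phantom(spec, seed = 1)
  expect_equal(as.numeric(jointkin:::landmark_matrix(ph$landmarks)),
               c(16, 16, 23), tolerance = 0.5)  # within half a voxel
  # tilted capsule: support point lies on the correct cap
  spec2 <- phantom_spec(grid_dim = c(32, 32, 32), noise_sd = 0,
                        bones = list(phantom_bone(1L, "capsule",
                                                  center = c(16, 16, 16),
                                                  axis = c(0, 0, 1),
                                                  half_length = 6,
                                                  radius = 4)),
                        landmarks = rec)
  ph2 <- generate_joint_phantom(spec2, seed = 1)
  expect_equal(as.numeric(jointkin:::landmark_matrix(ph2$landmarks)),
               c(16, 16, 26), tolerance = 1e-9)
})

test_that("overlapping bones are rejected", {
  spec <- phantom_spec(grid_dim = c(32, 32, 32), noise_sd = 0,
                       bones = list(
                         phantom_bone(1L, "ellipsoid", center = c(14, 16, 16),
                                      semi_axes = c(6, 6, 6)),
                         phantom_bone(2L, "ellipsoid", center = c(18, 16, 16),
                                      semi_axes = c(6, 6, 6))))
  expect_error(generate_joint_phantom(spec), "overlap")
})

test_that("a zero-deformation population is n identical atlases", {
  spec <- small_joint_spec(noise_sd = 0)
  pop <- generate_atlas_population(spec, 3, deformation_sd = 0, seed = 2)
  expect_length(pop, 3)
  expect_identical(pop[[1]]$image$voxels, pop[[2]]$image$voxels)
  expect_identical(pop[[2]]$labels$voxels, pop[[3]]$labels$voxels)
  expect_equal(as.data.frame(pop[[1]]$landmarks[1:5]),
               as.data.frame(pop[[3]]$landmarks[1:5]))
})

test_that("warped landmarks stay inside their warped bone", {
  spec <- small_joint_spec(noise_sd = 0)
  pop <- generate_atlas_population(spec, 4, deformation_sd = 3, seed = 3)
  for (a in pop) {
    for (r in seq_len(nrow(a$landmarks))) {
      ci <- round(world_to_index(
        a$labels, jointkin:::landmark_matrix(a$landmarks[r, ]))) + 1
      ci <- pmin(pmax(ci, 1), dim(a$labels$voxels))
      expect_equal(a$labels$voxels[ci[1], ci[2], ci[3]],
                   a$landmarks$label[r])
    }
  }
})

test_that("population diversity grows with the deformation amplitude", {
  spec <- small_joint_spec(noise_sd = 0)
  mean_pair_dice <- sapply(c(1, 3, 6), function(sd_) {
    pop <- generate_atlas_population(spec, 3, deformation_sd = sd_,
                                     seed = 4)
    pairs <- combn(3, 2)
    mean(apply(pairs, 2, function(p)
      overlap_scores(pop[[p[1]]]$labels, pop[[p[2]]]$labels, 1)$dice))
  })
  expect_true(all(diff(mean_pair_dice) < 0))
})

test_that("identity motion reproduces the atlas up to noise", {
  ph <- generate_joint_phantom(small_joint_spec(noise_sd = 0), seed = 5)
  dyn <- generate_dynamic_sequence(ph, motion_spec(3L, list()), seed = 6,
                                   noise_sd = 0)
  for (f in dyn$sequence$frames)
    expect_equal(f$voxels, ph$image$voxels, tolerance = 1e-12)
  dyn2 <- generate_dynamic_sequence(ph, motion_spec(2L, list()), seed = 6,
                                    noise_sd = 8)
  resid <- dyn2$sequence$frames[[1]]$voxels - ph$image$voxels
  expect_lt(abs(mean(resid)), 0.5)
  expect_equal(sd(as.vector(resid)), 8, tolerance = 0.3)
})

test_that("ground-truth transforms and landmarks follow the motion spec", {
  ph <- generate_joint_phantom(small_joint_spec(noise_sd = 0), seed = 7)
  mot <- motion_spec(5L, list(bone_motion(2L, axis = c(0, 0, 1),
                                          angle_total_deg = 8)))
  dyn <- generate_dynamic_sequence(ph, mot, seed = 8, noise_sd = 0)
  for (t in 1:5) {
    R <- dyn$motion$transforms[["2"]][[t]]$matrix[1:3, 1:3]
    a <- cardan_from_rotation(t(R), "ZYX")$angles
    expect_equal(a[1], 2 * (t - 1), tolerance = 1e-9)
    expect_identical(dyn$motion$transforms[["1"]][[t]]$matrix, diag(4))
  }
  # only bone 2 moves: bone 1's region is identical across noise-free frames
  sel1 <- ph$labels$voxels == 1
  for (t in 2:5)
    expect_equal(dyn$sequence$frames[[t]]$voxels[sel1],
                 dyn$sequence$frames[[1]]$voxels[sel1], tolerance = 1e-12)
})

test_that("motion pushing a bone off the grid is rejected with the frame", {
  ph <- generate_joint_phantom(small_joint_spec(noise_sd = 0), seed = 9)
  mot <- motion_spec(4L, list(bone_motion(2L, angle_total_deg = 0,
                                          translation_total = c(100, 0, 0))))
  expect_error(generate_dynamic_sequence(ph, mot, seed = 10, noise_sd = 0),
               "frame")
})
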