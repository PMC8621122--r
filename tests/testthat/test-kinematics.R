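# Bone-embedded frames, relative rotation, cardan angles, landmark
# propagation.

triad <- function() landmark_set(c("o", "a", "p"), c(1L, 1L, 1L),
                                 c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))

def_i_j <- function() frame_definition(1L, "o", axis_from = "o",
                                       axis_to = "a", axis_name = "i",
                                       plane_landmark = "p",
                                       plane_axis = "j")

test_that("the canonical landmark triad builds the identity frame", {
  f <- build_frame(triad(), def_i_j())
  expect_equal(f$R, diag(3), tolerance = 1e-12)
  expect_equal(f$origin, c(0, 0, 0))
})

test_that("frame construction is equivariant under rigid rotations", {
  set.seed(71)
  for (rep in 1:20) {
    Q <- random_rotation()
    lm <- triad()
    rot <- jointkin:::set_landmark_positions(
      lm, t(Q %*% t(jointkin:::landmark_matrix(lm))))
    f <- build_frame(rot, def_i_j())
    # rows transform by Q: R_rotated = R_original %*% t(Q)
    expect_equal(f$R, diag(3) %*% t(Q), tolerance = 1e-9)
    expect_equal(det(f$R), 1, tolerance = 1e-9)
  }
})

test_that("collinear or degenerate landmarks are rejected", {
  bad <- landmark_set(c("o", "a", "p"), c(1L, 1L, 1L),
                      c(0, 1, 2), c(0, 0, 0), c(0, 0, 0))
  expect_error(build_frame(bad, def_i_j()), "collinear")
  expect_error(build_frame(triad()[1:2, ], def_i_j()), "not found")
})

test_that("relative rotation follows the distal-times-inverse-proximal rule", {
  to_row <- function(deg) cardan_to_rotation(c(deg, 0, 0), "ZYX")
  expect_equal(relative_rotation(to_row(40), to_row(10)), to_row(30),
               tolerance = 1e-12)
  f <- list(origin = c(0, 0, 0), R = to_row(25))
  expect_equal(relative_rotation(f, f), diag(3), tolerance = 1e-12)
  expect_equal(relative_rotation(f, list(origin = 0, R = diag(3))), f$R)
})

test_that("cardan angles satisfy compose-decompose identities", {
  expect_equal(cardan_from_rotation(diag(3), "ZXY")$angles, c(0, 0, 0))
  expect_equal(cardan_from_rotation(diag(3), "ZYX")$angles, c(0, 0, 0))
  # a pure Z rotation is the first angle in either sequence
  Rz30 <- cardan_to_rotation(c(30, 0, 0), "ZYX")
  expect_equal(cardan_from_rotation(Rz30, "ZYX")$angles, c(30, 0, 0),
               tolerance = 1e-12)
  expect_equal(cardan_from_rotation(Rz30, "ZXY")$angles, c(30, 0, 0),
               tolerance = 1e-12)
  # the documented worked example
  R <- cardan_to_rotation(c(10, 20, 30), "ZXY")
  expect_equal(cardan_from_rotation(R, "ZXY")$angles, c(10, 20, 30),
               tolerance = 1e-9)
})

test_that("gimbal lock is flagged and handled", {
  R <- cardan_to_rotation(c(25, 90, 0), "ZYX")
  d <- cardan_from_rotation(R, "ZYX")
  expect_true(d$gimbal_flag)
  expect_equal(d$angles[2], 90, tolerance = 1e-6)
  expect_equal(d$angles[3], 0)
  # reconstruction still reproduces the rotation
  expect_equal(cardan_to_rotation(d$angles, "ZYX"), R, tolerance = 1e-6)
})

test_that("landmarks propagate through time rigidly", {
  lm <- landmark_set(c("a", "b", "c"), c(2L, 2L, 2L),
                     c(0, 3, 1), c(0, 0, 2), c(0, 1, 4))
  tfs <- lapply(0:3, function(t)
    rigid_from_axis_angle(c(0, 0, 1), 10 * t, center = c(1, 1, 1),
                          translation = c(t, 0, 0)))
  motion <- rigid_motion_series(list("2" = tfs), reference_index = 0L)
  out <- propagate_landmarks_time(lm, motion)
  expect_equal(as.data.frame(out[[1]]), as.data.frame(lm))
  d0 <- dist(jointkin:::landmark_matrix(lm))
  for (t in 2:4)
    expect_lt(max(abs(dist(jointkin:::landmark_matrix(out[[t]])) - d0)),
              1e-9)
  # pure translation shifts exactly
  tfs2 <- lapply(0:3, function(t)
    rigid_from_axis_angle(c(0, 0, 1), 0, translation = c(0, 2 * t, 0)))
  out2 <- propagate_landmarks_time(
    lm, rigid_motion_series(list("2" = tfs2), 0L))
  expect_equal(out2[[3]]$y, lm$y + 4)
  expect_error(propagate_landmarks_time(
    landmark_set("q", 9L, 1, 1, 1), motion), "no motion")
})

test_that("the kinematics pipeline recovers a prescribed joint rotation", {
  lm <- landmark_set(
    c("d_o", "d_a", "d_p", "p_o", "p_a", "p_p"),
    c(2L, 2L, 2L, 1L, 1L, 1L),
    x = c(0, 1, 0, 10, 11, 10), y = c(0, 0, 1, 0, 0, 1),
    z = c(0, 0, 0, 5, 5, 5))
  ddef <- frame_definition(2L, "d_o", "d_o", "d_a", "i", "d_p", "j")
  pdef <- frame_definition(1L, "p_o", "p_o", "p_a", "i", "p_p", "j")
  nf <- 6L
  tfs_d <- lapply(seq_len(nf) - 1, function(t)
    rigid_from_axis_angle(c(0, 0, 1), 4 * t, center = c(0, 0, 0)))
  tfs_p <- replicate(nf, identity_transform(), simplify = FALSE)
  motion <- rigid_motion_series(list("1" = tfs_p, "2" = tfs_d), 0L)
  ks <- kinematics_pipeline(motion, lm, ddef, pdef, "ZYX")
  expect_equal(ks$theta_Z, 4 * (seq_len(nf) - 1), tolerance = 1e-9)
  expect_equal(ks$theta_Y, rep(0, nf), tolerance = 1e-9)
  expect_equal(ks$theta_X, rep(0, nf), tolerance = 1e-9)
  expect_true(all(ks$valid))
  # static sequence gives an all-zero series
  ks0 <- kinematics_pipeline(
    rigid_motion_series(list("1" = tfs_p, "2" = tfs_p), 0L),
    lm, ddef, pdef, "ZYX")
  expect_true(all(abs(as.matrix(ks0[, 2:4])) < 1e-12))
})

test_that("common rigid motion of both segments leaves angles unchanged", {
  set.seed(72)
  lm <- landmark_set(
    c("d_o", "d_a", "d_p", "p_o", "p_a", "p_p"),
    c(2L, 2L, 2L, 1L, 1L, 1L),
    x = c(0, 1, 0, 10, 11, 10), y = c(0, 0, 1, 0, 0, 1),
    z = c(0, 0, 0, 5, 5, 5))
  ddef <- frame_definition(2L, "d_o", "d_o", "d_a", "i", "d_p", "j")
  pdef <- frame_definition(1L, "p_o", "p_o", "p_a", "i", "p_p", "j")
  nf <- 4L
  tfs_d <- lapply(seq_len(nf) - 1, function(t)
    rigid_from_axis_angle(c(0, 1, 0), 5 * t, center = c(0, 0, 0)))
  tfs_p <- replicate(nf, identity_transform(), simplify = FALSE)
  base <- kinematics_pipeline(
    rigid_motion_series(list("1" = tfs_p, "2" = tfs_d), 0L),
    lm, ddef, pdef, "ZXY")
  # superimpose one common random rigid transform per frame on both bones
  common <- lapply(seq_len(nf) - 1, function(t)
    if (t == 0) identity_transform() else
      rigid_from_axis_angle(rnorm(3), 15 * t, center = c(3, -2, 1),
                            translation = rnorm(3)))
  tfs_d2 <- Map(compose_transforms, common, tfs_d)
  tfs_p2 <- Map(compose_transforms, common, tfs_p)
  moved <- kinematics_pipeline(
    rigid_motion_series(list("1" = tfs_p2, "2" = tfs_d2), 0L),
    lm, ddef, pdef, "ZXY")
  expect_equal(as.matrix(moved[, 2:4]), as.matrix(base[, 2:4]),
               tolerance = 1e-9)
})

test_that("atlas landmark voting picks the locally best-matching atlas", {
  set.seed(73)
  d <- c(16, 16, 16)
  tgt <- volume(array(rnorm(prod(d), 100, 30), d))
  lm1 <- landmark_set("L", 1L, 8, 8, 8)
  lm2 <- landmark_set("L", 1L, 10, 8, 8)
  lab <- labelmap(array(1L, d), reference = tgt)
  atl <- list(atlas(tgt, lab, lm1, id = "good"),
              atlas(tgt, lab, lm2, id = "bad"))
  stack <- structure(list(
    labels = list(lab, lab), images = list(tgt, tgt),
    transforms = list(identity_transform(), identity_transform()),
    ids = c("good", "bad"), atlases = atl), class = "candidate_stack")
  mkw <- function(val) volume(array(val, d))
  # atlas 1 locally better near the landmark
  out <- propagate_atlas_landmarks(stack, tgt,
                                   lncc_maps = list(mkw(0.9), mkw(0.2)))
  expect_equal(c(out$x, out$y, out$z), c(8, 8, 8))
  # flip the weights: atlas 2 wins
  out2 <- propagate_atlas_landmarks(stack, tgt,
                                    lncc_maps = list(mkw(0.2), mkw(0.9)))
  expect_equal(c(out2$x, out2$y, out2$z), c(10, 8, 8))
  # identical atlas under identity transform returns its landmark unchanged
  out3 <- propagate_atlas_landmarks(stack, tgt)
  expect_true(out3$name == "L" && nrow(out3) == 1)
})

test_that("landmarks mapping outside the target are reported missing", {
  d <- c(8, 8, 8)
  tgt <- volume(array(rnorm(prod(d), 100, 30), d))
  lab <- labelmap(array(1L, d), reference = tgt)
  lm_out <- landmark_set("far", 1L, 100, 100, 100)
  atl <- list(atlas(tgt, lab, lm_out, id = "a1"))
  stack <- structure(list(labels = list(lab), images = list(tgt),
                          transforms = list(identity_transform()),
                          ids = "a1", atlases = atl),
                     class = "candidate_stack")
  out <- propagate_atlas_landmarks(stack, tgt,
                                   lncc_maps = list(volume(array(1, d))))
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "missing"), "far")
})

test_that("frame definitions round-trip through YAML", {
  dirn <- withr::local_tempdir()
  def <- frame_definition(2L, "o", "o", "a", "k", "p", "i",
                          handedness = -1, sign_mask = c(1, -1, 1))
  p <- file.path(dirn, "def.yaml")
  write_frame_definition(def, p)
  r <- read_frame_definition(p)
  expect_equal(r[names(r) != "sign_mask"], def[names(def) != "sign_mask"])
  expect_equal(r$sign_mask, def$sign_mask)
})
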