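# Volume, landmark and transform I/O round trips.

test_that("volume containers validate their geometry", {
  expect_error(volume(array(0, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(volume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "positive")
  expect_error(volume(array(0, c(2, 2, 2)),
                      direction = matrix(1, 3, 3)), "orthonormal")
  expect_error(labelmap(array(-1, c(2, 2, 2))), "nonnegative")
  v <- volume(array(rnorm(8), c(2, 2, 2)), spacing = c(1, 2, 3),
              origin = c(-1, 0, 4))
  w <- index_to_world(v, rbind(c(1, 1, 1)))
  expect_equal(as.numeric(w), c(0, 2, 7))
  expect_equal(world_to_index(v, w), rbind(c(1, 1, 1)))
})

test_that("MetaImage and NIfTI round trips are lossless", {
  dirn <- withr::local_tempdir()
  v <- volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), spacing = c(1, 2, 3),
              origin = c(0.5, -1, 2))
  for (ext in c("mha", "mhd", "nii", "nii.gz")) {
    # NIfTI stores its geometry header in float32; MetaImage in full text
    tol <- if (ext %in% c("mha", "mhd")) 1e-12 else 1e-5
    p <- file.path(dirn, paste0("v.", ext))
    write_volume(v, p)
    r <- read_volume(p)
    expect_equal(r$voxels, v$voxels, tolerance = 1e-12)
    expect_equal(r$spacing, v$spacing, tolerance = tol)
    expect_equal(r$origin, v$origin, tolerance = tol)
    expect_equal(r$direction, v$direction, tolerance = tol)
  }
})

test_that("integer labels and anisotropic spacing survive a round trip", {
  dirn <- withr::local_tempdir()
  lm <- labelmap(array(sample(0:2, 3 * 3 * 3, TRUE), c(3, 3, 3)),
                 spacing = c(0.5, 0.5, 2.5))
  p <- file.path(dirn, "lab.mha")
  write_volume(lm, p)
  r <- read_volume(p, as_labels = TRUE)
  expect_identical(r$voxels, lm$voxels)
  expect_equal(r$spacing, c(0.5, 0.5, 2.5))
  expect_identical(sort(unique(as.vector(r$voxels))),
                   sort(unique(as.vector(lm$voxels))))
  # overwrite with new content succeeds
  lm2 <- labelmap(array(1L, c(3, 3, 3)), spacing = c(0.5, 0.5, 2.5))
  write_volume(lm2, p)
  expect_true(all(read_volume(p)$voxels == 1))
})

test_that("a non-identity direction matrix is preserved exactly", {
  dirn <- withr::local_tempdir()
  D <- jointkin:::rotation_about_axis(c(1, 1, 0), 30)
  v <- volume(array(rnorm(27), c(3, 3, 3)), direction = D)
  for (ext in c("mha", "nii.gz")) {
    p <- file.path(dirn, paste0("d.", ext))
    write_volume(v, p)
    expect_equal(read_volume(p)$direction, D,
                 tolerance = if (ext == "mha") 1e-12 else 1e-5)
  }
})

test_that("unreadable or malformed volume files raise I/O errors", {
  dirn <- withr::local_tempdir()
  expect_error(read_volume(file.path(dirn, "missing.mha")), "not found")
  expect_error(read_volume(file.path(dirn, "v.xyz")), "unsupported")
  # truncated file: header promises more voxels than are present
  p <- file.path(dirn, "trunc.mha")
  v <- volume(array(rnorm(1000), c(10, 10, 10)))
  write_volume(v, p)
  raw <- readBin(p, "raw", file.size(p))
  writeBin(raw[1:(length(raw) - 2000)], p)
  expect_error(read_volume(p), "truncated")
})

test_that("landmark CSV round trips losslessly and validates", {
  dirn <- withr::local_tempdir()
  lm <- landmark_set(paste0("L", 1:9), rep(1:3, 3),
                     rnorm(9) * 100, rnorm(9) * 100, rnorm(9) * 100)
  p <- file.path(dirn, "lm.csv")
  write_landmarks(lm, p)
  r <- read_landmarks(p)
  expect_equal(r$name, lm$name)
  expect_lt(max(abs(as.matrix(r[3:5]) - as.matrix(lm[3:5]))), 1e-9)
  # duplicate names rejected
  writeLines(c("name,label,x,y,z", "A,1,0,0,0", "A,1,1,1,1"), p)
  expect_error(read_landmarks(p), "duplicate")
  # missing column rejected
  writeLines(c("name,label,x,y", "A,1,0,0"), p)
  expect_error(read_landmarks(p), "missing column")
  # header-only file gives an empty set
  writeLines("name,label,x,y,z", p)
  expect_equal(nrow(read_landmarks(p)), 0L)
})

test_that("transforms serialize to JSON and back", {
  dirn <- withr::local_tempdir()
  p <- file.path(dirn, "tf.json")
  tf <- rigid_from_axis_angle(c(1, 2, 3), 25, center = c(5, 0, -3),
                              translation = c(1, 2, 3))
  write_transform(tf, p)
  expect_equal(read_transform(p)$matrix, tf$matrix, tolerance = 1e-12)
  bs <- bspline_transform(array(rnorm(4^3 * 3), c(4, 4, 4, 3)),
                          grid_origin = c(-8, -8, -8),
                          grid_spacing = c(8, 8, 8))
  comp <- composite_transform(list(bs, affine_transform(tf$matrix)))
  write_transform(comp, p)
  r <- read_transform(p)
  pts <- matrix(runif(15, 0, 10), 5, 3)
  expect_equal(transform_points(r, pts), transform_points(comp, pts),
               tolerance = 1e-12)
})
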