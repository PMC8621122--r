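# Overlap scores, surface distances, agreement statistics.

cube_mask <- function(d, lo, hi, label = 1L) {
  a <- array(0L, d)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- label
  labelmap(a)
}

test_that("overlap scores follow their set-theoretic definitions", {
  A <- cube_mask(c(6, 6, 6), c(2, 2, 2), c(3, 3, 3))   # 2x2x2 cube
  expect_equal(overlap_scores(A, A, 1), list(dice = 1, fp = 0, fn = 0))
  B <- cube_mask(c(6, 6, 6), c(5, 5, 5), c(6, 6, 6))   # disjoint
  expect_equal(overlap_scores(A, B, 1), list(dice = 0, fp = 1, fn = 1))
  # 2x2x2 cubes sharing a 1x2x2 slab: |A|=|B|=8, overlap 4
  C <- cube_mask(c(6, 6, 6), c(3, 2, 2), c(4, 3, 3))
  sc <- overlap_scores(A, C, 1)
  expect_equal(sc, list(dice = 0.5, fp = 0.5, fn = 0.5))
  # label absent from test
  expect_equal(overlap_scores(A, cube_mask(c(6, 6, 6), c(1, 1, 1),
                                           c(2, 2, 2), 2L), 1),
               list(dice = 0, fp = 0, fn = 1))
  expect_error(overlap_scores(B, A, 9), "absent")
})

test_that("dice is symmetric and FP/FN swap under argument exchange", {
  set.seed(81)
  for (rep in 1:10) {
    A <- labelmap(array(as.integer(runif(6^3) < 0.3), c(6, 6, 6)))
    B <- labelmap(array(as.integer(runif(6^3) < 0.3), c(6, 6, 6)))
    if (!any(A$voxels == 1) || !any(B$voxels == 1)) next
    ab <- overlap_scores(A, B, 1); ba <- overlap_scores(B, A, 1)
    expect_equal(ab$dice, ba$dice)
    expect_equal(ab$fp, ba$fn)
    expect_equal(ab$fn, ba$fp)
  }
})

test_that("surface distances match closed forms on point masks", {
  d <- c(12, 12, 12)
  A <- labelmap(array(0L, d)); A$voxels[3, 3, 3] <- 1L
  B <- labelmap(array(0L, d)); B$voxels[8, 3, 3] <- 1L
  A$spacing <- B$spacing <- c(1, 1, 1)
  sd_ <- surface_distances(A, B, 1)
  expect_equal(sd_$hausdorff, 5)
  expect_equal(sd_$mean_surface_distance, 5)
  expect_equal(sd_$sd_surface_distance, 0)
  expect_equal(surface_distances(A, A, 1)$hausdorff, 0)
  expect_error(surface_distances(A, labelmap(array(0L, d)), 1), "nonempty")
})

test_that("anisotropic spacing is honoured in mm distances", {
  d <- c(8, 8, 8)
  A <- labelmap(array(0L, d), spacing = c(1, 1, 2.5))
  B <- A
  A$voxels[4, 4, 2] <- 1L
  B$voxels[4, 4, 5] <- 1L
  expect_equal(surface_distances(A, B, 1)$hausdorff, 3 * 2.5)
})

test_that("surface distances agree with brute force on random masks", {
  set.seed(82)
  for (rep in 1:10) {
    d <- sample(5:10, 3, replace = TRUE)
    sp <- runif(3, 0.5, 2)
    A <- labelmap(array(as.integer(runif(prod(d)) < 0.25), d), spacing = sp)
    B <- labelmap(array(as.integer(runif(prod(d)) < 0.25), d), spacing = sp)
    if (!any(A$voxels == 1) || !any(B$voxels == 1)) next
    sAv <- jointkin:::surface_voxels(A$voxels == 1)
    sBv <- jointkin:::surface_voxels(B$voxels == 1)
    pa <- sweep(which(sAv, arr.ind = TRUE) - 1, 2, sp, "*")
    pb <- sweep(which(sBv, arr.ind = TRUE) - 1, 2, sp, "*")
    cross <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), Vectorize(
      function(i, j) sqrt(sum((pa[i, ] - pb[j, ])^2))))
    dir_ab <- apply(cross, 1, min); dir_ba <- apply(cross, 2, min)
    got <- surface_distances(A, B, 1)
    expect_equal(got$hausdorff, max(max(dir_ab), max(dir_ba)),
                 tolerance = 1e-9)
    expect_equal(got$mean_surface_distance, mean(c(dir_ab, dir_ba)),
                 tolerance = 1e-9)
    expect_equal(got$max_surface_distance, max(c(dir_ab, dir_ba)),
                 tolerance = 1e-9)
    expect_equal(got$sd_surface_distance, sd(c(dir_ab, dir_ba)),
                 tolerance = 1e-9)
    expect_gte(got$hausdorff, got$mean_surface_distance)
  }
})

test_that("Bland-Altman bias and limits follow the d = a - b definition", {
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3)),
               list(bias = 0, loa_low = 0, loa_high = 0, sd = 0, n = 3))
  ba <- bland_altman(c(2, 3, 4), c(1, 2, 3))
  expect_equal(ba$bias, 1); expect_equal(ba$loa_low, 1)
  # d = {0, 2}: bias 1, sd sqrt(2)
  ba2 <- bland_altman(c(1, 3), c(1, 1))
  expect_equal(ba2$bias, 1)
  expect_equal(ba2$sd, sqrt(2))
  expect_equal(ba2$loa_low, 1 - 1.96 * sqrt(2))
  expect_equal(ba2$loa_high, 1 + 1.96 * sqrt(2))
  # antisymmetry
  x <- rnorm(5); y <- rnorm(5)
  expect_equal(bland_altman(x, y)$bias, -bland_altman(y, x)$bias)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("ICC(2,k) matches a two-way ANOVA mean-squares oracle", {
  set.seed(83)
  for (rep in 1:10) {
    n <- sample(5:20, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, 10, 2), n, k) +
      rnorm(n, sd = runif(1, 0, 3))  # subject effects
    got <- icc_2k(m)
    # oracle: aov() two-way decomposition
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
    icc_oracle <- (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / n)
    expect_equal(got$icc, icc_oracle, tolerance = 1e-10)
  }
})

test_that("ICC is 1 for perfect agreement and penalizes rater offsets", {
  m <- matrix(rep(rnorm(10, 5, 2), 3), 10, 3)
  expect_equal(icc_2k(m)$icc, 1, tolerance = 1e-12)
  m2 <- cbind(m[, 1], m[, 1] + 10)  # huge constant offset
  got <- icc_2k(m2)
  consistency <- (got$msr - got$mse) / got$msr  # no column term
  expect_lt(got$icc, consistency + 1e-12)
  # invariance to a global shift and positive rescaling
  expect_equal(icc_2k(m2 + 100)$icc, got$icc, tolerance = 1e-9)
  expect_equal(icc_2k(m2 * 3)$icc, got$icc, tolerance = 1e-9)
  # degenerate: zero total variance
  expect_true(icc_2k(matrix(5, 4, 3))$degenerate)
})

test_that("ICC of independent ratings is near zero", {
  set.seed(84)
  vals <- replicate(20, icc_2k(matrix(rnorm(50 * 3), 50, 3))$icc)
  expect_lt(abs(mean(vals)), 0.2)
})

test_that("landmark errors are reported by shared name", {
  a <- landmark_set(c("p", "q"), c(1L, 1L), c(0, 3), c(0, 0), c(0, 0))
  b <- landmark_set(c("q", "p", "z"), c(1L, 1L, 1L), c(3, 0, 9), c(0, 0, 9),
                    c(0, 0, 9))
  le <- landmark_error(a, b)
  expect_equal(unname(le$per_name[c("p", "q")]), c(0, 0))
  off <- a; off$x <- off$x + 3
  le2 <- landmark_error(off, a)
  expect_equal(unname(le2$per_name), c(3, 3))
  expect_equal(le2$median, 3)
  expect_error(landmark_error(a, landmark_set("w", 1L, 0, 0, 0)),
               "no shared")
})
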