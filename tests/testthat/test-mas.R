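# Label fusion and atlas ranking. The fusion operators are checked against
# a brute-force per-voxel reimplementation on random stacks.

tgt8 <- function(seed = 1) {
  set.seed(seed)
  volume(array(rnorm(8^3, 100, 30), c(8, 8, 8)))
}

stack_to_mats <- function(stack) {
  list(labels = sapply(stack$labels, function(l) as.integer(l$voxels)),
       n = length(stack$labels))
}

test_that("all three fusers match the brute-force oracle on random stacks", {
  set.seed(11)
  for (rep in 1:12) {
    d <- sample(4:10, 3, replace = TRUE)
    na <- sample(3:5, 1)
    tgt <- volume(array(rnorm(prod(d), 100, 30), d))
    stack <- random_stack(tgt, na)
    lm <- sapply(stack$labels, function(l) as.integer(l$voxels))
    # MV
    mv <- fuse_labels(stack, tgt, fusion_config("MV"))
    expect_identical(as.integer(mv$voxels), fuse_bruteforce(lm))
    # GNCC: restrict to the globally top-r atlases, then majority vote
    r <- sample(seq_len(na), 1)
    ord <- rank_atlases_global(stack, tgt)
    g <- fuse_labels(stack, tgt, fusion_config("GNCC", r = r))
    expect_identical(as.integer(g$voxels),
                     fuse_bruteforce(lm[, ord[seq_len(r)], drop = FALSE]))
    # LNCC: per-voxel top-r by local weight
    w <- lncc_weight_maps(stack, tgt, k = 2)
    wm <- sapply(w, function(x) as.double(x$voxels))
    l <- fuse_labels(stack, tgt, fusion_config("LNCC", k = 2, r = r))
    expect_identical(as.integer(l$voxels), fuse_bruteforce(lm, wm, r))
  }
})

test_that("identical candidates fuse to themselves under every method", {
  tgt <- tgt8(12)
  lab <- labelmap(array(sample(0:2, 8^3, TRUE), c(8, 8, 8)),
                  reference = tgt)
  stack <- random_stack(tgt, 3)
  stack$labels <- list(lab, lab, lab)
  for (cfg in list(fusion_config("MV"), fusion_config("GNCC", r = 2),
                   fusion_config("LNCC", k = 2, r = 2)))
    expect_identical(fuse_labels(stack, tgt, cfg)$voxels, lab$voxels * 1)
})

test_that("majority vote follows vote counts with smallest-label ties", {
  tgt <- tgt8(13)
  mk <- function(val) labelmap(array(val, c(8, 8, 8)), reference = tgt)
  stack <- random_stack(tgt, 3)
  stack$labels <- list(mk(1L), mk(1L), mk(2L))
  expect_true(all(fuse_labels(stack, tgt, fusion_config("MV"))$voxels == 1))
  stack$labels <- list(mk(1L), mk(2L), mk(0L))   # three-way tie
  expect_true(all(fuse_labels(stack, tgt, fusion_config("MV"))$voxels == 0))
})

test_that("MV is invariant to atlas order", {
  set.seed(14)
  tgt <- tgt8(14)
  stack <- random_stack(tgt, 4)
  mv1 <- fuse_labels(stack, tgt, fusion_config("MV"))
  perm <- c(3, 1, 4, 2)
  stack2 <- stack
  stack2$labels <- stack$labels[perm]
  stack2$images <- stack$images[perm]
  mv2 <- fuse_labels(stack2, tgt, fusion_config("MV"))
  expect_identical(mv1$voxels, mv2$voxels)
})

test_that("LNCC with r equal to the stack size reduces to MV", {
  set.seed(15)
  tgt <- tgt8(15)
  stack <- random_stack(tgt, 4)
  mv <- fuse_labels(stack, tgt, fusion_config("MV"))
  ln <- fuse_labels(stack, tgt, fusion_config("LNCC", k = 2, r = 4))
  expect_identical(mv$voxels, ln$voxels)
})

test_that("global ranking puts an exact copy first and orders by noise", {
  set.seed(16)
  tgt <- tgt8(16)
  stack <- random_stack(tgt, 4)
  stack$images[[2]] <- tgt  # exact copy
  for (i in c(1, 3, 4))
    stack$images[[i]] <- volume(
      tgt$voxels + array(rnorm(8^3, sd = c(80, 5, 20)[match(i, c(1, 3, 4))]),
                         c(8, 8, 8)))
  ord <- rank_atlases_global(stack, tgt)
  expect_equal(ord[1], 2L)
  expect_equal(ord[2:4], c(3L, 4L, 1L))  # ascending noise
  expect_equal(attr(ord, "ncc")[2], 1, tolerance = 1e-12)
  # exact ties break by stack position
  stack$images <- replicate(4, tgt, simplify = FALSE)
  expect_equal(as.integer(rank_atlases_global(stack, tgt)), 1:4)
})

test_that("LNCC weights are near 1 for a perfect atlas and degrade locally", {
  set.seed(17)
  tgt <- tgt8(17)
  stack <- random_stack(tgt, 2)
  stack$images[[1]] <- tgt
  corrupted <- tgt
  corrupted$voxels[5:8, , ] <- rnorm(4 * 8 * 8, 100, 30)  # right half noise
  stack$images[[2]] <- corrupted
  w <- lncc_weight_maps(stack, tgt, k = 2)
  expect_gt(min(w[[1]]$voxels), 0.95)
  left <- mean(w[[2]]$voxels[1:3, , ]); right <- mean(w[[2]]$voxels[6:8, , ])
  expect_gt(left, right)
  expect_true(all(abs(w[[2]]$voxels) <= 1))
})

test_that("with a kernel much larger than the image LNCC approaches GNCC", {
  set.seed(18)
  tgt <- tgt8(18)
  stack <- random_stack(tgt, 3)
  ord <- rank_atlases_global(stack, tgt)
  gncc <- attr(ord, "ncc")
  w <- lncc_weight_maps(stack, tgt, k = 50)
  for (i in 1:3) {
    rng <- range(w[[i]]$voxels)
    expect_lt(diff(rng), 0.05)                      # ~uniform map
    expect_lt(abs(mean(w[[i]]$voxels) - gncc[i]), 0.05)
  }
})

test_that("fusion validates r against the stack size", {
  tgt <- tgt8(19)
  stack <- random_stack(tgt, 3)
  expect_error(fuse_labels(stack, tgt, fusion_config("GNCC", r = 5)),
               "exceeds")
})

test_that("fused labels never leave the candidate alphabet", {
  set.seed(20)
  tgt <- tgt8(20)
  stack <- random_stack(tgt, 4, n_labels = 4)
  seen <- sort(unique(unlist(lapply(stack$labels,
                                    function(l) unique(as.vector(l$voxels))))))
  for (cfg in list(fusion_config("MV"), fusion_config("LNCC", k = 1, r = 2)))
    expect_true(all(fuse_labels(stack, tgt, cfg)$voxels %in% seen))
})
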