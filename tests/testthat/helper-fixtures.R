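# Shared fixtures: small phantoms and cached expensive objects. Everything
# is generated in code under fixed seeds; nothing is read from disk.

# cache across test files (helpers are sourced once per test run)
.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# a compact two-bone joint on a 48^3 grid for fast registration tests
small_joint_spec <- function(noise_sd = 15) {
  phantom_spec(
    grid_dim = c(48, 48, 48),
    bones = list(
      phantom_bone(1L, "ellipsoid", center = c(24, 24, 31),
                   semi_axes = c(9, 6.5, 6.5),
                   orientation = jointkin:::rotation_about_axis(c(0, 1, 0),
                                                                8)),
      phantom_bone(2L, "ellipsoid", center = c(24, 24, 14),
                   semi_axes = c(7.5, 5.5, 6),
                   orientation = jointkin:::rotation_about_axis(c(1, 0, 0),
                                                                -6))),
    noise_sd = noise_sd)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rotation_angle_deg <- function(Ra, Rb) {
  acos(pmin(1, pmax(-1, (sum(diag(Ra %*% t(Rb))) - 1) / 2))) * 180 / pi
}

# brute-force per-voxel label fusion (independent oracle)
fuse_bruteforce <- function(label_mat, weight_mat = NULL, r = ncol(label_mat)) {
  n <- nrow(label_mat); na <- ncol(label_mat)
  nb <- max(label_mat) + 1L
  out <- integer(n)
  for (v in seq_len(n)) {
    sel <- if (is.null(weight_mat) || r >= na) seq_len(na) else
      order(-weight_mat[v, ], seq_len(na))[seq_len(r)]
    votes <- tabulate(label_mat[v, sel] + 1L, nbins = nb)
    out[v] <- which(votes == max(votes))[1] - 1L  # smallest label wins ties
  }
  out
}

# random small candidate stack on the grid of `target`
random_stack <- function(target, n_atlas, n_labels = 3) {
  d <- dim(target$voxels)
  labels <- lapply(seq_len(n_atlas), function(i)
    labelmap(array(sample(0:(n_labels - 1), prod(d), TRUE), dim = d),
             reference = target))
  images <- lapply(seq_len(n_atlas), function(i)
    volume(array(rnorm(prod(d), mean = 100, sd = 40), dim = d),
           spacing = target$spacing, origin = target$origin,
           direction = target$direction))
  structure(list(labels = labels, images = images,
                 transforms = replicate(n_atlas, identity_transform(),
                                        simplify = FALSE),
                 ids = sprintf("a%02d", seq_len(n_atlas)),
                 atlases = NULL),
            class = "candidate_stack")
}
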