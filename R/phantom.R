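# Synthetic joint phantoms with exact ground truth. A phantom is 2-3 rigid
# high-intensity "bones" (dense cortical shell around a trabecular core) on
# a soft-tissue background, with named anatomical-style landmarks defined
# analytically on the bone surfaces. Populations of atlases are produced by
# smooth random free-form warps of a base phantom; dynamic sequences by
# per-frame rigid motion of each bone with the true transforms returned.

#' Describe a phantom bone
#'
#' @param label positive integer bone label.
#' @param shape "ellipsoid" or "capsule" (cylinder with hemispherical caps).
#' @param center world mm centre.
#' @param semi_axes ellipsoid semi-axes (mm, length 3).
#' @param axis,half_length,radius capsule geometry: unit axis direction,
#'   half-length of the core segment and tube radius (mm).
#' @param orientation 3x3 rotation applied to the shape before placing it.
#' @param shell_thickness cortical shell thickness (mm).
#' @param core_intensity,shell_intensity CT-like intensities of the
#'   trabecular core and cortical shell.
#' @export
phantom_bone <- function(label, shape = c("ellipsoid", "capsule"),
                         center = c(0, 0, 0), semi_axes = c(10, 10, 15),
                         axis = c(0, 0, 1), half_length = 10, radius = 7,
                         orientation = diag(3), shell_thickness = 2,
                         core_intensity = 300, shell_intensity = 1200) {
  shape <- match.arg(shape)
  list(label = as.integer(label), shape = shape,
       center = as.numeric(center), semi_axes = as.numeric(semi_axes),
       axis = axis / sqrt(sum(axis^2)), half_length = half_length,
       radius = radius, orientation = orientation,
       shell_thickness = shell_thickness,
       core_intensity = core_intensity, shell_intensity = shell_intensity)
}

#' Describe a joint phantom
#'
#' @param grid_dim voxels per axis.
#' @param spacing mm per voxel.
#' @param origin world mm of voxel (0,0,0).
#' @param bones list of [phantom_bone()]s; regions must not overlap.
#' @param background_intensity soft-tissue background level.
#' @param noise_sd additive Gaussian noise SD.
#' @param pv_ramp_mm width (mm) of the smooth partial-volume ramp applied
#'   at bone surfaces, emulating the point spread of the reconstruction
#'   kernel; 0 gives hard binary rasterization. Default 2.5 mm, matching
#'   the reconstructed slice thickness of clinical dynamic knee protocols,
#'   so the cortical edge is resolved by the sampling grid.
#' @param landmarks landmark recipe: data.frame with columns name, label,
#'   type ("extremal" or "center") and ux,uy,uz (world direction for
#'   extremal points). `NULL` uses a per-bone default (proximal/distal
#'   apexes and two lateral surface points on the first bone).
#' @export
phantom_spec <- function(grid_dim = c(64, 64, 64), spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), bones = NULL,
                         background_intensity = 50, noise_sd = 20,
                         landmarks = NULL, pv_ramp_mm = NULL) {
  if (is.null(bones)) bones <- default_joint_bones()
  labs <- vapply(bones, `[[`, 0L, "label")
  if (anyDuplicated(labs)) stop("bone labels must be unique", call. = FALSE)
  if (is.null(landmarks)) landmarks <- default_landmark_recipe(bones)
  if (is.null(pv_ramp_mm)) pv_ramp_mm <- 2.5
  list(grid_dim = as.integer(grid_dim), spacing = as.numeric(spacing),
       origin = as.numeric(origin), bones = bones,
       background_intensity = background_intensity, noise_sd = noise_sd,
       landmarks = landmarks, pv_ramp_mm = pv_ramp_mm)
}

# a two-bone "knee-like" joint centred in a 64 mm cube: a proximal bone
# (femur-like, label 1) above a distal bone (tibia-like, label 2) with a
# ~4 mm joint space. Triaxial ellipsoids with slight tilts, so that every
# rigid rotation (including about the long axis) is observable.
default_joint_bones <- function() {
  list(
    phantom_bone(1L, "ellipsoid", center = c(32, 32, 40),
                 semi_axes = c(11, 8, 8),
                 orientation = rotation_about_axis(c(0, 1, 0), 8)),
    phantom_bone(2L, "ellipsoid", center = c(32, 32, 19),
                 semi_axes = c(9, 6.5, 7),
                 orientation = rotation_about_axis(c(1, 0, 0), -6)))
}

default_landmark_recipe <- function(bones) {
  rec <- list()
  for (b in bones) {
    rec[[length(rec) + 1L]] <- data.frame(
      name = paste0("bone", b$label, c("_distal", "_proximal", "_lateral",
                                       "_anterior")),
      label = b$label, type = "extremal",
      ux = c(0, 0, 1, 0), uy = c(0, 0, 0, 1), uz = c(-1, 1, 0, 0),
      inset_mm = 1.5, stringsAsFactors = FALSE)
    rec[[length(rec) + 1L]] <- data.frame(
      name = paste0("bone", b$label, "_center"), label = b$label,
      type = "center", ux = 0, uy = 0, uz = 0, inset_mm = 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rec)
}

# world coordinates of every voxel centre as three arrays
voxel_world_grids <- function(dim, spacing, origin, direction = diag(3)) {
  i <- (seq_len(dim[1]) - 1) * spacing[1]
  j <- (seq_len(dim[2]) - 1) * spacing[2]
  k <- (seq_len(dim[3]) - 1) * spacing[3]
  I <- array(rep(i, times = dim[2] * dim[3]), dim = dim)
  J <- array(rep(rep(j, each = dim[1]), times = dim[3]), dim = dim)
  K <- array(rep(k, each = dim[1] * dim[2]), dim = dim)
  list(x = origin[1] + direction[1, 1] * I + direction[1, 2] * J +
         direction[1, 3] * K,
       y = origin[2] + direction[2, 1] * I + direction[2, 2] * J +
         direction[2, 3] * K,
       z = origin[3] + direction[3, 1] * I + direction[3, 2] * J +
         direction[3, 3] * K)
}

# signed distances (mm, negative inside) of one bone's outer and core
# surfaces over the world grids; `inside` is the binary outer region
bone_masks <- function(b, W) {
  R <- b$orientation
  px <- R[1, 1] * (W$x - b$center[1]) + R[2, 1] * (W$y - b$center[2]) +
    R[3, 1] * (W$z - b$center[3])
  py <- R[1, 2] * (W$x - b$center[1]) + R[2, 2] * (W$y - b$center[2]) +
    R[3, 2] * (W$z - b$center[3])
  pz <- R[1, 3] * (W$x - b$center[1]) + R[2, 3] * (W$y - b$center[2]) +
    R[3, 3] * (W$z - b$center[3])
  if (b$shape == "ellipsoid") {
    s <- b$semi_axes
    si <- pmax(s - b$shell_thickness, s * 0.1)
    sd_of <- function(sa) {
      q <- sqrt((px / sa[1])^2 + (py / sa[2])^2 + (pz / sa[3])^2)
      gq <- sqrt((px / sa[1]^2)^2 + (py / sa[2]^2)^2 + (pz / sa[3]^2)^2)
      (q - 1) * q / pmax(gq, 1e-9)  # first-order distance to the surface
    }
    sd_out <- sd_of(s)
    sd_core <- sd_of(si)
    inside <- sd_out <= 0
    core <- sd_core <= 0
  } else {
    # capsule axis is local +z after orientation; b$axis rotates it further
    a <- b$axis
    # rotate local coords so the capsule axis is a: build basis with a as z
    u <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- u - sum(u * a) * a; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
            a[1] * e1[2] - a[2] * e1[1])
    qx <- e1[1] * px + e1[2] * py + e1[3] * pz
    qy <- e2[1] * px + e2[2] * py + e2[3] * pz
    qz <- a[1] * px + a[2] * py + a[3] * pz
    t <- pmin(pmax(qz, -b$half_length), b$half_length)
    d <- sqrt(qx^2 + qy^2 + (qz - t)^2)
    sd_out <- d - b$radius
    sd_core <- d - pmax(b$radius - b$shell_thickness, b$radius * 0.1)
    inside <- sd_out <= 0
    core <- sd_core <= 0
  }
  list(inside = inside, core = core, sd_out = sd_out, sd_core = sd_core)
}

# partial-volume coverage from a signed distance: linear ramp of width h
# centred on the surface (emulates the scanner point-spread averaging; also
# keeps image gradients informative at bone edges). h <= 0 gives a hard
# indicator.
pv_weight <- function(sd, h) {
  if (h <= 0) return(array(as.numeric(sd <= 0), dim = dim(sd)))
  t <- pmin(pmax(0.5 - sd / h, 0), 1)
  t * t * (3 - 2 * t)  # C1 smoothstep: benign under interpolation
}

# analytic landmark positions from the recipe (exact ground truth)
recipe_landmarks <- function(spec) {
  rec <- spec$landmarks
  pos <- matrix(0, nrow(rec), 3)
  for (r in seq_len(nrow(rec))) {
    b <- spec$bones[[which(vapply(spec$bones, `[[`, 0L, "label") ==
                             rec$label[r])]]
    if (rec$type[r] == "center") {
      pos[r, ] <- b$center
    } else {
      u <- c(rec$ux[r], rec$uy[r], rec$uz[r])
      u <- u / sqrt(sum(u^2))
      inset <- if ("inset_mm" %in% names(rec)) rec$inset_mm[r] else 0
      if (b$shape == "ellipsoid") {
        M <- b$orientation %*% diag(b$semi_axes^2) %*% t(b$orientation)
        pos[r, ] <- b$center + as.numeric(M %*% u) /
          sqrt(sum(u * as.numeric(M %*% u))) - inset * u
      } else {
        a <- b$axis
        e_plus <- b$center + a * b$half_length
        e_minus <- b$center - a * b$half_length
        e <- if (sum(u * e_plus) >= sum(u * e_minus)) e_plus else e_minus
        pos[r, ] <- e + (b$radius - inset) * u
      }
    }
  }
  landmark_set(rec$name, rec$label, pos[, 1], pos[, 2], pos[, 3])
}

#' Generate a joint phantom atlas
#'
#' Rasterizes the phantom onto its grid (shell, core and background
#' intensities plus Gaussian noise), builds the matching label map of bone
#' regions and the analytic landmark set. Deterministic given `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @param id atlas identifier string.
#' @return An [atlas()].
#' @export
generate_joint_phantom <- function(spec, seed = 1L, id = "phantom") {
  ras <- rasterize_phantom(spec)
  img <- ras$img
  if (spec$noise_sd > 0) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    img <- img + array(rnorm(length(img), sd = spec$noise_sd),
                       dim = dim(img))
  }
  vol <- volume(img, spacing = spec$spacing, origin = spec$origin)
  out <- atlas(image = vol,
               labels = labelmap(ras$lab, reference = vol),
               landmarks = recipe_landmarks(spec), id = id)
  out$spec <- spec  # keeps the parametric description for exact re-rendering
  out
}

# noise-free rasterization of a phantom spec (image + labels)
rasterize_phantom <- function(spec) {
  W <- voxel_world_grids(spec$grid_dim, spec$spacing, spec$origin)
  img <- array(spec$background_intensity, dim = spec$grid_dim)
  lab <- array(0L, dim = spec$grid_dim)
  h <- spec$pv_ramp_mm %||% mean(spec$spacing)
  for (b in spec$bones) {
    mk <- bone_masks(b, W)
    if (any(lab[mk$inside] != 0))
      stop("phantom bones overlap (labels ",
           paste(unique(lab[mk$inside][lab[mk$inside] != 0]), collapse = ","),
           " and ", b$label, ")", call. = FALSE)
    img <- img + (b$shell_intensity - spec$background_intensity) *
      pv_weight(mk$sd_out, h) +
      (b$core_intensity - b$shell_intensity) * pv_weight(mk$sd_core, h)
    lab[mk$inside] <- b$label
  }
  list(img = img, lab = lab)
}

# rigidly move one bone's parametric description
transform_bone <- function(b, tf) {
  R <- tf$matrix[1:3, 1:3]
  b$center <- as.numeric(transform_points(tf, matrix(b$center, 1, 3)))
  b$orientation <- R %*% b$orientation
  b$axis <- as.numeric(R %*% b$axis)
  b
}

#' Generate an atlas population by smooth random warps
#'
#' Each atlas is the base phantom warped by a random, smooth, invertible
#' cubic B-spline deformation (control-point displacements drawn i.i.d.
#' Gaussian); image, labels and landmarks are warped consistently. Fields
#' whose sampled Jacobian determinant drops below 0.05 are rejected and
#' redrawn from the next substream.
#'
#' @param base a [phantom_spec()].
#' @param n number of atlases (>= 2).
#' @param deformation_sd control-point displacement SD in mm.
#' @param seed integer seed.
#' @param grid_spacing_mm control-point spacing of the random field
#'   (default 16 mm; must stay well above the voxel spacing so the warp is
#'   smooth).
#' @return list of [atlas()]s; attribute `n_rejected` counts redrawn fields.
#' @export
generate_atlas_population <- function(base, n, deformation_sd, seed = 1L,
                                      grid_spacing_mm = 16) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (any(grid_spacing_mm < 4 * base$spacing))
    stop("deformation control-point spacing must be >= 4x voxel spacing",
         call. = FALSE)
  clean_spec <- base
  clean_spec$noise_sd <- 0
  base_atlas <- generate_joint_phantom(clean_spec, seed = seed, id = "base")
  gr <- bspline_grid_for(base_atlas$image, grid_spacing_mm)
  out <- vector("list", n)
  rejected <- 0L
  for (i in seq_len(n)) {
    tf <- NULL
    sub <- 0L
    repeat {
      old <- local_seed((seed + 1000L * i + sub) %% .Machine$integer.max)
      coef <- array(rnorm(prod(gr$dim) * 3, sd = deformation_sd),
                    dim = c(gr$dim, 3))
      noise <- if (base$noise_sd > 0)
        array(rnorm(prod(base$grid_dim), sd = base$noise_sd),
              dim = base$grid_dim) else 0
      restore_seed(old)
      tf <- bspline_transform(coef, gr$origin, gr$spacing)
      if (deformation_sd == 0 || jacobian_ok(tf, base_atlas$image)) break
      rejected <- rejected + 1L
      sub <- sub + 1L
      if (sub > 20L) stop("could not draw an invertible deformation; ",
                          "reduce deformation_sd", call. = FALSE)
    }
    img_w <- resample_volume(base_atlas$image, tf, base_atlas$image,
                             "linear",
                             default_value = base$background_intensity)
    lab_w <- resample_labels(base_atlas$labels, tf, base_atlas$labels)
    lm_w <- map_points(tf, base_atlas$landmarks, direction = "inverse")
    img_w$voxels <- img_w$voxels + noise
    out[[i]] <- atlas(image = img_w, labels = lab_w,
                      landmarks = lm_w[, c("name", "label", "x", "y", "z")],
                      id = sprintf("atlas%02d", i))
  }
  attr(out, "n_rejected") <- rejected
  out
}

# sampled Jacobian-determinant positivity check for T(x) = x + d(x)
jacobian_ok <- function(tf, vol, min_det = 0.05, n_grid = 6L, h = 0.5) {
  d <- vol_dim(vol)
  g <- as.matrix(expand.grid(
    seq(0, d[1] - 1, length.out = n_grid),
    seq(0, d[2] - 1, length.out = n_grid),
    seq(0, d[3] - 1, length.out = n_grid)))
  pts <- index_to_world(vol, g)
  J1 <- (transform_points(tf, sweep(pts, 2, c(h, 0, 0), "+")) -
           transform_points(tf, sweep(pts, 2, c(h, 0, 0), "-"))) / (2 * h)
  J2 <- (transform_points(tf, sweep(pts, 2, c(0, h, 0), "+")) -
           transform_points(tf, sweep(pts, 2, c(0, h, 0), "-"))) / (2 * h)
  J3 <- (transform_points(tf, sweep(pts, 2, c(0, 0, h), "+")) -
           transform_points(tf, sweep(pts, 2, c(0, 0, h), "-"))) / (2 * h)
  dets <- J1[, 1] * (J2[, 2] * J3[, 3] - J2[, 3] * J3[, 2]) -
    J2[, 1] * (J1[, 2] * J3[, 3] - J1[, 3] * J3[, 2]) +
    J3[, 1] * (J1[, 2] * J2[, 3] - J1[, 3] * J2[, 2])
  all(dets > min_det)
}

#' Describe per-bone rigid motion for a dynamic sequence
#'
#' Either a linear ramp (rotation from 0 to `angle_total_deg` about `axis`
#' through `center`, translation from 0 to `translation_total`) or an
#' explicit list of per-frame transforms. Frame 0 is always the identity.
#'
#' @param label bone label the motion applies to.
#' @param axis rotation axis.
#' @param angle_total_deg total rotation reached at the last frame.
#' @param translation_total total translation (mm) reached at the last frame.
#' @param center centre of rotation; `NULL` = bone label centroid.
#' @export
bone_motion <- function(label, axis = c(0, 0, 1), angle_total_deg = 0,
                        translation_total = c(0, 0, 0), center = NULL) {
  list(label = as.integer(label), axis = as.numeric(axis),
       angle_total_deg = angle_total_deg,
       translation_total = as.numeric(translation_total), center = center)
}

#' @rdname bone_motion
#' @param n_frames number of timepoints (the clinical cine protocols this
#'   emulates acquire 15).
#' @param bones list of `bone_motion()`s; unlisted bones stay static.
#' @export
motion_spec <- function(n_frames = 15L, bones = list()) {
  list(n_frames = as.integer(n_frames), bones = bones)
}

label_centroid <- function(labels, label) {
  idx <- which(labels$voxels == label, arr.ind = FALSE)
  if (!length(idx)) stop("label ", label, " not present", call. = FALSE)
  ai <- arrayInd(idx, vol_dim(labels)) - 1
  colMeans(index_to_world(labels, ai))
}

# ground-truth rigid transform of one bone at frame t (0-based)
motion_transform <- function(bm, t, n_frames, labels) {
  frac <- if (n_frames > 1) t / (n_frames - 1) else 0
  center <- bm$center %||% label_centroid(labels, bm$label)
  rigid_from_axis_angle(bm$axis, bm$angle_total_deg * frac, center,
                        bm$translation_total * frac)
}

#' Generate a dynamic sequence with exact ground truth
#'
#' Each frame is the atlas image with every bone's region rigidly moved by
#' its ground-truth transform, composited over a uniform background (moved
#' bones pasted in descending label order; any overlap between moved bones
#' is an error), plus fresh Gaussian noise per frame.
#'
#' An atlas generated by [generate_joint_phantom()] carries its parametric
#' description, and frames are then re-rendered analytically (each bone's
#' geometry is rigidly moved and rasterized afresh), so every frame is a
#' faithful discrete sample of the continuous scene. A generic atlas
#' without a parametric description is moved by voxel resampling instead,
#' which adds a little interpolation blur to the moved bones.
#'
#' @param atlas an [atlas()] (for a noise-free compositing source, generate
#'   it with `noise_sd = 0` and set `noise_sd` here).
#' @param motion a [motion_spec()].
#' @param seed integer seed for the per-frame noise.
#' @param noise_sd additive Gaussian noise per frame.
#' @param background_intensity fill value outside the moved bones (ignored
#'   on the analytic path, which keeps the spec's background).
#' @return list(sequence = [dynamic_sequence()], motion = ground-truth
#'   `rigid_motion_series`, landmarks = per-frame list of [landmark_set()]).
#' @export
generate_dynamic_sequence <- function(atlas, motion, seed = 1L,
                                      noise_sd = 20,
                                      background_intensity = 50) {
  stopifnot(inherits(atlas, "jk_atlas"))
  nf <- motion$n_frames
  labs <- sort(setdiff(unique(as.vector(atlas$labels$voxels)), 0))
  frames <- vector("list", nf)
  truth <- lapply(labs, function(l) vector("list", nf))
  names(truth) <- as.character(labs)
  lms <- vector("list", nf)
  analytic <- !is.null(atlas$spec)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (t in seq_len(nf) - 1L) {
    lm_t <- atlas$landmarks
    frame_tfs <- list()
    for (l in labs) {
      bm_i <- which(vapply(motion$bones, `[[`, 0L, "label") == l)
      tf <- if (length(bm_i))
        motion_transform(motion$bones[[bm_i]], t, nf, atlas$labels)
      else identity_transform()
      truth[[as.character(l)]][[t + 1L]] <- tf
      frame_tfs[[as.character(l)]] <- tf
      here <- lm_t$label == l
      if (any(here)) {
        p <- transform_points(tf, landmark_matrix(lm_t[here, ]))
        lm_t$x[here] <- p[, 1]; lm_t$y[here] <- p[, 2]
        lm_t$z[here] <- p[, 3]
      }
    }
    if (analytic) {
      spec_t <- atlas$spec
      spec_t$bones <- lapply(spec_t$bones, function(b)
        transform_bone(b, frame_tfs[[as.character(b$label)]]))
      ras <- tryCatch(rasterize_phantom(spec_t), error = function(e)
        stop("at frame ", t, ": ", conditionMessage(e), call. = FALSE))
      img <- ras$img
      for (l in labs)
        if (!any(ras$lab == l))
          stop("motion pushed bone ", l, " outside the grid at frame ", t,
               call. = FALSE)
    } else {
      img <- array(background_intensity, dim = vol_dim(atlas$image))
      occupied <- array(FALSE, dim = vol_dim(atlas$image))
      for (l in rev(labs)) {  # descending label order
        tf <- frame_tfs[[as.character(l)]]
        inv <- invert_transform(tf)
        mask_t <- resample_volume(
          labelmap(array(as.numeric(atlas$labels$voxels == l),
                         dim = vol_dim(atlas$labels)),
                   reference = atlas$labels),
          inv, atlas$image, "nearest")
        sel <- mask_t$voxels != 0
        if (!any(sel))
          stop("motion pushed bone ", l, " outside the grid at frame ", t,
               call. = FALSE)
        if (any(occupied[sel]))
          stop("moved bones overlap at frame ", t, call. = FALSE)
        vals <- resample_volume(atlas$image, inv, atlas$image, "linear",
                                default_value = background_intensity)
        img[sel] <- vals$voxels[sel]
        occupied <- occupied | sel
      }
    }
    if (noise_sd > 0)
      img <- img + array(rnorm(length(img), sd = noise_sd), dim = dim(img))
    frames[[t + 1L]] <- volume(img, spacing = atlas$image$spacing,
                               origin = atlas$image$origin,
                               direction = atlas$image$direction)
    lms[[t + 1L]] <- lm_t
  }
  list(sequence = dynamic_sequence(frames, reference_index = 0L),
       motion = rigid_motion_series(truth, reference_index = 0L),
       landmarks = lms)
}
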