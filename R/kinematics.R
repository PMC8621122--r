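# Kinematics: landmark propagation (atlas -> reference -> all frames),
# bone-embedded reference frames built from anatomical landmarks, relative
# rotation between distal and proximal segments, and intrinsic cardan-angle
# extraction (ZXY or ZYX sequences).
#
# Convention: a bone-embedded frame stores its unit vectors i, j, k as the
# ROWS of its rotation matrix, expressed in the global (scanner) coordinate
# system. The relative rotation between a distal and a proximal segment is
# R_rel = R_distal %*% R_proximal^-1.

#' Propagate atlas landmarks onto the segmented reference image
#'
#' Each registered atlas contributes one candidate position per landmark by
#' pulling its own landmark back through the registration (inverse point
#' mapping, since the pairwise transform maps target space into atlas
#' space). A majority vote weighted by local normalized cross-correlation
#' decides the winner: for each landmark name, the candidate whose atlas has
#' the highest LNCC weight at the candidate's position is kept. Atlases
#' whose candidate falls outside the target domain (or whose numeric inverse
#' failed) abstain; a landmark with no remaining candidate is reported in
#' the `missing` attribute instead of a position.
#'
#' @param stack a `candidate_stack` from [build_candidates()] (carries the
#'   atlases and their transforms).
#' @param target the segmented reference [volume()].
#' @param lncc_maps optional list of weight volumes from
#'   [lncc_weight_maps()]; computed at `k = 5` if missing.
#' @param k kernel size when computing the weight maps here.
#' @return A [landmark_set()] with one entry per landmark name found in the
#'   atlases; attribute `missing` lists names with no valid candidate.
#' @export
propagate_atlas_landmarks <- function(stack, target, lncc_maps = NULL,
                                      k = 5L) {
  stopifnot(inherits(stack, "candidate_stack"))
  if (is.null(lncc_maps)) lncc_maps <- lncc_weight_maps(stack, target, k)
  d <- vol_dim(target)
  atl <- stack$atlases[match(stack$ids,
                             vapply(stack$atlases, `[[`, "", "id"))]
  nm_all <- unique(unlist(lapply(atl, function(a) a$landmarks$name)))
  out_name <- character(); out_label <- integer(); out_pos <- NULL
  missing <- character()
  for (nm in nm_all) {
    best_w <- -Inf; best <- NULL; best_label <- 0L
    for (ai in seq_along(atl)) {
      lmrow <- atl[[ai]]$landmarks[atl[[ai]]$landmarks$name == nm, ]
      if (!nrow(lmrow)) next
      cand <- map_points(stack$transforms[[ai]],
                         matrix(c(lmrow$x, lmrow$y, lmrow$z), 1, 3),
                         direction = "inverse")
      ok <- attr(cand, "mapped_ok")
      ci <- world_to_index(target, cand)[1, ]
      if (!is.null(ok) && !all(ok)) next
      if (any(ci < 0) || any(ci > d - 1)) next  # abstain: outside domain
      wmap <- lncc_maps[[ai]]
      wv <- cpp_sample_volume(as.double(wmap$voxels), d, wmap$spacing,
                              wmap$origin, wmap$direction,
                              rbind(cand[1, ]), list(), 1L)$value
      if (is.finite(wv) && wv > best_w) {
        best_w <- wv; best <- cand[1, ]; best_label <- lmrow$label
      }
    }
    if (is.null(best)) {
      missing <- c(missing, nm)
    } else {
      out_name <- c(out_name, nm)
      out_label <- c(out_label, best_label)
      out_pos <- rbind(out_pos, best)
    }
  }
  res <- if (length(out_name))
    landmark_set(out_name, out_label, out_pos[, 1], out_pos[, 2],
                 out_pos[, 3]) else landmark_set()
  attr(res, "missing") <- missing
  res
}

#' Propagate reference landmarks through a motion series
#'
#' Position at frame t is `T_bone,t(position)`; names and labels are
#' preserved.
#'
#' @param landmarks [landmark_set()] in reference space; each `label` must
#'   exist in `motion`.
#' @param motion a `rigid_motion_series`.
#' @return list of [landmark_set()]s, one per frame.
#' @export
propagate_landmarks_time <- function(landmarks, motion) {
  stopifnot(inherits(motion, "rigid_motion_series"))
  labs <- unique(landmarks$label)
  miss <- setdiff(as.character(labs), names(motion$transforms))
  if (length(miss))
    stop("no motion available for bone label(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lapply(seq_len(n_frames(motion)), function(t) {
    lm <- landmarks
    for (l in labs) {
      sel <- lm$label == l
      p <- transform_points(motion$transforms[[as.character(l)]][[t]],
                            landmark_matrix(lm[sel, ]))
      lm$x[sel] <- p[, 1]; lm$y[sel] <- p[, 2]; lm$z[sel] <- p[, 3]
    }
    lm
  })
}

#' Define a bone-embedded reference frame from landmarks
#'
#' The primary axis is the unit vector from `axis_from` to `axis_to`,
#' assigned to `axis_name`. The plane landmark (relative to the origin
#' landmark) fixes the rotation about that axis: the remaining axis is the
#' unit cross product of the primary axis and the in-plane vector (sign
#' chosen so the frame is right-handed, det +1, with the plane landmark on
#' the positive `plane_axis` side under `handedness = +1`), and the
#' `plane_axis` closes the triad.
#'
#' @param bone_label bone the frame is attached to.
#' @param origin_landmark landmark name used as the frame origin.
#' @param axis_from,axis_to landmark names spanning the primary axis.
#' @param axis_name which unit vector ("i", "j" or "k") the primary axis is.
#' @param plane_landmark landmark (with the origin) spanning the reference
#'   plane.
#' @param plane_axis which unit vector the in-plane axis closes.
#' @param handedness +1 or -1; -1 mirrors the in-plane sign convention
#'   (left/right side flips).
#' @param sign_mask length-3 multipliers applied to the extracted cardan
#'   angles (sequence order), for side-consistent reporting.
#' @export
frame_definition <- function(bone_label, origin_landmark, axis_from, axis_to,
                             axis_name = c("k", "i", "j"), plane_landmark,
                             plane_axis = c("i", "j", "k"), handedness = 1,
                             sign_mask = c(1, 1, 1)) {
  axis_name <- match.arg(axis_name)
  plane_axis <- match.arg(plane_axis)
  if (axis_name == plane_axis)
    stop("axis_name and plane_axis must differ", call. = FALSE)
  structure(list(bone_label = as.integer(bone_label),
                 origin_landmark = origin_landmark, axis_from = axis_from,
                 axis_to = axis_to, axis_name = axis_name,
                 plane_landmark = plane_landmark, plane_axis = plane_axis,
                 handedness = sign(handedness),
                 sign_mask = as.numeric(sign_mask)),
            class = "frame_definition")
}

#' Read / write frame definitions as YAML
#' @param path YAML file.
#' @export
read_frame_definition <- function(path) {
  y <- yaml::read_yaml(path)
  frame_definition(y$bone_label, y$origin, y$axis_a$from, y$axis_a$to,
                   y$axis_a$axis, y$plane$landmark, y$plane$axis,
                   y$handedness %||% 1, unlist(y$sign_mask %||% c(1, 1, 1)))
}

#' @rdname read_frame_definition
#' @param def a [frame_definition()].
#' @export
write_frame_definition <- function(def, path) {
  yaml::write_yaml(list(bone_label = def$bone_label,
                        origin = def$origin_landmark,
                        axis_a = list(from = def$axis_from,
                                      to = def$axis_to,
                                      axis = def$axis_name),
                        plane = list(landmark = def$plane_landmark,
                                     axis = def$plane_axis),
                        handedness = def$handedness,
                        sign_mask = def$sign_mask), path)
  invisible(path)
}

#' Build a bone-embedded reference frame
#'
#' @param landmarks [landmark_set()] containing the definition's landmarks.
#' @param definition a [frame_definition()].
#' @return list(origin, R) with `R` the 3x3 rotation whose rows are the unit
#'   vectors i, j, k in global coordinates (orthonormal, det +1).
#' @export
build_frame <- function(landmarks, definition) {
  get_pt <- function(nm) {
    row <- landmarks[landmarks$name == nm, ]
    if (!nrow(row)) stop("landmark '", nm, "' not found", call. = FALSE)
    c(row$x, row$y, row$z)
  }
  o <- get_pt(definition$origin_landmark)
  u1 <- get_pt(definition$axis_to) - get_pt(definition$axis_from)
  n1 <- sqrt(sum(u1^2))
  if (n1 < 1e-12) stop("primary-axis landmarks coincide", call. = FALSE)
  u1 <- u1 / n1
  v <- get_pt(definition$plane_landmark) - o
  w <- c(u1[2] * v[3] - u1[3] * v[2], u1[3] * v[1] - u1[1] * v[3],
         u1[1] * v[2] - u1[2] * v[1])
  nw <- sqrt(sum(w^2))
  if (nw < 1e-6 * max(sqrt(sum(v^2)), 1))
    stop("frame landmarks are collinear", call. = FALSE)
  w <- w / nw
  ax <- c(i = 1L, j = 2L, k = 3L)
  a1 <- ax[[definition$axis_name]]
  a2 <- ax[[definition$plane_axis]]
  a3 <- setdiff(1:3, c(a1, a2))
  nxt <- function(i) i %% 3L + 1L
  slots <- matrix(NA_real_, 3, 3)
  build <- function(w_signed) {
    s <- slots
    s[a1, ] <- u1
    s[a3, ] <- w_signed
    b <- nxt(a2); c <- nxt(b)  # (a2, b, c) cyclic => s[a2] = s[b] x s[c]
    s[a2, ] <- c(s[b, 2] * s[c, 3] - s[b, 3] * s[c, 2],
                 s[b, 3] * s[c, 1] - s[b, 1] * s[c, 3],
                 s[b, 1] * s[c, 2] - s[b, 2] * s[c, 1])
    s
  }
  R <- build(w)
  if (sum(R[a2, ] * v) * definition$handedness < 0) R <- build(-w)
  if (abs(det(R) - 1) > 1e-9)
    R <- project_so3(R)
  list(origin = o, R = R)
}

#' Relative rotation between two bone-embedded frames
#'
#' `R_rel = R_distal %*% solve(R_proximal)` (the orthonormal inverse is the
#' transpose): the rotation carrying the proximal frame onto the distal one.
#'
#' @param distal,proximal frames from [build_frame()] (or raw 3x3 rotation
#'   matrices).
#' @return 3x3 orthonormal rotation.
#' @export
relative_rotation <- function(distal, proximal) {
  Rd <- if (is.list(distal)) distal$R else distal
  Rp <- if (is.list(proximal)) proximal$R else proximal
  Rd %*% t(Rp)
}

rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                              0, 0, 1), 3, 3)
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                              0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                              sin(a), 0, cos(a)), 3, 3)

#' Compose a rotation from cardan angles
#'
#' Intrinsic (mobile-axes) sequences ZXY or ZYX, angles in degrees, under
#' the package's row-vector frame convention (rows of the matrix are the
#' rotated frame's unit vectors).
#'
#' @param angles length-3 numeric, degrees, in sequence order.
#' @param sequence "ZXY" or "ZYX".
#' @return 3x3 rotation matrix.
#' @export
cardan_to_rotation <- function(angles, sequence = c("ZXY", "ZYX")) {
  sequence <- match.arg(sequence)
  a <- angles * pi / 180
  Rcol <- if (sequence == "ZXY")
    rot_z(a[1]) %*% rot_x(a[2]) %*% rot_y(a[3])
  else
    rot_z(a[1]) %*% rot_y(a[2]) %*% rot_x(a[3])
  t(Rcol)
}

#' Extract cardan angles from a rotation matrix
#'
#' Intrinsic factorization in the stated order under the row-vector
#' convention; angles in degrees with principal ranges (-180, 180] x
#' [-90, 90] x (-180, 180]. Near gimbal lock (middle-angle sine within
#' 1e-9 of +-1) the third angle is set to 0 and `gimbal_flag` is raised.
#'
#' @param R 3x3 rotation (orthonormal within 1e-6).
#' @param sequence "ZXY" or "ZYX".
#' @return list(sequence, angles (degrees, sequence order), gimbal_flag).
#' @export
cardan_from_rotation <- function(R, sequence = c("ZXY", "ZYX")) {
  sequence <- match.arg(sequence)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("R must be orthonormal within 1e-6", call. = FALSE)
  M <- t(R)  # column-vector form
  gimbal <- FALSE
  if (sequence == "ZXY") {
    s <- M[3, 2]
    if (abs(s) > 1 - 1e-9) {
      gimbal <- TRUE
      b <- asin(max(-1, min(1, s)))
      a <- atan2(M[2, 1], M[1, 1])
      c <- 0
    } else {
      b <- asin(s)
      a <- atan2(-M[1, 2], M[2, 2])
      c <- atan2(-M[3, 1], M[3, 3])
    }
  } else {
    s <- -M[3, 1]
    if (abs(s) > 1 - 1e-9) {
      gimbal <- TRUE
      b <- asin(max(-1, min(1, s)))
      a <- atan2(-M[1, 2], M[2, 2])
      c <- 0
    } else {
      b <- asin(s)
      a <- atan2(M[2, 1], M[1, 1])
      c <- atan2(M[3, 2], M[3, 3])
    }
  }
  list(sequence = sequence, angles = c(a, b, c) * 180 / pi,
       gimbal_flag = gimbal)
}

#' Joint kinematics through a dynamic sequence
#'
#' Per frame: propagate the reference landmarks with the tracked bone
#' motions, build the distal and proximal bone-embedded frames, form the
#' relative rotation, and extract cardan angles. The entry at the reference
#' frame is (0, 0, 0) by construction. Frames flagged as tracking fallbacks
#' for either bone, and frames whose landmark geometry degenerates, are
#' marked invalid (the series continues).
#'
#' @param motion a `rigid_motion_series`.
#' @param landmarks reference-space [landmark_set()].
#' @param distal_def,proximal_def [frame_definition()]s.
#' @param sequence "ZXY" or "ZYX".
#' @param zero_at_reference report rotation relative to the reference
#'   posture (the series is exactly (0,0,0) at the reference frame); set
#'   `FALSE` for the raw anatomical distal-relative-to-proximal angles.
#' @return A data.frame (class `kinematic_series`): frame, the three angles
#'   (degrees, named by rotation axis in sequence order), gimbal and valid
#'   flags.
#' @export
kinematics_pipeline <- function(motion, landmarks, distal_def, proximal_def,
                                sequence = c("ZXY", "ZYX"),
                                zero_at_reference = TRUE) {
  sequence <- match.arg(sequence)
  per_frame <- propagate_landmarks_time(landmarks, motion)
  nf <- length(per_frame)
  rels <- vector("list", nf)
  for (t in seq_len(nf)) {
    rels[[t]] <- tryCatch({
      fd <- build_frame(per_frame[[t]], distal_def)
      fp <- build_frame(per_frame[[t]], proximal_def)
      relative_rotation(fd, fp)
    }, error = function(e) e)
  }
  ref_rel <- rels[[motion$reference_index + 1L]]
  ang <- matrix(NA_real_, nf, 3)
  valid <- rep(TRUE, nf)
  gimbal <- rep(FALSE, nf)
  for (t in seq_len(nf)) {
    res <- tryCatch({
      R <- rels[[t]]
      if (inherits(R, "error")) stop(R)
      if (zero_at_reference) {
        if (inherits(ref_rel, "error")) stop(ref_rel)
        R <- R %*% t(ref_rel)
      }
      cardan_from_rotation(R, sequence)
    }, error = function(e) e)
    if (inherits(res, "error")) { valid[t] <- FALSE; next }
    ang[t, ] <- res$angles * distal_def$sign_mask
    gimbal[t] <- res$gimbal_flag
  }
  if (!is.null(motion$meta)) {
    for (b in c(distal_def$bone_label, proximal_def$bone_label)) {
      m <- motion$meta[[as.character(b)]]
      if (!is.null(m)) valid <- valid & !m$fallback
    }
  }
  axes <- strsplit(sequence, "")[[1]]
  out <- data.frame(frame = seq_len(nf) - 1L,
                    ang1 = ang[, 1], ang2 = ang[, 2], ang3 = ang[, 3],
                    gimbal = gimbal, valid = valid)
  names(out)[2:4] <- paste0("theta_", axes)
  class(out) <- c("kinematic_series", "data.frame")
  out
}
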