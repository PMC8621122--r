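# Per-bone rigid motion tracking through a dynamic sequence, and target
# registration error on corresponding landmarks.

#' Per-bone, per-frame rigid transform series
#'
#' For every bone label, an ordered list of rigid transforms T_bone,t
#' mapping reference-space world points into frame-t space; the entry at the
#' reference frame is the identity. Per-entry convergence metadata lives in
#' the `meta` element (`final_cost`, `fallback` flag).
#'
#' @param transforms named list (by bone label) of per-frame transform
#'   lists.
#' @param reference_index 0-based reference frame index.
#' @param meta optional per-bone data.frames of convergence metadata.
#' @export
rigid_motion_series <- function(transforms, reference_index = 0L,
                                meta = NULL) {
  stopifnot(is.list(transforms), length(transforms) >= 1L)
  nf <- length(transforms[[1]])
  for (b in names(transforms)) {
    if (length(transforms[[b]]) != nf)
      stop("all bones must have one transform per frame", call. = FALSE)
    ref <- transforms[[b]][[reference_index + 1L]]
    if (max(abs(ref$matrix - diag(4))) > 1e-9)
      stop("transform at the reference frame must be the identity",
           call. = FALSE)
  }
  structure(list(transforms = transforms,
                 reference_index = as.integer(reference_index),
                 meta = meta),
            class = "rigid_motion_series")
}

#' @export
print.rigid_motion_series <- function(x, ...) {
  cat(sprintf("<rigid_motion_series> %d bone(s) x %d frames (reference #%d)\n",
              length(x$transforms), length(x$transforms[[1]]),
              x$reference_index))
  invisible(x)
}

#' Number of frames in a motion series
#' @param motion a `rigid_motion_series`.
#' @export
n_frames <- function(motion) length(motion$transforms[[1]])

#' Track each bone rigidly through a dynamic sequence
#'
#' The reference-frame segmentation provides the region of interest for each
#' bone: its mask is dilated (default kernel radius 3 voxels) so the
#' immediate vicinity contributes, and each frame is registered to the
#' reference image by masked rigid registration with the MSD metric. Frames
#' are visited walking outward from the reference frame in both temporal
#' directions, and each registration is initialized with the neighbouring
#' frame's solution (sequential initialization). The resulting transforms
#' map reference-space points into each frame.
#'
#' A frame whose registration fails keeps the previous frame's transform and
#' is flagged (`fallback`) in the metadata; a bone failing at every frame is
#' an error.
#'
#' @param sequence a [dynamic_sequence()].
#' @param reference_labels [labelmap()] on the reference frame's grid.
#' @param dilation_radius mask dilation radius in voxels.
#' @param seed integer seed.
#' @param ... further arguments passed to [register_rigid_masked()].
#' @return A `rigid_motion_series` with convergence metadata.
#' @export
track_bones <- function(sequence, reference_labels, dilation_radius = 3L,
                        seed = 1L, ...) {
  stopifnot(inherits(sequence, "dynamic_sequence"),
            is_labelmap(reference_labels))
  ref_i <- sequence$reference_index
  reference <- sequence$frames[[ref_i + 1L]]
  if (!same_grid(reference, reference_labels))
    stop("reference_labels must live on the reference frame's grid",
         call. = FALSE)
  labs <- sort(setdiff(unique(as.vector(reference_labels$voxels)), 0))
  if (!length(labs)) stop("no bone labels in reference_labels",
                          call. = FALSE)
  nf <- length(sequence$frames)
  transforms <- list(); metas <- list()
  for (l in labs) {
    mask <- dilate_mask(
      labelmap(array(as.numeric(reference_labels$voxels == l),
                     dim = vol_dim(reference_labels)),
               reference = reference_labels),
      dilation_radius)
    series <- vector("list", nf)
    meta <- data.frame(frame = seq_len(nf) - 1L, final_cost = NA_real_,
                       fallback = FALSE)
    series[[ref_i + 1L]] <- identity_transform()
    meta$final_cost[ref_i + 1L] <- 0
    n_ok <- 0L
    # walk outward in both temporal directions, warm-starting each frame
    for (dir in c(1L, -1L)) {
      prev <- identity_transform()
      t <- ref_i + dir
      while (t >= 0L && t < nf) {
        res <- tryCatch(
          register_rigid_masked(reference, sequence$frames[[t + 1L]], mask,
                                init = prev,
                                seed = (seed + 101L * t + l) %%
                                  .Machine$integer.max, ...),
          error = function(e) e)
        if (inherits(res, "error")) {
          series[[t + 1L]] <- prev
          meta$fallback[t + 1L] <- TRUE
        } else {
          series[[t + 1L]] <- res
          info <- attr(res, "optimizer_info")
          meta$final_cost[t + 1L] <- info[[length(info)]]$cost
          prev <- res
          n_ok <- n_ok + 1L
        }
        t <- t + dir
      }
    }
    if (n_ok == 0L && nf > 1L)
      stop("tracking failed at every frame for bone ", l, call. = FALSE)
    transforms[[as.character(l)]] <- series
    metas[[as.character(l)]] <- meta
  }
  rigid_motion_series(transforms, reference_index = ref_i, meta = metas)
}

#' Target registration error on corresponding landmark pairs
#'
#' Applies `transform` to the reference-space points and reports the
#' Euclidean distances (mm) to the corresponding frame-space points.
#'
#' @param reference_points,frame_points n x 3 matrices (or
#'   [landmark_set()]s) of corresponding points, matched by row (or name).
#' @param transform `spatial_transform` mapping reference space to frame
#'   space.
#' @return list(distances, mean, max, median, n).
#' @export
compute_tre <- function(reference_points, frame_points, transform) {
  to_mat <- function(p) if (inherits(p, "landmark_set"))
    landmark_matrix(p) else rbind(p)
  a <- to_mat(reference_points); b <- to_mat(frame_points)
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    shared <- intersect(rownames(a), rownames(b))
    if (!length(shared)) stop("no shared landmark names", call. = FALSE)
    a <- a[shared, , drop = FALSE]; b <- b[shared, , drop = FALSE]
  }
  if (nrow(a) == 0L) stop("no landmark pairs supplied", call. = FALSE)
  if (nrow(a) != nrow(b))
    stop("reference and frame point lists differ in length", call. = FALSE)
  mapped <- transform_points(transform, a)
  d <- sqrt(rowSums((mapped - b)^2))
  list(distances = d, mean = mean(d), max = max(d), median = median(d),
       n = length(d))
}
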