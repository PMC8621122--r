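# Grid-level utilities: resampling, morphological dilation with a Euclidean
# ball, bilateral splitting, Gaussian smoothing and resolution pyramids.

#' Resample a volume onto a target grid
#'
#' `transform` maps target-grid world points into the source space
#' (resampling convention). Intensities use trilinear interpolation; label
#' maps use nearest neighbour. Voxels mapping outside the source domain get
#' `default_value` (0 for labels).
#'
#' @param src source [volume()].
#' @param transform a `spatial_transform` (target world -> source world);
#'   `NULL` for identity.
#' @param target_grid a `vol3d` supplying the output grid.
#' @param interpolation "linear" or "nearest".
#' @param default_value fill value outside the source domain.
#' @return A [volume()] on the target grid.
#' @export
resample_volume <- function(src, transform = NULL, target_grid = src,
                            interpolation = c("linear", "nearest"),
                            default_value = 0) {
  stopifnot(is_vol3d(src), is_vol3d(target_grid))
  interpolation <- match.arg(interpolation)
  out <- cpp_resample(as.double(src$voxels), dim(src$voxels), src$spacing,
                      src$origin, src$direction,
                      dim(target_grid$voxels), target_grid$spacing,
                      target_grid$origin, target_grid$direction,
                      if (is.null(transform)) list() else
                        stage_list(transform),
                      if (interpolation == "nearest") 0L else 1L,
                      default_value)
  volume(array(out, dim = vol_dim(target_grid)),
         spacing = target_grid$spacing, origin = target_grid$origin,
         direction = target_grid$direction)
}

#' Resample a label map onto a target grid
#'
#' Nearest-neighbour propagation of atlas labels: never invents labels
#' (output values are a subset of the input values plus background 0).
#'
#' @param labels a [labelmap()].
#' @inheritParams resample_volume
#' @return A [labelmap()] on the target grid.
#' @export
resample_labels <- function(labels, transform = NULL, target_grid = labels) {
  stopifnot(is_labelmap(labels))
  v <- resample_volume(labels, transform, target_grid,
                       interpolation = "nearest", default_value = 0)
  labelmap(v$voxels, reference = v, label_names = labels$label_names)
}

#' Dilate a binary mask with a Euclidean ball
#'
#' Morphological dilation with a ball structuring element of the given radius
#' in voxel units (not mm), clipped at the image bounds: a voxel is
#' foreground after dilation iff its Euclidean index-space distance to the
#' nearest input foreground voxel is at most `radius_voxels`.
#'
#' @param mask a [labelmap()] or `vol3d` treated as binary (nonzero =
#'   foreground).
#' @param radius_voxels integer >= 0.
#' @return A binary [labelmap()] on the same grid.
#' @export
dilate_mask <- function(mask, radius_voxels) {
  stopifnot(is_vol3d(mask))
  if (length(radius_voxels) != 1L || !is.finite(radius_voxels) ||
      radius_voxels < 0)
    stop("radius_voxels must be a single nonnegative number", call. = FALSE)
  fg <- mask$voxels != 0
  if (radius_voxels == 0 || !any(fg)) {
    out <- array(as.numeric(fg), dim = dim(fg))
  } else {
    d2 <- cpp_edt_sq(as.logical(fg), dim(fg), c(1, 1, 1))
    out <- array(as.numeric(d2 <= radius_voxels^2 + 1e-9), dim = dim(fg))
  }
  labelmap(out, reference = mask)
}

#' Split a bilateral acquisition into left and right halves
#'
#' For scans holding two laterally separated high-intensity structures (for
#' instance both knees in the gantry), detects the symmetry trough of the
#' summed intensity profile along the left-right axis and splits there: the
#' split index is the minimum of the profile between its two dominant maxima.
#' A unimodal profile (single object) splits at the profile midpoint and the
#' result carries `attr(, "split_warning")`.
#'
#' Both halves keep their world geometry: a world point in a cropped half has
#' the same coordinates as in the parent volume.
#'
#' @param vol a [volume()].
#' @param axis grid axis (1, 2 or 3) along which the two sides are separated;
#'   defaults to the first axis.
#' @param smooth_sigma Gaussian smoothing (in profile samples) applied to the
#'   intensity profile before peak finding.
#' @return list(left =, right =, split_index =, warning =): `left` holds
#'   indices up to the split plane (lower world side along `axis`).
#' @export
split_bilateral <- function(vol, axis = 1L, smooth_sigma = 2) {
  stopifnot(is_vol3d(vol), axis %in% 1:3)
  prof <- apply(vol$voxels, axis, sum)
  n <- length(prof)
  if (smooth_sigma > 0) {
    r <- ceiling(3 * smooth_sigma)
    k <- exp(-0.5 * ((-r):r)^2 / smooth_sigma^2)
    padded <- c(rep(prof[1], r), prof, rep(prof[n], r))
    prof_s <- vapply(seq_len(n), function(i)
      sum(padded[i:(i + 2 * r)] * k) / sum(k), 0)
  } else prof_s <- prof
  # local maxima of the smoothed profile; the two dominant ones must be
  # laterally separated (two sides, not two bumps on one structure)
  ismax <- which(diff(sign(diff(prof_s))) < 0) + 1L
  min_sep <- max(3L, as.integer(n / 8))
  p1 <- ismax[which.max(prof_s[ismax])]
  far <- ismax[abs(ismax - p1) >= min_sep]
  warning_flag <- FALSE
  if (length(p1) && length(far)) {
    p2 <- far[which.max(prof_s[far])]
    top2 <- sort(c(p1, p2))
    between <- seq(top2[1], top2[2])
    # midpoint of the minimal plateau: keeps the split centred when the
    # inter-object trough is flat or mirror-symmetric
    eps <- 1e-9 * max(diff(range(prof_s)), 1)
    cand <- between[prof_s[between] <= min(prof_s[between]) + eps]
    split_idx <- as.integer(floor((min(cand) + max(cand)) / 2))
  } else {
    split_idx <- as.integer(round(n / 2))
    warning_flag <- TRUE
    warning("intensity profile is unimodal; splitting at the midpoint",
            call. = FALSE)
  }
  crop <- function(lo, hi) {
    idx <- list(seq_len(dim(vol$voxels)[1]), seq_len(dim(vol$voxels)[2]),
                seq_len(dim(vol$voxels)[3]))
    idx[[axis]] <- lo:hi
    sub <- vol$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    shift <- numeric(3); shift[axis] <- (lo - 1) * vol$spacing[axis]
    volume(sub, spacing = vol$spacing,
           origin = vol$origin + as.numeric(vol$direction %*% shift),
           direction = vol$direction)
  }
  out <- list(left = crop(1L, split_idx),
              right = crop(split_idx + 1L, n),
              split_index = split_idx, warning = warning_flag)
  if (warning_flag) attr(out, "split_warning") <- TRUE
  out
}

#' Gaussian smoothing of a volume
#'
#' Separable truncated-Gaussian filter with reflecting boundaries.
#' @param vol a `vol3d`.
#' @param sigma_voxels scalar or length-3 standard deviation in voxels.
#' @export
gauss_smooth <- function(vol, sigma_voxels) {
  stopifnot(is_vol3d(vol))
  s <- rep(as.numeric(sigma_voxels), length.out = 3)
  out <- cpp_gauss3(as.double(vol$voxels), dim(vol$voxels), s)
  volume(array(out, dim = vol_dim(vol)), spacing = vol$spacing,
         origin = vol$origin, direction = vol$direction)
}

# Smooth + subsample a volume by integer factor (multi-resolution pyramid).
# Smoothing sigma follows the standard factor/2 rule; geometry is preserved
# (new spacing = old spacing * factor, origin unchanged since voxel (0,0,0)
# is retained).
downsample_volume <- function(vol, factor, interpolation = "linear") {
  if (factor <= 1) return(vol)
  sm <- if (interpolation == "linear")
    gauss_smooth(vol, factor / 2) else vol
  nd <- pmax(2L, as.integer(ceiling(vol_dim(vol) / factor)))
  tgt <- volume(array(0, dim = nd), spacing = vol$spacing * factor,
                origin = vol$origin, direction = vol$direction)
  resample_volume(sm, NULL, tgt, interpolation = interpolation)
}
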