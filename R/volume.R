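# Core image containers. A volume is a plain 3D numeric array plus world
# geometry, the unit everything in the package registers on. World frame is
# right-handed, positions in mm, voxel indices 0-based, and a voxel's world
# position is the centre of its cell:
#   world = origin + direction %*% (spacing * index)

#' Create a 3D scalar volume with world geometry
#'
#' @param voxels 3D numeric array of intensities (CT-like, arbitrary units).
#' @param spacing numeric length-3, mm per voxel along each grid axis (> 0).
#' @param origin numeric length-3, world position (mm) of the centre of voxel
#'   (0,0,0).
#' @param direction 3x3 orthonormal matrix whose columns are the world
#'   directions of the grid axes.
#' @return An object of class `vol3d`.
#' @export
volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = diag(3)) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers", call. = FALSE)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("`direction` must be orthonormal (within 1e-6)", call. = FALSE)
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction),
            class = "vol3d")
}

#' Create a label map on an existing volume grid
#'
#' Integer labels on the grid of a companion [volume()]; 0 is background and
#' each positive label identifies one bone.
#'
#' @param labels 3D array of nonnegative integers.
#' @param reference a `vol3d` providing the grid geometry, or `NULL` to give
#'   `spacing`/`origin`/`direction` directly.
#' @param label_names optional named character vector or list mapping label
#'   value (as name) to bone name, e.g. `c("1" = "femur", "2" = "tibia")`.
#' @inheritParams volume
#' @return An object of class `labelmap` (also a `vol3d`).
#' @export
labelmap <- function(labels, reference = NULL, spacing = c(1, 1, 1),
                     origin = c(0, 0, 0), direction = diag(3),
                     label_names = NULL) {
  if (!is.null(reference)) {
    stopifnot(is_vol3d(reference))
    spacing <- reference$spacing; origin <- reference$origin
    direction <- reference$direction
    if (!identical(dim(labels), dim(reference$voxels)))
      stop("label array dimensions differ from the reference grid",
           call. = FALSE)
  }
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be nonnegative integers", call. = FALSE)
  v <- volume(labels, spacing, origin, direction)
  v$label_names <- label_names
  class(v) <- c("labelmap", "vol3d")
  v
}

is_vol3d <- function(x) inherits(x, "vol3d")
is_labelmap <- function(x) inherits(x, "labelmap")

vol_dim <- function(v) dim(v$voxels)

#' @export
print.vol3d <- function(x, ...) {
  d <- vol_dim(x)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s mm, origin (%s)\n",
              if (is_labelmap(x)) "labelmap" else "vol3d",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  if (is_labelmap(x)) {
    labs <- setdiff(sort(unique(as.vector(x$voxels))), 0)
    cat("  labels:", if (length(labs)) paste(labs, collapse = ", ") else
      "(none)", "\n")
  } else {
    cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$voxels),
                max(x$voxels)))
  }
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' Indices are 0-based and may be fractional; a voxel's world position is the
#' centre of its cell.
#'
#' @param v a `vol3d`.
#' @param idx,pts n x 3 matrices of 0-based indices / world mm positions.
#' @return n x 3 matrix.
#' @export
index_to_world <- function(v, idx) {
  idx <- rbind(idx)
  t(v$direction %*% (t(idx) * v$spacing) + v$origin)
}

#' @rdname index_to_world
#' @export
world_to_index <- function(v, pts) {
  pts <- rbind(pts)
  t((t(v$direction) %*% (t(pts) - v$origin)) / v$spacing)
}

# same grid geometry (dims, spacing, origin, direction)?
same_grid <- function(a, b, tol = 1e-6) {
  identical(vol_dim(a), vol_dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

# world-space bounding box corners of the grid (mm)
grid_extent_mm <- function(v) (vol_dim(v) - 1) * v$spacing

#' Landmark sets
#'
#' Named 3D world-coordinate points, each attached to a bone label.
#'
#' @param name character vector of unique landmark names.
#' @param label integer bone labels (may be 0 when unattached).
#' @param x,y,z world coordinates in mm.
#' @return A `landmark_set`: a data.frame with columns name, label, x, y, z.
#' @export
landmark_set <- function(name = character(), label = integer(),
                         x = numeric(), y = numeric(), z = numeric()) {
  df <- data.frame(name = as.character(name), label = as.integer(label),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  validate_landmarks(df)
}

validate_landmarks <- function(df) {
  need <- c("name", "label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark set must have columns name, label, x, y, z",
         call. = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicate landmark names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  if (nrow(df) && any(!is.finite(as.matrix(df[c("x", "y", "z")]))))
    stop("landmark positions must be finite", call. = FALSE)
  class(df) <- c("landmark_set", "data.frame")
  df
}

landmark_matrix <- function(lm) {
  m <- as.matrix(lm[, c("x", "y", "z"), drop = FALSE])
  rownames(m) <- lm$name
  m
}

set_landmark_positions <- function(lm, pts) {
  lm$x <- pts[, 1]; lm$y <- pts[, 2]; lm$z <- pts[, 3]
  lm
}

#' Dynamic sequence container
#'
#' An ordered list of 3D frames sharing one grid, with one frame designated
#' as the reference (the frame the bones are segmented on).
#'
#' @param frames list of `vol3d`, all on the same grid.
#' @param reference_index 0-based index of the reference frame.
#' @return A `dynamic_sequence`.
#' @export
dynamic_sequence <- function(frames, reference_index = 0L) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  for (f in frames) stopifnot(is_vol3d(f))
  for (f in frames[-1])
    if (!same_grid(frames[[1]], f))
      stop("all frames must share the same grid geometry", call. = FALSE)
  reference_index <- as.integer(reference_index)
  if (reference_index < 0L || reference_index >= length(frames))
    stop("reference_index out of range", call. = FALSE)
  structure(list(frames = frames, reference_index = reference_index),
            class = "dynamic_sequence")
}

#' @export
print.dynamic_sequence <- function(x, ...) {
  cat(sprintf("<dynamic_sequence> %d frames (reference #%d)\n",
              length(x$frames), x$reference_index))
  invisible(x)
}
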