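# Spatial transforms between world coordinate spaces. A registration result
# follows the resampling convention: it maps FIXED-space world points into
# MOVING space. Rigid and affine transforms are stored as 4x4 homogeneous
# matrices; free-form deformations as cubic B-spline displacement fields
# d(x) acting as x + d(x); composites apply their stages in declared order.

#' Spatial transform constructors
#'
#' @param matrix 4x4 homogeneous matrix (last row 0 0 0 1).
#' @return A `spatial_transform` of the requested kind.
#' @export
rigid_transform <- function(matrix = diag(4)) {
  matrix <- as_h4(matrix)
  R <- matrix[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("rigid rotation block must be orthonormal with det +1 (within 1e-9)",
         call. = FALSE)
  structure(list(kind = "rigid", matrix = matrix),
            class = c("rigid_transform", "spatial_transform"))
}

#' @rdname rigid_transform
#' @export
affine_transform <- function(matrix = diag(4)) {
  matrix <- as_h4(matrix)
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop("affine matrix is singular", call. = FALSE)
  structure(list(kind = "affine", matrix = matrix),
            class = c("affine_transform", "spatial_transform"))
}

#' @rdname rigid_transform
#' @param coef 4D array of control-point displacements, dim (n1,n2,n3,3), mm.
#' @param grid_origin,grid_spacing world origin / spacing (mm) of the
#'   control-point grid (axis-aligned in world space).
#' @export
bspline_transform <- function(coef, grid_origin, grid_spacing) {
  stopifnot(length(dim(coef)) == 4L, dim(coef)[4] == 3L)
  storage.mode(coef) <- "double"
  structure(list(kind = "bspline", coef = coef,
                 grid_origin = as.numeric(grid_origin),
                 grid_spacing = as.numeric(grid_spacing)),
            class = c("bspline_transform", "spatial_transform"))
}

#' @rdname rigid_transform
#' @param stages list of `spatial_transform`s, applied in declared order
#'   (first element first).
#' @export
composite_transform <- function(stages) {
  stopifnot(is.list(stages), length(stages) >= 1L)
  for (s in stages) stopifnot(inherits(s, "spatial_transform"))
  structure(list(kind = "composite", stages = stages),
            class = c("composite_transform", "spatial_transform"))
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform(diag(4))

as_h4 <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 4L, ncol(m) == 4L)
  storage.mode(m) <- "double"
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("last row of a homogeneous matrix must be (0,0,0,1)", call. = FALSE)
  m
}

#' Build a rigid transform from a rotation about a centre plus translation
#'
#' Maps `x` to `R (x - center) + center + translation`.
#'
#' @param axis rotation axis (need not be unit length).
#' @param angle_deg rotation angle in degrees (right-handed about `axis`).
#' @param center centre of rotation, world mm.
#' @param translation translation, world mm.
#' @export
rigid_from_axis_angle <- function(axis = c(0, 0, 1), angle_deg = 0,
                                  center = c(0, 0, 0),
                                  translation = c(0, 0, 0)) {
  R <- rotation_about_axis(axis, angle_deg)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center + translation - R %*% center
  rigid_transform(m)
}

rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<spatial_transform: %s>\n", x$kind))
  if (x$kind %in% c("rigid", "affine")) print(round(x$matrix, 6))
  if (x$kind == "bspline")
    cat(sprintf("  control grid %s, spacing %s mm\n",
                paste(dim(x$coef)[1:3], collapse = " x "),
                paste(format(x$grid_spacing, digits = 4), collapse = " x ")))
  if (x$kind == "composite")
    cat(sprintf("  %d stages: %s\n", length(x$stages),
                paste(vapply(x$stages, `[[`, "", "kind"), collapse = " -> ")))
  invisible(x)
}

#' Flat parameter vector of a transform
#'
#' Rigid/affine: the 12 top rows of the homogeneous matrix (row-major);
#' B-spline: the control-point displacements; composite: concatenation.
#' @param tf a `spatial_transform`.
#' @export
transform_parameters <- function(tf) {
  switch(tf$kind,
         rigid = ,
         affine = as.numeric(t(tf$matrix[1:3, ])),
         bspline = as.numeric(tf$coef),
         composite = unlist(lapply(tf$stages, transform_parameters)))
}

# flatten to the C++ stage-spec list
stage_list <- function(tf) {
  if (is.null(tf)) return(list())
  switch(tf$kind,
         rigid = ,
         affine = list(list(kind = "affine", matrix = tf$matrix)),
         bspline = list(list(kind = "bspline",
                             coef = as.numeric(tf$coef),
                             grid_dim = as.integer(dim(tf$coef)[1:3]),
                             grid_origin = tf$grid_origin,
                             grid_spacing = tf$grid_spacing)),
         composite = do.call(c, lapply(tf$stages, stage_list)))
}

flatten_stages <- function(tf) {
  if (tf$kind == "composite") do.call(c, lapply(tf$stages, flatten_stages))
  else list(tf)
}

#' Apply a transform to world points
#'
#' @param tf a `spatial_transform`.
#' @param pts n x 3 matrix of world mm points.
#' @return n x 3 matrix of mapped points.
#' @export
transform_points <- function(tf, pts) {
  pts <- rbind(pts)
  storage.mode(pts) <- "double"
  if (nrow(pts) == 0L) return(pts)
  cpp_transform_points(pts, stage_list(tf))
}

#' Invert a transform
#'
#' Rigid and affine transforms invert analytically. Composites invert their
#' stages in reverse order. B-spline displacement stages have no closed-form
#' inverse; points are pulled back numerically (see [map_points()]), so
#' `invert_transform` refuses them.
#' @param tf a `spatial_transform`.
#' @export
invert_transform <- function(tf) {
  switch(tf$kind,
         rigid = rigid_transform(solve(tf$matrix)),
         affine = affine_transform(solve(tf$matrix)),
         bspline = stop(
           "B-spline transforms invert numerically; use map_points(..., ",
           "direction = \"inverse\")", call. = FALSE),
         composite = composite_transform(rev(lapply(tf$stages,
                                                    invert_transform))))
}

# numeric inverse of a displacement stage by fixed-point iteration:
# find x with x + d(x) = y. Returns list(points, ok).
invert_displacement_points <- function(tf, y, tol = 1e-3, max_iter = 100L) {
  x <- y
  ok <- rep(FALSE, nrow(y))
  spec <- stage_list(tf)
  for (it in seq_len(max_iter)) {
    fx <- cpp_transform_points(x, spec)
    resid <- y - fx
    err <- sqrt(rowSums(resid^2))
    ok <- err <= tol
    if (all(ok)) break
    x <- x + resid
  }
  list(points = x, ok = ok)
}

#' Map landmark points through a transform
#'
#' Forward mapping applies the transform; inverse mapping applies the
#' analytic inverse where one exists and otherwise solves
#' `T(x) = y` per point by fixed-point iteration (tolerance 1e-3 mm,
#' at most 100 iterations). Non-convergent points are flagged in the
#' `mapped_ok` column rather than aborting.
#'
#' @param tf a `spatial_transform`.
#' @param landmarks a [landmark_set()] (or n x 3 matrix).
#' @param direction "forward" or "inverse".
#' @return A landmark set (or matrix) of mapped positions; when any numeric
#'   inverse was needed the result carries a logical `mapped_ok` column.
#' @export
map_points <- function(tf, landmarks, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  is_lm <- inherits(landmarks, "landmark_set")
  pts <- if (is_lm) landmark_matrix(landmarks) else rbind(landmarks)
  if (nrow(pts) == 0L) return(landmarks)
  ok <- rep(TRUE, nrow(pts))
  if (direction == "forward") {
    out <- transform_points(tf, pts)
  } else {
    stages <- rev(flatten_stages(tf))
    out <- pts
    for (s in stages) {
      if (s$kind %in% c("rigid", "affine")) {
        out <- transform_points(invert_transform(s), out)
      } else {
        inv <- invert_displacement_points(s, out)
        out <- inv$points
        ok <- ok & inv$ok
      }
    }
  }
  if (is_lm) {
    res <- set_landmark_positions(landmarks, out)
    if (!all(ok)) res$mapped_ok <- ok
    res
  } else {
    attr(out, "mapped_ok") <- ok
    out
  }
}

#' Compose transforms
#'
#' `compose_transforms(a, b)` returns the map `x -> a(b(x))`. Two
#' rigid/affine inputs collapse to a single matrix transform; anything else
#' yields a composite whose stages apply `b` first.
#' @param a,b `spatial_transform`s.
#' @export
compose_transforms <- function(a, b) {
  if (a$kind %in% c("rigid", "affine") && b$kind %in% c("rigid", "affine")) {
    m <- a$matrix %*% b$matrix
    if (a$kind == "rigid" && b$kind == "rigid") {
      m[1:3, 1:3] <- project_so3(m[1:3, 1:3])
      return(rigid_transform(m))
    }
    return(affine_transform(m))
  }
  composite_transform(c(flatten_stages(b), flatten_stages(a)))
}

# nearest rotation matrix (polar decomposition via SVD)
project_so3 <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}
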