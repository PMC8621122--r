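# Intensity-based registration: pairwise three-stage (rigid -> affine ->
# cubic B-spline free-form deformation) and masked rigid registration, with
# MSD / NCC / MI similarity, multi-resolution Gaussian pyramids, random
# sampling of 2000 voxels per iteration, and an adaptively scaled
# stochastic-gradient-descent optimizer. A result maps fixed-space world
# points into moving space (resampling convention).

#' Registration stage and configuration
#'
#' `registration_stage()` describes one stage; `registration_config()`
#' bundles the stage list with global settings. The defaults mirror a
#' standard clinical multi-atlas protocol: three stages (rigid, affine,
#' B-spline), 4 resolution levels, random sampler with 2000 samples per
#' iteration, stochastic gradient descent capped at 2000/1000/1000
#' iterations per level, 32 histogram bins for MI, and a bending-energy
#' regulariser on the deformable stage.
#'
#' @param transform_kind "rigid", "affine" or "bspline".
#' @param metric "MSD", "NCC" or "MI" (MI is supported for rigid/affine
#'   stages; the B-spline stage needs an analytic gradient and accepts MSD
#'   or NCC).
#' @param max_iterations SGD iteration cap per resolution level.
#' @param n_samples random fixed-image samples drawn fresh each iteration.
#' @param n_resolution_levels Gaussian pyramid depth (>= 1).
#' @param regularizer_weight bending-energy weight (B-spline stage only),
#'   relative to the unit-normalized similarity term.
#' @param step_mm target initial SGD step length in mm (gain is auto-scaled
#'   from a gradient-magnitude probe).
#' @export
registration_stage <- function(transform_kind = c("rigid", "affine",
                                                  "bspline"),
                               metric = c("MSD", "NCC", "MI"),
                               max_iterations = NULL, n_samples = 2000L,
                               n_resolution_levels = 4L,
                               regularizer_weight = 1.0, step_mm = 1.0) {
  transform_kind <- match.arg(transform_kind)
  metric <- match.arg(metric)
  if (is.null(max_iterations))
    max_iterations <- switch(transform_kind, rigid = 2000L, affine = 1000L,
                             bspline = 1000L)
  if (n_resolution_levels < 1L) stop("levels must be >= 1", call. = FALSE)
  if (n_samples < 100L) stop("n_samples must be >= 100", call. = FALSE)
  if (transform_kind == "bspline" && metric == "MI")
    stop("MI metric is not available for the B-spline stage", call. = FALSE)
  list(transform_kind = transform_kind, metric = metric,
       max_iterations = as.integer(max_iterations),
       n_samples = as.integer(n_samples),
       n_resolution_levels = as.integer(n_resolution_levels),
       regularizer_weight = regularizer_weight, step_mm = step_mm)
}

#' @rdname registration_stage
#' @param stages ordered list of stages from `registration_stage()`.
#' @param mi_bins joint-histogram bins per axis for MI (>= 8).
#' @param rng_seed integer seed; identical inputs and seed give identical
#'   results.
#' @param bspline_final_grid_spacing control-point spacing (mm) at the finest
#'   level; coarser levels use successive doublings.
#' @param metric similarity used by every stage (convenience shortcut).
#' @export
registration_config <- function(stages = NULL, metric = "MSD", mi_bins = 32L,
                                rng_seed = 1L,
                                bspline_final_grid_spacing = 16) {
  if (is.null(stages))
    stages <- list(registration_stage("rigid", metric),
                   registration_stage("affine", metric),
                   registration_stage("bspline",
                                      if (metric == "MI") "MSD" else metric))
  if (mi_bins < 8L) stop("mi_bins must be >= 8", call. = FALSE)
  list(stages = stages, mi_bins = as.integer(mi_bins),
       rng_seed = as.integer(rng_seed),
       bspline_final_grid_spacing = bspline_final_grid_spacing)
}

# ------------------------------------------------------------- similarity

#' Compute a similarity value between two volumes under a transform
#'
#' Samples fixed-image voxel centres (optionally restricted to a mask), maps
#' them through `transform` into the moving image, and evaluates the metric
#' on the paired intensities. Transformed points falling outside the moving
#' domain are excluded; if fewer than half the requested samples remain the
#' overlap is degenerate and an error of class `degenerate_overlap` is
#' raised.
#'
#' @param fixed,moving [volume()]s.
#' @param transform `spatial_transform` mapping fixed world points into
#'   moving space (`NULL` = identity).
#' @param metric "MSD" (mean squared intensity difference), "NCC" (Pearson
#'   correlation, in `[-1, 1]`) or "MI" (mutual information from a
#'   `mi_bins^2` joint histogram, in nats).
#' @param samples number of random samples, or "all" for every fixed voxel.
#' @param mask optional [labelmap()]; samples are drawn where nonzero.
#' @param mi_bins histogram bins per axis for MI.
#' @param seed RNG seed for the sample draw.
#' @return list(metric, value, n_samples_used).
#' @export
compute_similarity <- function(fixed, moving, transform = NULL,
                               metric = c("MSD", "NCC", "MI"),
                               samples = 2000L, mask = NULL, mi_bins = 32L,
                               seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(is_vol3d(fixed), is_vol3d(moving))
  nvox <- prod(vol_dim(fixed))
  pool <- if (is.null(mask)) seq_len(nvox) else which(mask$voxels != 0)
  if (!length(pool)) stop("mask is empty", call. = FALSE)
  if (identical(samples, "all")) {
    sel <- pool
  } else {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    sel <- pool[ceiling(runif(samples) * length(pool))]
  }
  idx <- arrayInd(sel, vol_dim(fixed)) - 1
  pts <- index_to_world(fixed, idx)
  sm <- cpp_sample_volume(as.double(moving$voxels), vol_dim(moving),
                          moving$spacing, moving$origin, moving$direction,
                          pts,
                          if (is.null(transform)) list() else
                            stage_list(transform), 1L)
  ok <- sm$valid
  if (sum(ok) < length(sel) / 2)
    stop(errorCondition(
      sprintf("degenerate overlap: only %d of %d samples map into the moving domain",
              sum(ok), length(sel)),
      class = c("degenerate_overlap", "error", "condition")))
  f <- fixed$voxels[sel][ok]
  m <- sm$value[ok]
  value <- switch(metric,
                  MSD = mean((f - m)^2),
                  NCC = if (sd(f) == 0 || sd(m) == 0) 0 else
                    stats::cor(f, m),
                  MI = mutual_information(f, m, mi_bins))
  list(metric = metric, value = value, n_samples_used = sum(ok))
}

mutual_information <- function(f, m, bins) {
  cut_bins <- function(x) {
    r <- range(x)
    if (r[2] <= r[1]) return(rep(1L, length(x)))
    pmin(bins, 1L + as.integer((x - r[1]) / (r[2] - r[1]) * bins))
  }
  h <- table(factor(cut_bins(f), levels = 1:bins),
             factor(cut_bins(m), levels = 1:bins))
  p <- h / sum(h)
  pi <- rowSums(p); pj <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pi, pj)[nz]))
}

# entropy of a hard-binned histogram, used as the self-MI reference
shannon_entropy <- function(x, bins) {
  r <- range(x)
  b <- if (r[2] <= r[1]) rep(1L, length(x)) else
    pmin(bins, 1L + as.integer((x - r[1]) / (r[2] - r[1]) * bins))
  p <- tabulate(b, bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# ------------------------------------------------------- stage optimizer

# B-spline control grid covering the world bounding box of a volume's grid
bspline_grid_for <- function(vol, spacing_mm) {
  d <- vol_dim(vol)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  w <- index_to_world(vol, corners)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  gs <- rep(spacing_mm, length.out = 3)
  go <- lo - 2 * gs
  nc <- pmax(4L, as.integer(ceiling((hi - go) / gs)) + 4L)
  list(origin = go, spacing = gs, dim = nc)
}

# Exact dyadic refinement of a cubic B-spline coefficient grid (spacing
# halved, same origin), via the two-scale relation with mask (1,4,6,4,1)/8.
refine_bspline_coef <- function(coef, old_dim, new_dim) {
  h <- c(1, 4, 6, 4, 1) / 8
  out <- array(0, dim = c(new_dim, 3))
  for (comp in 1:3) {
    a <- coef[, , , comp, drop = FALSE]
    dim(a) <- old_dim
    # refine along each axis in turn: c'_m = sum_j h[m - 2j] c_j
    for (axis in 1:3) {
      nd <- dim(a); nd[axis] <- new_dim[axis]
      b <- array(0, dim = nd)
      for (j in seq_len(dim(a)[axis])) {
        for (k in -2:2) {
          m <- 2 * (j - 1) + k + 1  # 1-based target index
          if (m < 1 || m > nd[axis]) next
          ia <- list(quote(expr = ), quote(expr = ), quote(expr = ))
          ib <- ia
          ia[[axis]] <- j; ib[[axis]] <- m
          slice <- do.call(`[`, c(list(a), ia, list(drop = FALSE)))
          cur <- do.call(`[`, c(list(b), ib, list(drop = FALSE)))
          b <- do.call(`[<-`, c(list(b), ib,
                                list(value = cur + h[k + 3] * slice)))
        }
      }
      a <- b
    }
    out[, , , comp] <- a
  }
  out
}

# run one registration stage through its resolution pyramid
run_stage <- function(fixed, moving, stage, init_matrix, mi_bins, seed,
                      bspline_final_spacing, mask = NULL,
                      stop_tol = 1e-6, stop_window = 20L) {
  kind_code <- match(stage$transform_kind, c("rigid", "affine", "bspline")) - 1L
  metric_code <- match(stage$metric, c("MSD", "NCC", "MI")) - 1L
  L <- stage$n_resolution_levels
  center <- index_to_world(fixed, matrix((vol_dim(fixed) - 1) / 2, 1))[1, ]
  cur <- init_matrix
  coef <- NULL; grid <- NULL
  info <- list()
  for (lev in seq_len(L)) {
    fac <- 2^(L - lev)
    f_l <- downsample_volume(fixed, fac)
    m_l <- downsample_volume(moving, fac)
    mask_idx <- integer()
    if (!is.null(mask)) {
      mk <- if (fac > 1)
        resample_volume(mask, NULL, f_l, "nearest") else mask
      mask_idx <- which(mk$voxels != 0) - 1L
      if (!length(mask_idx)) {  # tiny masks can vanish at coarse levels
        mk <- resample_volume(dilate_mask(mask, fac), NULL, f_l, "nearest")
        mask_idx <- which(mk$voxels != 0) - 1L
      }
      if (!length(mask_idx)) stop("mask is empty", call. = FALSE)
    }
    if (kind_code == 2L) {
      gs <- bspline_final_spacing * 2^(L - lev)
      new_grid <- bspline_grid_for(fixed, gs)
      if (is.null(coef)) {
        coef <- array(0, dim = c(new_grid$dim, 3))
      } else {
        coef <- refine_bspline_coef(coef, grid$dim, new_grid$dim)
      }
      grid <- new_grid
    }
    res <- cpp_sgd_stage(
      as.double(f_l$voxels), vol_dim(f_l), f_l$spacing, f_l$origin,
      f_l$direction,
      as.double(m_l$voxels), vol_dim(m_l), m_l$spacing, m_l$origin,
      m_l$direction,
      kind_code, metric_code, mi_bins,
      if (kind_code == 2L) diag(4) else cur,
      if (kind_code == 2L) cur else diag(4),
      center, mask_idx,
      if (kind_code == 2L) as.numeric(coef) else numeric(),
      if (kind_code == 2L) grid$dim else integer(3),
      if (kind_code == 2L) grid$origin else numeric(3),
      if (kind_code == 2L) grid$spacing else numeric(3),
      if (kind_code == 2L) stage$regularizer_weight else 0,
      500L,
      stage$n_samples, stage$max_iterations, 0.602, 20, stage$step_mm,
      as.integer((seed + 7919 * lev) %% .Machine$integer.max),
      stop_tol, stop_window,
      if (lev == L) 3L else 1L)  # cubic interpolation at the finest level
    if (identical(res$status, "degenerate_overlap")) {
      last <- stage_result_transform(kind_code, cur, coef, grid, init_matrix)
      stop(errorCondition(
        sprintf("registration failed at resolution level %d: degenerate overlap",
                lev),
        class = c("registration_failure", "degenerate_overlap", "error",
                  "condition"),
        last_transform = last))
    }
    if (kind_code == 2L) coef <- array(res$coef, dim = c(grid$dim, 3))
    else cur <- res$matrix
    info[[lev]] <- list(iterations = res$iterations, cost = res$cost,
                        n_valid = res$n_valid)
  }
  tf <- stage_result_transform(kind_code, cur, coef, grid, init_matrix)
  attr(tf, "optimizer_info") <- info
  tf
}

stage_result_transform <- function(kind_code, cur, coef, grid, init_matrix) {
  if (kind_code == 0L) {
    m <- cur
    m[1:3, 1:3] <- project_so3(m[1:3, 1:3])
    rigid_transform(m)
  } else if (kind_code == 1L) {
    affine_transform(cur)
  } else {
    disp <- bspline_transform(coef, grid$origin, grid$spacing)
    pre <- cur
    if (max(abs(pre - diag(4))) < 1e-15) disp
    else composite_transform(list(disp, affine_transform(pre)))
  }
}

#' Run a single registration stage
#'
#' Optimizes one transform of the stage's kind by multi-resolution
#' stochastic gradient descent with fresh random samples each iteration,
#' starting from `init`. Deterministic given the seed.
#'
#' @param fixed,moving [volume()]s; the result maps fixed world points into
#'   moving space.
#' @param stage a [registration_stage()].
#' @param init initial transform (rigid or affine; also the frozen
#'   pre-transform of a B-spline stage).
#' @param mi_bins,seed,bspline_final_grid_spacing see
#'   [registration_config()].
#' @param mask optional [labelmap()] restricting the fixed-image samples.
#' @return A `spatial_transform` (for a B-spline stage with a non-identity
#'   `init`, the composite displacement-then-affine map) with an
#'   `optimizer_info` attribute (per-level iterations and final cost).
#' @export
register_stage <- function(fixed, moving, stage, init = identity_transform(),
                           mi_bins = 32L, seed = 1L,
                           bspline_final_grid_spacing = 16, mask = NULL) {
  stopifnot(is_vol3d(fixed), is_vol3d(moving))
  if (!init$kind %in% c("rigid", "affine"))
    stop("init must be a rigid or affine transform", call. = FALSE)
  run_stage(fixed, moving, stage, init$matrix, mi_bins, seed,
            bspline_final_grid_spacing, mask = mask)
}

#' Pairwise three-stage registration
#'
#' Rigid, then affine, then B-spline free-form deformation, each stage
#' initialized from the previous solution. The returned composite maps fixed
#' world points into moving space and is what label and landmark propagation
#' consume.
#'
#' @param fixed,moving [volume()]s.
#' @param config a [registration_config()].
#' @return A `spatial_transform` (composite for a multi-stage config).
#' @export
register_pairwise <- function(fixed, moving, config = registration_config()) {
  stopifnot(is_vol3d(fixed), is_vol3d(moving))
  cur <- init_center_matrix(fixed, moving)
  tf <- NULL
  for (si in seq_along(config$stages)) {
    stage <- config$stages[[si]]
    tf <- tryCatch(
      run_stage(fixed, moving, stage, cur, config$mi_bins,
                config$rng_seed + 131 * si,
                config$bspline_final_grid_spacing),
      error = function(e) {
        if (inherits(e, "registration_failure"))
          stop(errorCondition(
            sprintf("stage %d (%s): %s", si, stage$transform_kind,
                    conditionMessage(e)),
            class = c("registration_failure", "degenerate_overlap", "error",
                      "condition"),
            last_transform = e$last_transform))
        stop(e)
      })
    if (stage$transform_kind != "bspline") cur <- tf$matrix
  }
  tf
}

# translation aligning the geometric centres of the two grids (identity when
# the grids coincide)
init_center_matrix <- function(fixed, moving) {
  cf <- index_to_world(fixed, matrix((vol_dim(fixed) - 1) / 2, 1))[1, ]
  cm <- index_to_world(moving, matrix((vol_dim(moving) - 1) / 2, 1))[1, ]
  m <- diag(4)
  m[1:3, 4] <- cm - cf
  m
}

#' Masked rigid registration
#'
#' Rigid registration in which the similarity (MSD) is evaluated only at
#' samples inside the given fixed-space mask — the bone of interest and its
#' immediate (dilated) vicinity. Used for per-bone tracking through a
#' dynamic sequence.
#'
#' @param fixed,moving [volume()]s.
#' @param mask nonempty [labelmap()] on the fixed grid (already dilated by
#'   the caller as desired).
#' @param init initial rigid transform (for sequential tracking, the
#'   previous frame's solution).
#' @param n_resolution_levels,max_iterations,n_samples,seed,step_mm
#'   optimizer settings.
#' @return A `rigid_transform`.
#' @export
register_rigid_masked <- function(fixed, moving, mask,
                                  init = identity_transform(),
                                  n_resolution_levels = 3L,
                                  max_iterations = 2000L, n_samples = 2000L,
                                  seed = 1L, step_mm = 1.0) {
  stopifnot(is_vol3d(fixed), is_vol3d(moving), is_vol3d(mask))
  if (!any(mask$voxels != 0)) stop("mask is empty", call. = FALSE)
  if (!same_grid(fixed, mask))
    stop("mask must live on the fixed grid", call. = FALSE)
  stage <- registration_stage("rigid", "MSD",
                              max_iterations = max_iterations,
                              n_samples = n_samples,
                              n_resolution_levels = n_resolution_levels,
                              step_mm = step_mm)
  run_stage(fixed, moving, stage, init$matrix, 32L, seed, 16, mask = mask)
}

# ------------------------------------------------------------ seed helpers

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
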