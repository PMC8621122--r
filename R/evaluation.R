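# Validation metrics: overlap scores (Dice, false positive / negative error
# fractions), surface distances from Euclidean distance maps (mean / max /
# SD and Hausdorff), a leave-one-out cross-validation driver, and agreement
# statistics (Bland-Altman limits of agreement, intraclass correlation).

#' Overlap scores between a truth and a test segmentation
#'
#' With A the ground-truth binary mask of `label` and B the test mask:
#' Dice `= 2|A n B| / (|A| + |B|)`, false positive error fraction
#' `FP = |B \ A| / |B|`, false negative error fraction `FN = |A \ B| / |A|`.
#' A label absent from the test map scores Dice 0, FP 0, FN 1.
#'
#' @param truth,test [labelmap()]s on the same grid.
#' @param label bone label to score (must be present in `truth`).
#' @return list(dice, fp, fn).
#' @export
overlap_scores <- function(truth, test, label) {
  stopifnot(is_vol3d(truth), is_vol3d(test))
  if (!same_grid(truth, test))
    stop("truth and test must share a grid", call. = FALSE)
  A <- truth$voxels == label
  B <- test$voxels == label
  nA <- sum(A); nB <- sum(B)
  if (nA == 0) stop("label ", label, " absent from the truth segmentation",
                    call. = FALSE)
  if (nB == 0) return(list(dice = 0, fp = 0, fn = 1))
  inter <- sum(A & B)
  list(dice = 2 * inter / (nA + nB),
       fp = sum(B & !A) / nB,
       fn = sum(A & !B) / nA)
}

# boundary voxels: foreground with at least one 6-neighbour outside the mask
surface_voxels <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    n <- d[ax]
    if (by > 0) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  interior <- mask
  for (ax in 1:3) for (by in c(1, -1))
    interior <- interior & shift(mask, ax, by)
  mask & !interior
}

#' Surface-distance statistics between two masks
#'
#' Surfaces are the 6-connected boundary voxels of each mask; distances come
#' from exact Euclidean distance maps in mm (anisotropic spacing honoured),
#' evaluated at the opposing surface's voxel centres. The directed distance
#' `dist(A,B) = max over a in A of min over b in B of |a - b|`; the
#' Hausdorff distance is the larger of the two directed distances. Mean,
#' max and SD are computed over the pooled symmetric set of directed
#' point-to-surface distances.
#'
#' @param truth,test [labelmap()]s on the same grid.
#' @param label label whose surfaces are compared (both masks nonempty).
#' @return list(mean_surface_distance, max_surface_distance,
#'   sd_surface_distance, hausdorff), all in mm.
#' @export
surface_distances <- function(truth, test, label) {
  stopifnot(is_vol3d(truth), is_vol3d(test))
  if (!same_grid(truth, test))
    stop("truth and test must share a grid", call. = FALSE)
  A <- truth$voxels == label
  B <- test$voxels == label
  if (!any(A) || !any(B))
    stop("both masks must be nonempty for label ", label, call. = FALSE)
  sA <- surface_voxels(A); sB <- surface_voxels(B)
  d <- dim(A); sp <- truth$spacing
  dmapA <- sqrt(cpp_edt_sq(as.logical(sA), d, sp))  # distance to surface A
  dmapB <- sqrt(cpp_edt_sq(as.logical(sB), d, sp))
  a_to_b <- dmapB[sA]   # per A-surface voxel: distance to nearest B voxel
  b_to_a <- dmapA[sB]
  pooled <- c(a_to_b, b_to_a)
  list(mean_surface_distance = mean(pooled),
       max_surface_distance = max(pooled),
       sd_surface_distance = stats::sd(pooled),
       hausdorff = max(max(a_to_b), max(b_to_a)))
}

#' All segmentation scores for one label
#'
#' Convenience wrapper combining [overlap_scores()] and
#' [surface_distances()].
#' @inheritParams surface_distances
#' @export
segmentation_scores <- function(truth, test, label) {
  ov <- overlap_scores(truth, test, label)
  sdist <- if (any(test$voxels == label))
    surface_distances(truth, test, label)
  else list(mean_surface_distance = NA_real_,
            max_surface_distance = NA_real_, sd_surface_distance = NA_real_,
            hausdorff = NA_real_)
  c(ov, sdist)
}

#' Leave-one-out cross-validation of the multi-atlas segmentation
#'
#' Holds out each atlas in turn, segments its image from the remaining
#' atlases, and scores the result against the held-out labels. A failed
#' fold is reported (`ok = FALSE`) rather than fatal.
#'
#' The atlas registrations of each fold are computed once; when several
#' fusion configurations are supplied (a named list), each is scored on the
#' same registered candidate stacks, so fusion methods can be compared on
#' identical folds.
#'
#' @param atlases list of [atlas()]s (>= 3).
#' @param reg_config a [registration_config()].
#' @param fusion_config a [fusion_config()], or a named list of them.
#' @return list(scores = per-fold/per-label/per-method data.frame, summary =
#'   per-label, per-method mean and SD of each metric, segmentations = list
#'   (by method) of per-subject fused [labelmap()]s).
#' @export
loocv_segmentation <- function(atlases, reg_config = registration_config(),
                               fusion_config = fusion_config()) {
  if (length(atlases) < 3L)
    stop("leave-one-out needs at least 3 atlases", call. = FALSE)
  configs <- if (!is.null(fusion_config$method)) {
    stats::setNames(list(fusion_config), fusion_config$method)
  } else fusion_config
  rows <- list(); segs <- list()
  fail_row <- function(id, msg) data.frame(
    subject = id, method = NA_character_, label = NA_integer_, ok = FALSE,
    dice = NA_real_, fp = NA_real_, fn = NA_real_,
    mean_surface_distance = NA_real_, max_surface_distance = NA_real_,
    sd_surface_distance = NA_real_, hausdorff = NA_real_, message = msg)
  for (i in seq_along(atlases)) {
    held <- atlases[[i]]
    stack <- tryCatch(
      build_candidates(held$image, atlases[-i], reg_config,
                       target_id = held$id),
      error = function(e) e)
    if (inherits(stack, "error")) {
      rows[[length(rows) + 1L]] <- fail_row(held$id,
                                            conditionMessage(stack))
      next
    }
    labs <- sort(setdiff(unique(as.vector(held$labels$voxels)), 0))
    for (m in names(configs)) {
      cfg <- configs[[m]]
      cfg$r <- min(cfg$r, length(stack$labels))
      seg <- tryCatch(fuse_labels(stack, held$image, cfg),
                      error = function(e) e)
      if (inherits(seg, "error")) {
        rows[[length(rows) + 1L]] <- fail_row(held$id,
                                              conditionMessage(seg))
        next
      }
      segs[[m]][[held$id]] <- seg
      for (l in labs) {
        sc <- segmentation_scores(held$labels, seg, l)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = held$id, method = m, label = l, ok = TRUE,
          dice = sc$dice, fp = sc$fp, fn = sc$fn,
          mean_surface_distance = sc$mean_surface_distance,
          max_surface_distance = sc$max_surface_distance,
          sd_surface_distance = sc$sd_surface_distance,
          hausdorff = sc$hausdorff, message = "")
      }
    }
  }
  scores <- do.call(rbind, rows)
  okr <- scores[scores$ok, ]
  summary <- if (nrow(okr)) {
    stats::aggregate(
      okr[c("dice", "fp", "fn", "mean_surface_distance",
            "max_surface_distance", "sd_surface_distance", "hausdorff")],
      by = list(method = okr$method, label = okr$label),
      function(x) c(mean = mean(x), sd = stats::sd(x)))
  } else NULL
  list(scores = scores, summary = summary, segmentations = segs)
}

#' Bland-Altman limits of agreement
#'
#' For paired series a and b, with d = a - b: bias `= mean(d)` and limits of
#' agreement `bias +- 1.96 SD(d)` (sample SD, n - 1 denominator).
#'
#' @param a,b equal-length numeric vectors (>= 2 pairs).
#' @return list(bias, loa_low, loa_high, sd, n).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    stop("series must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, n = length(d))
}

#' Average-measures absolute-agreement intraclass correlation, ICC(2,k)
#'
#' Two-way ANOVA decomposition of a subjects x raters matrix into row (MSR),
#' column (MSC) and error (MSE) mean squares; the average-measures
#' absolute-agreement coefficient is
#' `(MSR - MSE) / (MSR + (MSC - MSE) / n)` with n the number of subjects.
#' The single-measures variant ICC(2,1) is also returned.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns, no
#'   missing cells, >= 2 of each.
#' @return list(icc, icc_single, msr, msc, mse, n_subjects, n_raters,
#'   degenerate) — `degenerate` is TRUE when the total variance is zero (the
#'   coefficient is then reported as 1 for exact agreement).
#' @export
icc_2k <- function(ratings) {
  m <- as.matrix(ratings)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  if (anyNA(m)) stop("ratings must have no missing cells", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst < 1e-24) {
    return(list(icc = 1, icc_single = 1, msr = msr, msc = msc, mse = mse,
                n_subjects = n, n_raters = k, degenerate = TRUE))
  }
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, icc_single = icc1, msr = msr, msc = msc, mse = mse,
       n_subjects = n, n_raters = k, degenerate = FALSE)
}

#' Landmark identification error
#'
#' Euclidean distances (mm) between identically named landmarks of an
#' automatic and a reference set.
#'
#' @param auto,reference [landmark_set()]s sharing at least one name.
#' @return list(per_name named distances, median, max, n).
#' @export
landmark_error <- function(auto, reference) {
  a <- landmark_matrix(auto); r <- landmark_matrix(reference)
  shared <- intersect(rownames(a), rownames(r))
  if (!length(shared)) stop("no shared landmark names", call. = FALSE)
  d <- sqrt(rowSums((a[shared, , drop = FALSE] -
                       r[shared, , drop = FALSE])^2))
  names(d) <- shared
  list(per_name = d, median = stats::median(d), max = max(d),
       n = length(d))
}
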