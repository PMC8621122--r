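# Multi-atlas, multi-label segmentation: register every atlas to the target,
# propagate the atlas labels, and fuse the candidates by majority vote (MV),
# globally ranked NCC (GNCC) or locally ranked NCC (LNCC).

#' Atlas container
#'
#' One annotated subject: intensity image, bone label map on the same grid,
#' and named anatomical landmarks attached to the labelled bones.
#'
#' @param image a [volume()].
#' @param labels a [labelmap()] on the same grid.
#' @param landmarks a [landmark_set()]; bone labels must exist in `labels`.
#' @param id identifier string (used for leave-one-out bookkeeping and tie
#'   breaking).
#' @export
atlas <- function(image, labels, landmarks = landmark_set(), id = "atlas") {
  stopifnot(is_vol3d(image), is_labelmap(labels))
  if (!same_grid(image, labels))
    stop("atlas labels must share the image grid", call. = FALSE)
  landmarks <- validate_landmarks(as.data.frame(landmarks))
  present <- unique(as.vector(labels$voxels))
  bad <- setdiff(unique(landmarks$label[landmarks$label > 0]), present)
  if (length(bad))
    stop("landmark bone labels absent from the label map: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(image = image, labels = labels, landmarks = landmarks,
                 id = as.character(id)),
            class = "jk_atlas")
}

#' @export
print.jk_atlas <- function(x, ...) {
  cat(sprintf("<atlas '%s'> %s voxels, %d landmark(s)\n", x$id,
              paste(vol_dim(x$image), collapse = " x "), nrow(x$landmarks)))
  invisible(x)
}

#' Read / write an atlas directory
#'
#' Layout: `<id>/image.<ext>`, `<id>/labels.<ext>`, `<id>/landmarks.csv`
#' with `<ext>` one of the supported volume formats.
#' @param path atlas directory.
#' @export
read_atlas <- function(path) {
  find1 <- function(stem) {
    hits <- list.files(path, pattern = paste0("^", stem,
                                              "\\.(mha|mhd|nii|nii\\.gz)$"),
                       full.names = TRUE)
    if (!length(hits))
      stop("no ", stem, " volume found in ", path, call. = FALSE)
    hits[1]
  }
  lm_path <- file.path(path, "landmarks.csv")
  atlas(image = read_volume(find1("image")),
        labels = read_volume(find1("labels"), as_labels = TRUE),
        landmarks = if (file.exists(lm_path)) read_landmarks(lm_path) else
          landmark_set(),
        id = basename(normalizePath(path)))
}

#' @rdname read_atlas
#' @param x an [atlas()].
#' @param format "mha" or "nii.gz".
#' @export
write_atlas <- function(x, path, format = "mha") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_volume(x$image, file.path(path, paste0("image.", format)))
  write_volume(x$labels, file.path(path, paste0("labels.", format)))
  write_landmarks(x$landmarks, file.path(path, "landmarks.csv"))
  invisible(path)
}

#' Label fusion configuration
#'
#' @param method "MV" (plain majority vote over all atlases), "GNCC"
#'   (majority vote over the `r` globally best-correlated atlases) or
#'   "LNCC" (per-voxel majority vote over the `r` locally best-correlated
#'   atlases within a kernel).
#' @param k LNCC kernel size in voxels (realized as a Gaussian of sigma `k`
#'   voxels, or a boxcar cube of edge `2k+1`).
#' @param r number of highest-ranked atlases used by GNCC/LNCC.
#' @param kernel "gaussian" or "boxcar".
#' @export
fusion_config <- function(method = c("LNCC", "GNCC", "MV"), k = 5L, r = 3L,
                          kernel = c("gaussian", "boxcar")) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (r < 1) stop("r must be >= 1", call. = FALSE)
  list(method = method, k = as.integer(k), r = as.integer(r),
       kernel = kernel)
}

#' Register all atlases to a target and propagate their labels
#'
#' For each atlas, runs the pairwise three-stage registration
#' (fixed = target, moving = atlas), then resamples the atlas intensity
#' (trilinear) and labels (nearest neighbour) onto the target grid. An atlas
#' whose registration fails is dropped with a warning; if all fail, an error
#' is raised. Atlases sharing the target's `id` are excluded (leave-one-out
#' discipline).
#'
#' @param target [volume()] to segment.
#' @param atlases list of [atlas()]s.
#' @param reg_config a [registration_config()].
#' @param target_id optional id to exclude from the atlas list.
#' @return A `candidate_stack`: list with per-atlas `labels`, `images`,
#'   `transforms` and `ids`, all on the target grid.
#' @export
build_candidates <- function(target, atlases, reg_config =
                               registration_config(), target_id = NULL) {
  stopifnot(is_vol3d(target), length(atlases) >= 1L)
  if (!is.null(target_id))
    atlases <- Filter(function(a) !identical(a$id, target_id), atlases)
  if (!length(atlases))
    stop("no atlases left after excluding the target id", call. = FALSE)
  labels <- list(); images <- list(); transforms <- list(); ids <- character()
  for (i in seq_along(atlases)) {
    a <- atlases[[i]]
    cfg <- reg_config
    cfg$rng_seed <- reg_config$rng_seed + 17L * i
    tf <- tryCatch(register_pairwise(target, a$image, cfg),
                   error = function(e) e)
    if (inherits(tf, "error")) {
      warning("atlas '", a$id, "' dropped: ", conditionMessage(tf),
              call. = FALSE)
      next
    }
    n <- length(labels) + 1L
    labels[[n]] <- resample_labels(a$labels, tf, target)
    images[[n]] <- resample_volume(a$image, tf, target, "linear")
    transforms[[n]] <- tf
    ids[n] <- a$id
  }
  if (!length(labels))
    stop("all atlas registrations failed", call. = FALSE)
  structure(list(labels = labels, images = images, transforms = transforms,
                 ids = ids, atlases = atlases),
            class = "candidate_stack")
}

#' Rank atlases by global normalized cross-correlation
#'
#' NCC between each registered atlas intensity and the target, evaluated
#' over the target foreground bounding box (intensities above `air_threshold`
#' define the foreground). Ties break by atlas position in the stack.
#'
#' @param stack a `candidate_stack`.
#' @param target the target [volume()].
#' @param air_threshold intensity below which a voxel counts as air.
#' @return Integer vector of atlas indices, best first, with attribute
#'   `ncc` giving the scores in stack order.
#' @export
rank_atlases_global <- function(stack, target, air_threshold = NULL) {
  stopifnot(inherits(stack, "candidate_stack"))
  if (is.null(air_threshold))
    air_threshold <- min(target$voxels) + 0.1 * diff(range(target$voxels))
  fg <- which(target$voxels > air_threshold, arr.ind = TRUE)
  if (!nrow(fg)) fg <- which(target$voxels >= min(target$voxels),
                             arr.ind = TRUE)
  lo <- apply(fg, 2, min); hi <- apply(fg, 2, max)
  sel <- target$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  ncc <- vapply(stack$images, function(im) {
    v <- im$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    if (sd(v) == 0 || sd(sel) == 0) 0 else stats::cor(as.vector(sel),
                                                      as.vector(v))
  }, 0)
  ord <- order(-ncc, seq_along(ncc))
  attr(ord, "ncc") <- ncc
  ord
}

#' Local normalized cross-correlation weight maps
#'
#' Voxelwise NCC between each registered atlas intensity and the target,
#' computed from local means, variances and covariances smoothed with the
#' fusion kernel (Gaussian of sigma `k` voxels, or boxcar cube of edge
#' `2k+1`). Values are clipped to `[-1, 1]`; voxels where either local
#' variance vanishes get weight 0.
#'
#' @param stack a `candidate_stack`.
#' @param target the target [volume()].
#' @param k kernel size in voxels.
#' @param kernel "gaussian" or "boxcar".
#' @return list of weight [volume()]s, one per atlas.
#' @export
lncc_weight_maps <- function(stack, target, k = 5L,
                             kernel = c("gaussian", "boxcar")) {
  kernel <- match.arg(kernel)
  sm <- if (kernel == "gaussian") {
    function(a) array(cpp_gauss3(as.double(a), dim(a), rep(k, 3)), dim(a))
  } else {
    function(a) boxcar3(a, k)
  }
  tv <- target$voxels
  mu_t <- sm(tv)
  var_t <- pmax(sm(tv * tv) - mu_t^2, 0)
  lapply(stack$images, function(im) {
    av <- im$voxels
    mu_a <- sm(av)
    var_a <- pmax(sm(av * av) - mu_a^2, 0)
    cov_at <- sm(av * tv) - mu_a * mu_t
    den <- sqrt(var_a * var_t)
    w <- ifelse(den > 1e-12, cov_at / pmax(den, 1e-300), 0)
    w <- pmin(pmax(w, -1), 1)
    volume(array(w, dim = dim(tv)), spacing = target$spacing,
           origin = target$origin, direction = target$direction)
  })
}

# cube moving average of edge 2k+1 (separable, reflecting borders)
boxcar3 <- function(a, k) {
  one <- function(m, axis) {
    n <- dim(m)[axis]
    idx <- lapply(seq(-k, k), function(s) {
      i <- seq_len(n) + s
      i[i < 1] <- 1 - (i[i < 1] - 1) - 1
      i[i > n] <- 2 * n - i[i > n] + 1
      pmin(pmax(i, 1), n)
    })
    acc <- 0
    for (i in idx) {
      ia <- list(quote(expr = ), quote(expr = ), quote(expr = ))
      ia[[axis]] <- i
      acc <- acc + do.call(`[`, c(list(m), ia, list(drop = FALSE)))
    }
    acc / length(idx)
  }
  one(one(one(a, 1), 2), 3)
}

#' Fuse candidate label maps into one segmentation
#'
#' Per voxel, votes are counted over the full multi-label alphabet
#' (background included) and the winning label is the argmax, ties broken
#' toward the smallest label value:
#' * MV — all atlases vote;
#' * GNCC — only the `r` globally top-ranked atlases vote;
#' * LNCC — at each voxel, only the `r` atlases with the highest local
#'   weight there vote.
#'
#' @param stack a `candidate_stack`.
#' @param target the target [volume()].
#' @param config a [fusion_config()].
#' @return A [labelmap()] on the target grid.
#' @export
fuse_labels <- function(stack, target, config = fusion_config()) {
  stopifnot(inherits(stack, "candidate_stack"))
  na <- length(stack$labels)
  if (config$method != "MV" && config$r > na)
    stop("r (", config$r, ") exceeds the stack size (", na, ")",
         call. = FALSE)
  lm <- vapply(stack$labels, function(l) as.integer(l$voxels),
               integer(prod(vol_dim(target))))
  lm <- matrix(lm, ncol = na)
  fused <- switch(config$method,
    MV = cpp_fuse_topr(lm, matrix(0, 0, 0), na),
    GNCC = {
      ord <- rank_atlases_global(stack, target)
      cpp_fuse_topr(lm[, ord[seq_len(config$r)], drop = FALSE],
                    matrix(0, 0, 0), config$r)
    },
    LNCC = {
      w <- lncc_weight_maps(stack, target, config$k, config$kernel)
      wm <- vapply(w, function(x) as.double(x$voxels),
                   numeric(prod(vol_dim(target))))
      cpp_fuse_topr(lm, matrix(wm, ncol = na), config$r)
    })
  labelmap(array(fused, dim = vol_dim(target)), reference = target)
}

#' End-to-end multi-atlas segmentation
#'
#' Registers every atlas to the target, propagates labels, and fuses them.
#' Returns the fused segmentation together with the candidate stack and
#' per-atlas transforms needed by landmark propagation.
#'
#' @inheritParams build_candidates
#' @param fusion_config a [fusion_config()].
#' @return list(segmentation = [labelmap()], stack = `candidate_stack`,
#'   transforms = list of `spatial_transform`).
#' @export
segment_multi_atlas <- function(target, atlases,
                                reg_config = registration_config(),
                                fusion_config = fusion_config(),
                                target_id = NULL) {
  stack <- build_candidates(target, atlases, reg_config, target_id)
  seg <- if (length(stack$labels) == 1L) {
    labelmap(array(as.integer(stack$labels[[1]]$voxels),
                   dim = vol_dim(target)), reference = target)
  } else {
    cfg <- fusion_config
    cfg$r <- min(cfg$r, length(stack$labels))
    fuse_labels(stack, target, cfg)
  }
  list(segmentation = seg, stack = stack, transforms = stack$transforms)
}
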