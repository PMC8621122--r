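# File I/O: volumes as MetaImage (.mha/.mhd) or NIfTI (.nii/.nii.gz),
# landmarks as CSV (name,label,x,y,z in world mm), transforms as JSON.

#' Read a 3D volume from disk
#'
#' Supported formats: MetaImage (`.mha` single file, `.mhd` + raw) and NIfTI
#' (`.nii`, `.nii.gz`). Geometry (spacing, origin, direction) is taken from
#' the header; intensities are returned unmodified.
#'
#' @param path file path.
#' @param as_labels logical; return a [labelmap()] (values must be
#'   nonnegative integers).
#' @return A [volume()] or [labelmap()].
#' @export
read_volume <- function(path, as_labels = FALSE) {
  ext <- volume_format(path)
  if (!file.exists(path))
    stop("cannot read volume: file not found: ", path, call. = FALSE)
  v <- switch(ext,
              mha = , mhd = read_metaimage(path),
              nii = read_nifti_volume(path))
  if (as_labels)
    v <- labelmap(v$voxels, spacing = v$spacing, origin = v$origin,
                  direction = v$direction)
  v
}

#' Write a 3D volume to disk
#'
#' The written file round-trips through [read_volume()] with lossless
#' geometry; integer-valued data (label maps) are stored in an integer
#' element type and round-trip exactly.
#'
#' @param vol a [volume()] or [labelmap()].
#' @param path destination; format chosen by extension (.mha/.mhd/.nii/.nii.gz).
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_vol3d(vol))
  if (!dir.exists(dirname(path)))
    stop("cannot write volume: directory does not exist: ", dirname(path),
         call. = FALSE)
  ext <- volume_format(path)
  switch(ext,
         mha = , mhd = write_metaimage(vol, path),
         nii = write_nifti_volume(vol, path))
  invisible(path)
}

volume_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.mha$", low)) return("mha")
  if (grepl("\\.mhd$", low)) return("mhd")
  if (grepl("\\.nii$", low) || grepl("\\.nii\\.gz$", low)) return("nii")
  stop("unsupported volume format: ", path,
       " (use .mha, .mhd, .nii or .nii.gz)", call. = FALSE)
}

# ------------------------------------------------------------- MetaImage

.met_types <- data.frame(
  name = c("MET_CHAR", "MET_UCHAR", "MET_SHORT", "MET_USHORT", "MET_INT",
           "MET_UINT", "MET_FLOAT", "MET_DOUBLE"),
  what = c("integer", "integer", "integer", "integer", "integer", "integer",
           "double", "double"),
  size = c(1L, 1L, 2L, 2L, 4L, 4L, 4L, 8L),
  signed = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
  stringsAsFactors = FALSE)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("I/O error reading ", path, ": truncated MetaImage header",
           call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L)
      stop("I/O error reading ", path, ": malformed header line: ", line,
           call. = FALSE)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "3")
  if (ndims != 3L)
    stop("unsupported MetaImage: NDims = ", ndims, call. = FALSE)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% "0 0 0",
                                "\\s+")[[1]])
  dirv <- as.numeric(strsplit(hdr$TransformMatrix %||%
                                "1 0 0 0 1 0 0 0 1", "\\s+")[[1]])
  direction <- matrix(dirv, 3, 3)  # row i of file = world direction of axis i
  type <- hdr$ElementType %||% "MET_SHORT"
  tt <- .met_types[.met_types$name == type, ]
  if (nrow(tt) != 1L)
    stop("unsupported MetaImage element type: ", type, call. = FALSE)
  msb <- identical(tolower(hdr$BinaryDataByteOrderMSB %||% "false"), "true")
  if (identical(tolower(hdr$CompressedData %||% "false"), "true"))
    stop("compressed MetaImage data is not supported: ", path, call. = FALSE)
  n <- prod(dims)
  if (!identical(hdr$ElementDataFile, "LOCAL")) {
    close(con); on.exit()
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path))
      stop("I/O error reading ", path, ": missing data file ", raw_path,
           call. = FALSE)
    con <- file(raw_path, "rb")
    on.exit(close(con))
  }
  vals <- readBin(con, what = tt$what, n = n, size = tt$size,
                  signed = tt$signed, endian = if (msb) "big" else "little")
  if (length(vals) != n)
    stop("I/O error reading ", path, ": truncated voxel data (",
         length(vals), " of ", n, " values)", call. = FALSE)
  volume(array(as.double(vals), dim = dims), spacing = spacing,
         origin = origin, direction = direction)
}

write_metaimage <- function(vol, path) {
  v <- vol$voxels
  is_int <- all(v == round(v)) && min(v) >= -32768 && max(v) <= 32767
  type <- if (is_int) "MET_SHORT" else "MET_DOUBLE"
  local_data <- volume_format(path) == "mha"
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =",
          paste(format(as.numeric(vol$direction), digits = 17),
                collapse = " ")),
    paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =",
          paste(format(vol$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(dim(v), collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", if (local_data) "LOCAL" else raw_name))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write volume: ", path,
                                           call. = FALSE))
  writeLines(hdr, con)
  if (!local_data) {
    close(con)
    con <- file(file.path(dirname(path), raw_name), "wb")
  }
  if (is_int) writeBin(as.integer(v), con, size = 2L, endian = "little")
  else writeBin(as.double(v), con, size = 8L, endian = "little")
  close(con)
  invisible(path)
}

# ---------------------------------------------------------------- NIfTI

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("I/O error reading ", path, ": ",
                                           conditionMessage(e),
                                           call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("unsupported NIfTI: expected a 3D image: ", path, call. = FALSE)
  x <- RNifti::xform(img)
  lin <- x[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  direction <- sweep(lin, 2, spacing, "/")
  volume(array(as.double(arr), dim = dim(arr)), spacing = spacing,
         origin = x[1:3, 4], direction = direction)
}

write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  x <- diag(4)
  x[1:3, 1:3] <- vol$direction %*% diag(vol$spacing)
  x[1:3, 4] <- vol$origin
  RNifti::pixdim(img) <- vol$spacing  # scale lives in pixdim on disk
  RNifti::sform(img) <- structure(x, code = 2L)
  RNifti::qform(img) <- structure(x, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# -------------------------------------------------------------- landmarks

#' Read / write landmark sets as CSV
#'
#' CSV with header `name,label,x,y,z`, coordinates in world mm. Duplicate
#' names are a validation error; a file with only the header yields an empty
#' set. Round-trips are lossless to better than 1e-9 mm.
#'
#' @param path CSV file path.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop("cannot read landmarks: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "label", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("landmark file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  validate_landmarks(df[need])
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path) {
  landmarks <- validate_landmarks(as.data.frame(landmarks))
  df <- landmarks
  for (col in c("x", "y", "z")) df[[col]] <- format(df[[col]], digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -------------------------------------------------------------- transforms

#' Read / write spatial transforms as JSON
#'
#' Serializes the transform kind, parameter vector and (for B-spline stages)
#' the control-grid metadata.
#' @param tf a `spatial_transform`.
#' @param path JSON file path.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(transform_to_list(tf), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path))
    stop("cannot read transform: file not found: ", path, call. = FALSE)
  transform_from_list(jsonlite::read_json(path, simplifyVector = TRUE,
                                          simplifyDataFrame = FALSE))
}

transform_to_list <- function(tf) {
  switch(tf$kind,
         rigid = ,
         affine = list(kind = tf$kind, matrix = as.numeric(tf$matrix)),
         bspline = list(kind = "bspline", coef = as.numeric(tf$coef),
                        grid_dim = dim(tf$coef)[1:3],
                        grid_origin = tf$grid_origin,
                        grid_spacing = tf$grid_spacing),
         composite = list(kind = "composite",
                          stages = lapply(tf$stages, transform_to_list)))
}

transform_from_list <- function(x) {
  switch(x$kind,
         rigid = rigid_transform(matrix(x$matrix, 4, 4)),
         affine = affine_transform(matrix(x$matrix, 4, 4)),
         bspline = bspline_transform(
           array(x$coef, dim = c(x$grid_dim, 3)),
           grid_origin = x$grid_origin, grid_spacing = x$grid_spacing),
         composite = composite_transform(lapply(x$stages,
                                                transform_from_list)),
         stop("unknown transform kind in file: ", x$kind, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
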