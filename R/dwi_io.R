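#' Construct a multi-b diffusion-weighted series
#'
#' Bundles a 4-D signal array (x, y, z, volume) with the b-value acquired for
#' each volume. Volumes are kept in acquisition order; the i-th b-value always
#' describes the i-th volume. The reference signal S0 used by the fitters is
#' the mean of all volumes acquired at the minimum b-value.
#'
#' @param signal 4-D numeric array of non-negative, finite signal intensities
#'   in arbitrary scanner units, dimensions (x, y, z, volume).
#' @param bvalues Numeric vector of non-negative b-values (s/mm^2), one per
#'   volume, in acquisition order.
#' @param voxel_size Numeric length-3 vector of voxel dimensions in mm.
#' @param affine 4x4 numeric voxel-to-world transform.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(signal, bvalues, voxel_size = c(1, 1, 1),
                       affine = diag(4)) {
  signal <- as.array(signal)
  if (length(dim(signal)) == 3L) dim(signal) <- c(dim(signal), 1L)
  if (length(dim(signal)) != 4L)
    stop("'signal' must be a 4-D array (x, y, z, volume)", call. = FALSE)
  bvalues <- as.numeric(bvalues)
  if (dim(signal)[4] != length(bvalues))
    stop(sprintf("dimension mismatch: %d volumes but %d b-values",
                 dim(signal)[4], length(bvalues)), call. = FALSE)
  if (anyNA(bvalues) || any(bvalues < 0))
    stop("b-values must be non-negative and finite", call. = FALSE)
  if (!all(is.finite(signal)))
    stop("signal contains non-finite values", call. = FALSE)
  if (any(signal < 0))
    stop("signal contains negative values", call. = FALSE)
  storage.mode(signal) <- "double"
  structure(
    list(signal = signal, bvalues = bvalues,
         voxel_size = as.numeric(voxel_size), affine = affine),
    class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("DWI series: %d x %d x %d grid, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat("b-values (s/mm^2):", paste(x$bvalues, collapse = " "), "\n")
  invisible(x)
}

#' @rdname dwi_series
#' @param x A `dwi_series`.
#' @export
n_volumes <- function(x) dim(x$signal)[4]

spatial_dim <- function(x) dim(x$signal)[1:3]

#' Read a b-value table
#'
#' Accepts the FSL-style single-line whitespace-separated `.bval` dialect, or
#' a two-column table (volume index, b-value). Values are returned in file
#' (acquisition) order.
#'
#' @param path Path to the b-value file.
#' @return Numeric vector of b-values (s/mm^2).
#' @export
read_bvals <- function(path) {
  if (!file.exists(path)) stop("b-value file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty b-value file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[[:space:],]+")
  ncols <- vapply(fields, length, 1L)
  if (length(lines) > 1L && all(ncols == 2L)) {
    bv <- vapply(fields, function(f) as.numeric(f[2]), 1.0)  # (volume, b) TSV
  } else {
    bv <- as.numeric(unlist(fields))
  }
  if (anyNA(bv)) stop("non-numeric entries in b-value file: ", path, call. = FALSE)
  if (any(bv < 0)) stop("negative b-value in ", path, call. = FALSE)
  bv
}

#' Read a 4-D DWI NIfTI volume with its b-value table
#'
#' @param image_path Path to a 4-D NIfTI (.nii or .nii.gz) image.
#' @param bval_path Path to the accompanying b-value file (see [read_bvals()]).
#' @return A [dwi_series()].
#' @export
read_dwi <- function(image_path, bval_path) {
  img <- RNifti::readNifti(image_path)
  bv <- read_bvals(bval_path)
  arr <- strip_nifti_attrs(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L)
    stop("expected a 4-D NIfTI image, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  dwi_series(arr, bv,
             voxel_size = RNifti::pixdim(img)[1:3],
             affine = unclass(RNifti::xform(img)))
}

#' Write a DWI series to NIfTI + b-value files
#'
#' @param series A [dwi_series()].
#' @param image_path Output NIfTI path.
#' @param bval_path Output b-value path (FSL single-line dialect).
#' @export
write_dwi <- function(series, image_path, bval_path) {
  stopifnot(inherits(series, "dwi_series"))
  img <- RNifti::asNifti(series$signal)
  RNifti::pixdim(img) <- c(series$voxel_size, 1)
  RNifti::sform(img) <- structure(series$affine, code = 2L)
  RNifti::writeNifti(img, image_path)
  writeLines(paste(format(series$bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  invisible(NULL)
}

#' Read a binary ROI mask and check it against a DWI grid
#'
#' Any nonzero voxel is part of the ROI (single-ROI convention: multi-label
#' masks are collapsed). The mask must live on exactly the same spatial grid
#' as the reference series; no resampling is performed.
#'
#' @param path Path to a 3-D NIfTI mask.
#' @param reference A [dwi_series()] defining the expected grid.
#' @return An object of class `roi_mask`: logical 3-D array plus a label.
#' @export
read_mask <- function(path, reference) {
  arr <- strip_nifti_attrs(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L)
    stop("mask must be a 3-D NIfTI image", call. = FALSE)
  roi_mask(arr != 0, reference, label = basename(path))
}

#' @rdname read_mask
#' @param mask Logical (or coercible) 3-D array.
#' @param label Text label for the ROI.
#' @export
roi_mask <- function(mask, reference = NULL, label = "roi") {
  mask <- as.array(mask) != 0
  if (length(dim(mask)) != 3L)
    stop("mask must be a 3-D array", call. = FALSE)
  if (!is.null(reference) && !identical(dim(mask), as.integer(spatial_dim(reference))) &&
      !identical(as.integer(dim(mask)), as.integer(spatial_dim(reference))))
    stop(sprintf("mask grid %s does not match DWI grid %s",
                 paste(dim(mask), collapse = "x"),
                 paste(spatial_dim(reference), collapse = "x")), call. = FALSE)
  if (!any(mask)) stop("empty ROI: mask has no nonzero voxels", call. = FALSE)
  structure(list(mask = mask, label = label), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI '%s': %d voxels on a %s grid\n", x$label, sum(x$mask),
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' Construct a voxelwise parameter map
#'
#' @param values 3-D numeric array; NaN marks voxels that were outside the
#'   mask or failed to fit.
#' @param parameter_name One of `mu_diff`, `f`, `D`, `Dstar`, `DDC`, `Alpha`,
#'   `ADC`, `S0`.
#' @param units Unit string (e.g. "kPa", "mm^2/s", "fraction").
#' @param affine 4x4 transform propagated from the source series.
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(values, parameter_name,
                          units = default_units(parameter_name),
                          affine = diag(4)) {
  parameter_name <- match.arg(parameter_name,
    c("mu_diff", "f", "D", "Dstar", "DDC", "Alpha", "ADC", "S0"))
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("parameter map values must be 3-D", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, parameter_name = parameter_name,
                 units = units, affine = affine),
            class = "parameter_map")
}

default_units <- function(parameter_name) {
  switch(parameter_name,
         mu_diff = "kPa", f = "fraction", Alpha = "unitless",
         S0 = "signal", "mm^2/s")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[!is.nan(x$values)]
  cat(sprintf("parameter map '%s' [%s]: %s grid, %d fitted voxels",
              x$parameter_name, x$units,
              paste(dim(x$values), collapse = "x"), length(v)))
  if (length(v)) cat(sprintf(", mean %.4g", mean(v)))
  cat("\n")
  invisible(x)
}

#' Write a parameter map as NIfTI
#'
#' The source affine is propagated and NaN voxels are preserved (written as
#' floating point).
#'
#' @param map A [parameter_map()].
#' @param path Output NIfTI path.
#' @export
write_parameter_map <- function(map, path) {
  stopifnot(inherits(map, "parameter_map"))
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- sqrt(colSums(map$affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(map$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(NULL)
}

# drop RNifti image attributes, leaving a plain numeric array
strip_nifti_attrs <- function(img) {
  arr <- as.array(img)
  array(as.vector(arr), dim(arr))
}

#' @rdname write_parameter_map
#' @param parameter_name Parameter housed in the file being read.
#' @export
read_parameter_map <- function(path, parameter_name) {
  img <- RNifti::readNifti(path)
  parameter_map(strip_nifti_attrs(img), parameter_name,
                affine = unclass(RNifti::xform(img)))
}

cohort_required_cols <- c("subject_id", "group")
cohort_parameters <- c("mu_diff", "f", "D", "Dstar", "DDC", "Alpha", "ADC")

#' Read / write a per-subject cohort table
#'
#' The cohort table carries one row per subject: outcome group
#' (`adverse`/`non_adverse`), clinical covariates, and ROI-mean quantitative
#' parameters on reporting scales (mu_diff kPa; f percent; D, Dstar, DDC, ADC
#' in 10^-3 mm^2/s; Alpha unitless). Unknown columns are preserved.
#'
#' @param path CSV path (header required, UTF-8).
#' @return A `data.frame` of class `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort_table(df)
}

#' @rdname read_cohort
#' @param df A data frame with at least `subject_id` and `group` columns.
#' @export
as_cohort_table <- function(df) {
  if (nrow(df) == 0L) stop("empty cohort table", call. = FALSE)
  missing_cols <- setdiff(cohort_required_cols, names(df))
  if (length(missing_cols))
    stop("cohort table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in cohort table", call. = FALSE)
  if (any(is.na(df$group) | !nzchar(df$group)))
    stop("missing group label in cohort table", call. = FALSE)
  bad <- setdiff(unique(df$group), c("adverse", "non_adverse"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (p in intersect(cohort_parameters, names(df))) {
    df[[p]] <- as.numeric(df[[p]])
    if (any(!is.finite(df[[p]]) & !is.na(df[[p]])))
      stop("non-finite values in parameter column ", p, call. = FALSE)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @rdname read_cohort
#' @param cohort A `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(NULL)
}

#' @export
print.cohort_table <- function(x, ...) {
  tab <- table(x$group)
  cat(sprintf("cohort table: %d subjects (%s)\n", nrow(x),
              paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  NextMethod()
}
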