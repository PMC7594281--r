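## Reading and writing images, masks, cohort manifests and feature tables.
## NIfTI (via RNifti) preserves intensities exactly and is the default
## on-disk format; PNG is supported for reading (8- and 16-bit grayscale,
## rescaled to integer intensity units) and for 8-bit writing (binary masks
## round-trip exactly). Pixel spacing travels in the cohort manifest.

#' Select the slice with the longest tumor diameter
#'
#' Given a stack of 2D masks (e.g. per-slice segmentations of a 3D tumor),
#' returns the index of the slice whose mask has the largest maximum Feret
#' diameter (largest pairwise distance between boundary pixel centers, in
#' mm). Ties are broken by the lowest index; empty slices are skipped.
#'
#' @param mask_stack List of logical (or 0/1) matrices.
#' @param spacing Pixel spacing in mm (scalar or `(row, col)`).
#' @return Integer slice index (1-based).
#' @export
select_longest_diameter_slice <- function(mask_stack, spacing = c(1, 1)) {
  stopifnot(is.list(mask_stack), length(mask_stack) >= 1)
  feret <- vapply(mask_stack, function(m) {
    if (!any(m != 0)) return(-Inf)
    feret_diameter(m, spacing)
  }, numeric(1))
  if (all(!is.finite(feret))) stop("all slices are empty")
  which.max(feret)  # which.max returns the first (lowest) index on ties
}

#' Read a grayscale image or mask from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`; exact values) and grayscale PNG
#' (`.png`; values rescaled from the unit interval to integer intensity
#' units, `0..255` for 8-bit and `0..65535` for 16-bit files).
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    x <- RNifti::readNifti(path)
    return(matrix(as.numeric(x), dim(x)[1], dim(x)[2]))
  }
  if (grepl("\\.png$", path)) {
    x <- png::readPNG(path, info = TRUE)
    bd <- attr(x, "info")$bit.depth
    if (length(dim(x)) == 3) x <- x[, , 1]
    return(matrix(as.numeric(x) * (2^bd - 1), nrow(x), ncol(x)))
  }
  stop("unsupported image format: ", path)
}

#' Write a grayscale image or mask to disk
#'
#' NIfTI output stores doubles exactly; PNG output is 8-bit (intensities
#' must be integers in 0..255 — suitable for binary masks).
#'
#' @param x Numeric matrix.
#' @param path Output path ending in `.nii`, `.nii.gz` or `.png`.
#' @export
write_image <- function(x, path) {
  stopifnot(is.matrix(x))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(x), path)
    return(invisible(path))
  }
  if (grepl("\\.png$", path)) {
    if (any(x < 0 | x > 255 | x != round(x)))
      stop("PNG output is 8-bit: intensities must be integers in 0..255")
    png::writePNG(x / 255, path)
    return(invisible(path))
  }
  stop("unsupported image format: ", path)
}

#' Write a phantom cohort to disk
#'
#' Writes each subject's image and both observer masks plus a manifest CSV
#' (`subject_id`, `class_label`, `vendor`, `pixel_spacing_mm` and relative
#' file paths).
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` (default, exact) or `"png"` (masks only are
#'   exact; images must be 8-bit representable).
#' @return The manifest as a data.frame, invisibly; also written to
#'   `manifest.csv` in `dir`.
#' @export
write_cohort <- function(cohort, dir, format = c("nifti", "png")) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".png"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    ip <- paste0(s$subject_id, "_image", ext)
    m1 <- paste0(s$subject_id, "_mask_obs1", ext)
    m2 <- paste0(s$subject_id, "_mask_obs2", ext)
    write_image(s$image, file.path(dir, ip))
    write_image((s$mask_obs1 != 0) * 1, file.path(dir, m1))
    write_image((s$mask_obs2 != 0) * 1, file.path(dir, m2))
    data.frame(subject_id = s$subject_id, class_label = s$class_label,
               vendor = s$vendor, pixel_spacing_mm = s$pixel_spacing_mm,
               image_path = ip, mask_obs1_path = m1, mask_obs2_path = m2,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Load one subject from a cohort directory
#'
#' Reads the image and both observer masks named in a manifest row and
#' validates them: shapes must match and masks must be non-empty binary
#' arrays.
#'
#' @param manifest_row One row of the manifest data.frame.
#' @param dir Cohort directory the paths are relative to.
#' @return A `phantom_subject` (masks logical).
#' @export
load_subject <- function(manifest_row, dir) {
  img <- read_image(file.path(dir, manifest_row$image_path))
  m1 <- read_image(file.path(dir, manifest_row$mask_obs1_path))
  m2 <- read_image(file.path(dir, manifest_row$mask_obs2_path))
  if (!identical(dim(img), dim(m1)) || !identical(dim(img), dim(m2)))
    stop("shape mismatch between image and mask for ",
         manifest_row$subject_id)
  if (!all(m1 %in% c(0, 1)) || !all(m2 %in% c(0, 1)))
    stop("mask is not binary for ", manifest_row$subject_id)
  if (!any(m1 != 0) || !any(m2 != 0))
    stop("empty mask for ", manifest_row$subject_id)
  structure(list(image = img, mask_obs1 = m1 != 0, mask_obs2 = m2 != 0,
                 class_label = manifest_row$class_label,
                 vendor = manifest_row$vendor,
                 pixel_spacing_mm = manifest_row$pixel_spacing_mm,
                 subject_id = manifest_row$subject_id),
            class = "phantom_subject")
}

.ft_meta_cols <- c("subject_id", "observer", "class_label", "vendor")

#' Write / read a feature table
#'
#' Feature tables have one row per (subject, observer) with the metadata
#' columns `subject_id`, `observer`, `class_label`, `vendor` followed by the
#' 87 feature columns. CSV serialization preserves doubles to full
#' round-trip precision and column order.
#'
#' @param table Feature table data.frame.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  data.table::fwrite(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @return `read_feature_table` returns the table as a data.frame; it
#'   errors if a required metadata column is missing.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- as.data.frame(data.table::fread(path))
  missing <- setdiff(.ft_meta_cols, names(tab))
  if (length(missing) > 0)
    stop("feature table missing required columns: ",
         paste(missing, collapse = ", "))
  tab
}
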