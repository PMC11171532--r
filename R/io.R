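#' Read a mammogram from PNG or TIFF
#'
#' Pixel values are returned as raw detector numbers at the file's stored bit
#' depth (no implicit rescaling); use [normalize_intensity()] to map onto
#' `[0, 1]`. DICOM input is not supported in this build; convert to 16-bit
#' PNG/TIFF upstream.
#'
#' @param path file path.
#' @param laterality `"L"` or `"R"` for the returned metadata.
#' @param format `"auto"` (by extension), `"png"`, or `"tiff"`.
#' @param thickness_mm optional compressed-breast-thickness metadata.
#' @return a [mammogram_image()] with `normalized = FALSE`.
#' @export
read_mammogram <- function(path, laterality, format = "auto",
                           thickness_mm = NA_real_) {
  if (!file.exists(path))
    stop_mammosub(sprintf("mammogram file not found: '%s'", path),
                  "missing_file")
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     png = "png", tif = "tiff", tiff = "tiff",
                     stop_mammosub(sprintf(
                       "unsupported mammogram format for '%s'", path),
                       "bad_format"))
  if (format == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3) x <- x[, , 1]
    bd <- png_bit_depth(path)
    pixels <- round(x * (2^bd - 1))
  } else if (format == "tiff") {
    x <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(x)) == 3) x <- x[, , 1]
    bd <- attr(x, "bits.per.sample")
    if (is.null(bd)) bd <- 16L
    pixels <- x
    attributes(pixels) <- list(dim = dim(x))
  } else {
    stop_mammosub(sprintf("unsupported format '%s'", format), "bad_format")
  }
  mammogram_image(pixels, laterality = laterality, bit_depth = bd,
                  thickness_mm = thickness_mm, normalized = FALSE)
}

# bit depth straight from the PNG IHDR (png::readPNG does not report it)
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", 26)
  as.integer(hdr[25])
}

#' Write an image as 16-bit grayscale PNG
#'
#' Intensities on `[0, 1]` are scaled linearly to `[0, 65535]`; raw images
#' are written at their stored values.
#'
#' @param img [mammogram_image()] or numeric matrix on `[0, 1]`.
#' @param path output path.
#' @export
write_mammogram <- function(img, path) {
  m <- img_matrix(img)
  if (isTRUE(attr(img, "normalized")) || max(m) <= 1)
    m <- m * 65535
  cpp_write_png16(m, path)
  invisible(path)
}

#' Write a difference image as 16-bit PNG
#'
#' The absolute difference image is the pipeline's diagnostic output. Values
#' must lie in `[0, 1]` and are stored with the fixed linear scaling
#' `[0, 1] -> [0, 65535]`, so files from different cases are directly
#' comparable; reloading reproduces each pixel within 1/65535.
#'
#' @param diff numeric matrix in `[0, 1]`.
#' @param path output path.
#' @export
write_difference_image <- function(diff, path) {
  if (any(!is.finite(diff)))
    stop_mammosub("difference image contains non-finite values", "bad_input")
  if (min(diff) < 0 || max(diff) > 1)
    stop_mammosub("difference image values must lie in [0, 1]", "bad_input")
  cpp_write_png16(img_matrix(diff) * 65535, path)
  invisible(path)
}

#' Read a difference image written by [write_difference_image()]
#' @param path input path.
#' @return numeric matrix on `[0, 1]`.
#' @export
read_difference_image <- function(path) {
  if (!file.exists(path))
    stop_mammosub(sprintf("file not found: '%s'", path), "missing_file")
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

#' Persist a displacement field as 32-bit float multi-channel TIFF
#'
#' Channel 1 holds row displacements, channel 2 column displacements, both in
#' pixels. Storage is uncompressed little-endian float32, so a write/read
#' cycle is lossless at float32 precision.
#'
#' @param field a [displacement_field()] or an `H x W x 2` array.
#' @param path output path.
#' @export
write_displacement_field <- function(field, path) {
  if (inherits(field, "displacement_field")) {
    arr <- array(c(field$u_row, field$u_col),
                 dim = c(dim(field$u_row), 2))
  } else {
    arr <- field
  }
  d <- dim(arr)
  if (length(d) != 3 || d[3] != 2)
    stop_mammosub("displacement fields have exactly 2 channels", "bad_input")
  cpp_write_tiff_float(arr, d[1], d[2], 2L, path)
  invisible(path)
}

#' Read a displacement field written by [write_displacement_field()]
#' @param path input path.
#' @return a [displacement_field()].
#' @export
read_displacement_field <- function(path) {
  if (!file.exists(path))
    stop_mammosub(sprintf("field file not found: '%s'", path), "missing_file")
  arr <- cpp_read_tiff_float(path)
  if (dim(arr)[3] != 2)
    stop_mammosub(sprintf("'%s' does not hold a 2-channel field", path),
                  "bad_input")
  displacement_field(arr[, , 1], arr[, , 2])
}

#' Write a binary mask as PNG
#' @param mask a [breast_mask()] or logical matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  cpp_write_png16(img_matrix(mask * 1) * 65535, path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path input path.
#' @return a [breast_mask()].
#' @export
read_mask <- function(path) {
  breast_mask(read_difference_image(path) > 0.5)
}

#' Read and validate a cohort manifest
#'
#' A manifest is a CSV with one row per case: `case_id` (unique),
#' `right_path`, `left_path`, `thickness_mm`, and optional further
#' covariate columns.
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_mammosub(sprintf("manifest not found: '%s'", path), "missing_file")
  m <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("case_id", "right_path", "left_path")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop_mammosub(paste("manifest lacks columns:",
                        paste(miss, collapse = ", ")), "bad_manifest")
  if (anyDuplicated(m$case_id))
    stop_mammosub("manifest case_id values must be unique", "bad_manifest")
  if (any(is.na(m$right_path)) || any(is.na(m$left_path)))
    stop_mammosub("manifest rows must carry both image paths", "bad_manifest")
  m
}

#' Write a cohort manifest CSV
#' @param manifest tibble with at least `case_id`, `right_path`, `left_path`.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
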