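#' Construct a mammogram image object
#'
#' A `mammogram_image` is a numeric matrix (rows = image rows, columns = image
#' columns) carrying acquisition metadata as attributes. Pixel values are
#' either raw detector numbers (`normalized = FALSE`, integers on
#' `[0, 2^bit_depth - 1]`) or normalized intensities on `[0, 1]`
#' (`normalized = TRUE`). By convention the chest wall of a right-breast MLO
#' image lies along column 1; a left-breast image is its mirror, with the
#' chest wall along the last column.
#'
#' @param pixels numeric matrix of pixel values.
#' @param laterality `"L"` or `"R"`.
#' @param view projection view; only `"MLO"` is used here.
#' @param pixel_pitch_um detector pixel pitch in micrometres (optional).
#' @param thickness_mm compressed breast thickness in millimetres (optional).
#' @param bit_depth bit depth of the raw representation (default 16).
#' @param normalized logical; `TRUE` if pixels are already on `[0, 1]`.
#' @return a `mammogram_image` object.
#' @export
mammogram_image <- function(pixels, laterality, view = "MLO",
                            pixel_pitch_um = NA_real_,
                            thickness_mm = NA_real_,
                            bit_depth = 16L, normalized = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_mammosub("`pixels` must be a numeric matrix", "bad_input")
  if (any(!is.finite(pixels)))
    stop_mammosub("pixel values must be finite", "bad_input")
  if (!laterality %in% c("L", "R"))
    stop_mammosub("`laterality` must be \"L\" or \"R\"", "bad_input")
  structure(pixels,
            laterality = laterality, view = view,
            pixel_pitch_um = pixel_pitch_um, thickness_mm = thickness_mm,
            bit_depth = as.integer(bit_depth), normalized = normalized,
            class = c("mammogram_image", "matrix", "array"))
}

#' @export
print.mammogram_image <- function(x, ...) {
  cat(sprintf("<mammogram_image> %d x %d, laterality %s, view %s, %s\n",
              nrow(x), ncol(x), attr(x, "laterality"), attr(x, "view"),
              if (isTRUE(attr(x, "normalized"))) "[0,1]"
              else sprintf("%d-bit raw", attr(x, "bit_depth"))))
  invisible(x)
}

# strip class/attributes down to a plain matrix
img_matrix <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(x))
  m
}

#' Construct a breast mask
#'
#' Binary mask of the breast plus pectoralis major region, stored as a logical
#' matrix with the same shape as its image.
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @return a `breast_mask` object.
#' @export
breast_mask <- function(mask) {
  if (is.numeric(mask)) mask <- mask > 0.5
  if (!is.matrix(mask) || !is.logical(mask))
    stop_mammosub("`mask` must be a logical matrix", "bad_input")
  structure(mask, class = c("breast_mask", "matrix", "array"))
}

#' @export
print.breast_mask <- function(x, ...) {
  cat(sprintf("<breast_mask> %d x %d, %.1f%% foreground\n",
              nrow(x), ncol(x), 100 * mean(x)))
  invisible(x)
}

#' Construct a displacement field
#'
#' A dense per-pixel displacement field in pixel units: `u_row[i, j]` and
#' `u_col[i, j]` say where output pixel `(i, j)` samples the moving image,
#' namely at `(i + u_row, j + u_col)`.
#'
#' @param u_row,u_col numeric matrices of identical shape.
#' @return a `displacement_field` object (list with elements `u_row`, `u_col`).
#' @export
displacement_field <- function(u_row, u_col) {
  if (!is.matrix(u_row) || !is.matrix(u_col) ||
      !identical(dim(u_row), dim(u_col)))
    stop_mammosub("`u_row` and `u_col` must be matrices of identical shape",
                  "bad_input")
  if (any(!is.finite(u_row)) || any(!is.finite(u_col)))
    stop_mammosub("displacement field must be finite", "bad_input")
  structure(list(u_row = u_row, u_col = u_col),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  rms <- field_rms(x)
  cat(sprintf("<displacement_field> %d x %d, RMS %.3f px\n",
              nrow(x$u_row), ncol(x$u_row), rms))
  invisible(x)
}

#' Root-mean-square displacement magnitude of a field, in pixels
#' @param field a [displacement_field()].
#' @export
field_rms <- function(field) {
  sqrt(mean(field$u_row^2 + field$u_col^2))
}

#' Mirror an image about the vertical axis
#'
#' Horizontal flip (left-right mirror); an involution used to map a
#' left-breast MLO image into the right-breast frame. Laterality metadata is
#' preserved, not toggled: flipping changes the frame, not the breast.
#'
#' @param x matrix, `mammogram_image`, or `breast_mask`.
#' @export
flip_horizontal <- function(x) {
  flipped <- x[, rev(seq_len(ncol(x))), drop = FALSE]
  attributes(flipped) <- attributes(x)
  flipped
}

#' Display an image, mask, field component, or difference image
#'
#' @param img matrix-like object to display.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_image <- function(img, title = NULL) {
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.vector(img_matrix(if (is.logical(img)) img * 1 else img))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mammogram_image <- function(object, ...) {
  plot_image(object, title = sprintf("%s %s", attr(object, "laterality"),
                                     attr(object, "view")))
}

#' @export
autoplot.breast_mask <- function(object, ...) plot_image(object, "breast mask")

#' @export
autoplot.displacement_field <- function(object, ...) {
  mag <- sqrt(object$u_row^2 + object$u_col^2)
  plot_image(mag, "displacement magnitude (px)")
}
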