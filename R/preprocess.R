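#' Normalize raw intensities onto `[0, 1]`
#'
#' Divides by the full bit-depth range (`2^bit_depth - 1`), never by the
#' per-image minimum/maximum, so intensities stay comparable across cases.
#' Images already normalized are returned unchanged.
#'
#' @param img a [mammogram_image()] (or numeric matrix, assumed 16-bit).
#' @return the image with values in `[0, 1]` and `normalized = TRUE`.
#' @export
normalize_intensity <- function(img) {
  if (any(img < 0))
    stop_mammosub("raw intensities must be non-negative", "bad_input")
  if (isTRUE(attr(img, "normalized"))) return(img)
  bd <- attr(img, "bit_depth")
  if (is.null(bd)) bd <- 16L
  out <- img / (2^bd - 1)
  a <- attributes(img)
  a$normalized <- TRUE
  attributes(out) <- a
  out
}

#' Detect the breast + pectoralis region by skin-line thresholding
#'
#' Otsu's threshold on the intensity histogram separates tissue from the
#' dark background; the largest connected foreground component is kept,
#' holes are filled, and a light morphological closing smooths the skin
#' line. The pectoralis major is included since it is brighter than
#' background.
#'
#' @param img a [mammogram_image()] (raw or normalized).
#' @return a [breast_mask()].
#' @export
detect_breast_mask <- function(img) {
  x <- img_matrix(normalize_intensity(img))
  eb <- EBImage::Image(x)
  # Otsu alone under-segments the faint skin-line rim; half the Otsu level
  # (capped into the skin-line intensity range, floored above background
  # noise) keeps the rim
  thr <- max(0.04, min(0.5 * EBImage::otsu(eb, range = c(0, 1)), 0.07))
  fg <- x > thr
  if (!any(fg))
    stop_mammosub("no breast detected: empty foreground", "empty_mask")
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  keep <- which.max(tab)
  comp <- matrix(as.integer(lab) == keep, nrow(x), ncol(x))
  comp <- EBImage::fillHull(EBImage::Image(comp * 1))
  brush <- EBImage::makeBrush(5, shape = "disc")
  comp <- EBImage::closing(comp, brush)
  m <- matrix(as.numeric(comp) > 0.5, nrow(x), ncol(x))
  # closing can only merge; keep the largest component for safety
  lab2 <- EBImage::bwlabel(EBImage::Image(m * 1))
  tab2 <- tabulate(as.integer(lab2)[as.integer(lab2) > 0])
  m <- matrix(as.integer(lab2) == which.max(tab2), nrow(x), ncol(x))
  breast_mask(m)
}

#' Geometric preprocessing of one image to network resolution
#'
#' Reproduces the standard chain for a chest-wall-left MLO image: pad the
#' nipple side (right-hand columns) with background to a square while
#' keeping the aspect ratio, resize with bicubic interpolation (4 x 4
#' neighbourhood) to `ceiling-free round(out_size * 520 / 512)` (520 for the
#' default 512 output), then centre-crop to `out_size`. The mask follows the
#' identical geometric chain with nearest-neighbour resampling and
#' re-binarization.
#'
#' @param img a [mammogram_image()] (normalized or raw; raw input is
#'   normalized first).
#' @param mask optional [breast_mask()]; detected from `img` if missing.
#' @param out_size output side length in pixels (default 512).
#' @return list with `image` (out_size x out_size, `[0, 1]`) and `mask`.
#' @export
preprocess_single <- function(img, mask = NULL, out_size = 512L) {
  img <- normalize_intensity(img)
  if (is.null(mask)) mask <- detect_breast_mask(img)
  h <- nrow(img); w <- ncol(img)
  if (w > h)
    stop_mammosub(
      "image is wider than tall; expected portrait MLO orientation",
      "bad_orientation")
  x <- img_matrix(img)
  m <- img_matrix(mask * 1)
  if (w < h) {  # pad the nipple side (right) with background 0
    x <- cbind(x, matrix(0, h, h - w))
    m <- cbind(m, matrix(0, h, h - w))
  }
  pre <- as.integer(round(out_size * 520 / 512))
  xr <- cpp_resize_bicubic(x, pre, pre)
  mr <- cpp_resize_nearest(m, pre, pre)
  off <- (pre - out_size) %/% 2
  idx <- seq_len(out_size) + off
  out <- pmin(pmax(xr[idx, idx], 0), 1)  # bicubic may overshoot slightly
  a <- attributes(img)
  a$dim <- dim(out)
  attributes(out) <- a
  list(image = out, mask = breast_mask(mr[idx, idx] > 0.5))
}

#' Build a registration-ready fixed/flipped pair
#'
#' The right-breast image is the fixed (reference) image; the left-breast
#' image is mirrored about the vertical axis so both have the chest wall on
#' the same side, and both are passed through [preprocess_single()]. The
#' pair's loss/evaluation mask is the fixed image's breast mask.
#'
#' @param right,left [mammogram_image()] objects with opposite lateralities.
#' @param right_mask,left_mask optional [breast_mask()]s at native
#'   resolution (left mask in the unflipped left frame).
#' @param out_size network input size (default 512).
#' @param case_id optional identifier carried through evaluation.
#' @return a `registration_pair`: list with `fixed`, `moving` (the flipped
#'   left image), `mask`, and `case_id`.
#' @export
preprocess_pair <- function(right, left, right_mask = NULL, left_mask = NULL,
                            out_size = 512L, case_id = NA_character_) {
  lr <- attr(right, "laterality"); ll <- attr(left, "laterality")
  if (identical(lr, ll))
    stop_mammosub("`right` and `left` have the same laterality", "bad_pair")
  if (!identical(lr, "R") || !identical(ll, "L"))
    stop_mammosub("`right` must be laterality R and `left` laterality L",
                  "bad_pair")
  left_flipped <- flip_horizontal(left)
  if (!is.null(left_mask)) left_mask <- breast_mask(flip_horizontal(left_mask))
  fx <- preprocess_single(right, right_mask, out_size)
  mv <- preprocess_single(left_flipped, left_mask, out_size)
  structure(list(fixed = fx$image, moving = mv$image, mask = fx$mask,
                 case_id = case_id),
            class = "registration_pair")
}

#' @export
print.registration_pair <- function(x, ...) {
  cat(sprintf("<registration_pair> %s: %d x %d, mask %.1f%%\n",
              x$case_id, nrow(x$fixed), ncol(x$fixed), 100 * mean(x$mask)))
  invisible(x)
}
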