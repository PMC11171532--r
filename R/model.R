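#' U-Net architecture configuration
#'
#' The deformation-field network follows the 2-D VoxelMorph layout: four
#' stride-2 3x3 encoder convolutions, seven stride-1 decoder convolutions
#' with nearest-neighbour x2 upsampling and skip connections (including a
#' final skip from the 2-channel input), LeakyReLU(0.2) activations, and a
#' 3x3 flow head producing a 2-channel displacement field in pixels.
#'
#' @param enc_channels four encoder output-channel counts.
#' @param dec_channels seven decoder output-channel counts.
#' @return a `unet_config` object.
#' @export
unet_config <- function(enc_channels = c(16L, 32L, 32L, 32L),
                        dec_channels = c(32L, 32L, 32L, 32L, 32L, 16L, 16L)) {
  if (length(enc_channels) != 4 || length(dec_channels) != 7 ||
      any(enc_channels < 1) || any(dec_channels < 1))
    stop_mammosub(
      "expected 4 encoder and 7 decoder channel counts, all positive",
      "bad_config")
  structure(list(enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels)),
            class = "unet_config")
}

# per-layer (cin, cout, stride) mirroring the C++ plan; parameter vector is
# the concatenation of each layer's column-major W then bias
unet_layer_plan <- function(config) {
  enc <- config$enc_channels; dec <- config$dec_channels
  cin <- c(2, enc[1:3],
           enc[4], dec[1] + enc[3], dec[2] + enc[2], dec[3] + enc[1],
           dec[4], dec[5] + 2, dec[6], dec[7])
  cout <- c(enc, dec, 2L)
  stride <- c(rep(2L, 4), rep(1L, 8))
  tibble::tibble(cin = cin, cout = cout, stride = stride,
                 n_w = cout * 9 * cin, n_b = cout)
}

#' Initialize a registration model
#'
#' Convolution weights use Kaiming-style normal initialization scaled for
#' LeakyReLU(0.2); biases start at zero. The flow head is zero-initialized so
#' an untrained model predicts the zero field, i.e. the identity transform.
#'
#' @param config a [unet_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @return a `registration_model` (untrained).
#' @export
init_registration_model <- function(config = unet_config(), seed = NULL) {
  plan <- unet_layer_plan(config)
  n_total <- sum(plan$n_w + plan$n_b)
  stopifnot(n_total == cpp_unet_n_params(config$enc_channels,
                                         config$dec_channels))
  params <- with_seed_if(seed, function() {
    gain <- sqrt(2 / (1 + 0.2^2))
    out <- numeric(0)
    for (k in seq_len(nrow(plan))) {
      if (k == nrow(plan)) {         # flow head: exact zeros
        w <- numeric(plan$n_w[k])
      } else {
        w <- rnorm(plan$n_w[k], 0, gain / sqrt(9 * plan$cin[k]))
      }
      out <- c(out, w, numeric(plan$n_b[k]))
    }
    out
  })
  structure(list(params = params, config = config, history = NULL,
                 trained = FALSE),
            class = "registration_model")
}

#' @export
print.registration_model <- function(x, ...) {
  cat(sprintf("<registration_model> %s, %d parameters (enc %s | dec %s)\n",
              if (x$trained) "trained" else "untrained", length(x$params),
              paste(x$config$enc_channels, collapse = "-"),
              paste(x$config$dec_channels, collapse = "-")))
  if (!is.null(x$history))
    cat(sprintf("  %d epochs; final train loss %.5f, val loss %.5f\n",
                nrow(x$history),
                x$history$train_loss[nrow(x$history)],
                x$history$val_loss[nrow(x$history)]))
  invisible(x)
}

as_image_matrix <- function(x, name) {
  m <- img_matrix(x)
  if (any(!is.finite(m)))
    stop_mammosub(sprintf("`%s` contains non-finite values", name),
                  "bad_input")
  m
}

#' Predict the dense displacement field for a fixed/flipped pair
#'
#' Runs the U-Net on the stacked pair; the output has one 2-vector per pixel
#' at input resolution, in pixels of the fixed frame. Inference is
#' deterministic: identical weights and inputs give identical fields.
#'
#' @param model a `registration_model` (see [init_registration_model()]).
#' @param fixed,flipped normalized images of equal size (multiples of 16).
#' @return a [displacement_field()].
#' @export
predict_displacement <- function(model, fixed, flipped) {
  f <- as_image_matrix(fixed, "fixed")
  m <- as_image_matrix(flipped, "flipped")
  if (!identical(dim(f), dim(m)))
    stop_mammosub("`fixed` and `flipped` must share the same shape",
                  "shape_mismatch")
  h <- nrow(f); w <- ncol(f)
  out <- cpp_unet_flow(model$params, model$config$enc_channels,
                       model$config$dec_channels,
                       matrix(as.vector(f), ncol = 1),
                       matrix(as.vector(m), ncol = 1), h, w)
  displacement_field(matrix(out[1, ], h, w), matrix(out[2, ], h, w))
}

#' Warp an image with a displacement field (spatial transformer)
#'
#' Bilinear sampling of the moving image at `(i + u_row, j + u_col)`;
#' samples falling outside the image clamp to the border. The zero field
#' reproduces the input exactly, and outputs never leave the intensity range
#' of the input (bilinear convexity). The operation is differentiable in
#' both arguments; see [warp_gradients()].
#'
#' @param moving image matrix to resample.
#' @param field a [displacement_field()] of the same shape.
#' @return the warped image matrix.
#' @export
warp_image <- function(moving, field) {
  m <- as_image_matrix(moving, "moving")
  if (!inherits(field, "displacement_field"))
    stop_mammosub("`field` must be a displacement_field", "bad_input")
  if (!identical(dim(m), dim(field$u_row)))
    stop_mammosub("image and field shapes differ", "shape_mismatch")
  if (nrow(m) < 2 || ncol(m) < 2)
    stop_mammosub("images must be at least 2 x 2", "bad_input")
  if (any(!is.finite(field$u_row)) || any(!is.finite(field$u_col)))
    stop_mammosub("displacement field must be finite", "bad_input")
  cpp_warp_bilinear(m, field$u_row, field$u_col)
}

#' Analytic gradients of the warp
#'
#' Vector-Jacobian product of [warp_image()]: given the upstream gradient of
#' a scalar loss with respect to the warped output, returns the gradients
#' with respect to the moving image and both field components.
#'
#' @param moving image matrix.
#' @param field a [displacement_field()].
#' @param upstream matrix of upstream gradients, same shape.
#' @return list with `d_moving`, `d_u_row`, `d_u_col`.
#' @export
warp_gradients <- function(moving, field, upstream) {
  cpp_warp_vjp(img_matrix(moving), field$u_row, field$u_col,
               img_matrix(upstream))
}

#' Save / load registration model checkpoints
#'
#' A checkpoint is a single weights file (RDS of the parameter vector) plus a
#' YAML sidecar with keys `enc_channels`, `dec_channels`, `trained`.
#'
#' @param model a `registration_model`.
#' @param path weights file path; the sidecar is `<path>.yaml`.
#' @export
save_registration_model <- function(model, path) {
  saveRDS(model$params, path)
  yaml::write_yaml(list(enc_channels = model$config$enc_channels,
                        dec_channels = model$config$dec_channels,
                        trained = model$trained), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_registration_model
#' @export
load_registration_model <- function(path) {
  if (!file.exists(path))
    stop_mammosub(sprintf("weights file not found: '%s'", path),
                  "missing_file")
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  structure(list(params = readRDS(path),
                 config = unet_config(side$enc_channels, side$dec_channels),
                 history = NULL, trained = isTRUE(side$trained)),
            class = "registration_model")
}
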