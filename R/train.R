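#' Training configuration
#'
#' Defaults reproduce the reference schedule: 800 epochs, batch size 32,
#' smoothness weight `lambda = 1`, Adam with initial learning rate 2e-4
#' annealed to zero by cosine annealing over the epochs.
#'
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param lambda_smooth weight of the displacement-smoothness penalty.
#' @param base_lr initial learning rate.
#' @param seed optional integer seed controlling shuffling (and model
#'   initialization when [train_registration()] builds the model itself).
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 800L, batch_size = 32L, lambda_smooth = 1,
                         base_lr = 2e-4, seed = NULL) {
  if (epochs < 1 || batch_size < 1 || lambda_smooth < 0 || base_lr <= 0)
    stop_mammosub("train_config values must be positive", "bad_config")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lambda_smooth = lambda_smooth,
                 base_lr = base_lr, seed = seed),
            class = "train_config")
}

#' Masked mean-squared-error similarity loss
#'
#' Mean over mask pixels of the squared intensity difference between the
#' fixed and warped (transformed) images; the loss region is the breast +
#' pectoralis mask only.
#'
#' @param fixed,warped image matrices of equal shape.
#' @param mask [breast_mask()] or logical matrix; must be nonempty.
#' @return scalar loss.
#' @export
loss_mse <- function(fixed, warped, mask) {
  if (!identical(dim(img_matrix(fixed)), dim(img_matrix(warped))))
    stop_mammosub("`fixed` and `warped` shapes differ", "shape_mismatch")
  sel <- as.logical(mask)
  if (!any(sel)) stop_mammosub("mask is empty", "empty_mask")
  d <- (img_matrix(fixed) - img_matrix(warped))[sel]
  mean(d * d)
}

#' Displacement-smoothness penalty (per-pixel misalignment)
#'
#' Forward-difference spatial gradients of each displacement component in
#' each direction; for each direction the squared gradients of both
#' components are averaged over `2 x (valid positions)`, and the two
#' directional means are summed. Under this normalization a linear field
#' `u_col = c * col` has penalty `c^2 / 2`, and any constant field has
#' penalty zero.
#'
#' @param field a [displacement_field()].
#' @return scalar penalty.
#' @export
loss_smoothness <- function(field) {
  if (!inherits(field, "displacement_field"))
    stop_mammosub("`field` must be a displacement_field", "bad_input")
  ur <- field$u_row; uc <- field$u_col
  h <- nrow(ur); w <- ncol(ur)
  row_term <- if (h > 1) {
    (sum(diff(ur)^2) + sum(diff(uc)^2)) / (2 * (h - 1) * w)
  } else 0
  col_term <- if (w > 1) {
    (sum(t(diff(t(ur)))^2) + sum(t(diff(t(uc)))^2)) / (2 * h * (w - 1))
  } else 0
  row_term + col_term
}

#' Composite registration loss
#'
#' `loss_mse(fixed, warped, mask) + lambda_smooth * loss_smoothness(field)`;
#' additive and exactly linear in `lambda_smooth`.
#'
#' @inheritParams loss_mse
#' @param field the predicted [displacement_field()].
#' @param lambda_smooth smoothness weight (default 1).
#' @return scalar loss.
#' @export
total_loss <- function(fixed, warped, field, mask, lambda_smooth = 1) {
  loss_mse(fixed, warped, mask) + lambda_smooth * loss_smoothness(field)
}

#' Cosine-annealed learning rate
#'
#' `base_lr * (1 + cos(pi * epoch / epochs)) / 2`: the initial rate at epoch
#' 0, half the rate at mid-schedule, zero at the final epoch. No warm
#' restarts.
#'
#' @param epoch epoch index in `[0, epochs]`.
#' @param config a [train_config()].
#' @return the learning rate.
#' @export
cosine_annealed_lr <- function(epoch, config) {
  if (any(epoch < 0) || any(epoch > config$epochs))
    stop_mammosub("`epoch` must lie in [0, epochs]", "bad_input")
  config$base_lr * (1 + cos(pi * epoch / config$epochs)) / 2
}

stack_pairs <- function(pairs, what) {
  do.call(cbind, lapply(pairs, function(p) as.vector(img_matrix(p[[what]]))))
}

#' Train the registration network
#'
#' Unsupervised training: each step predicts a displacement field for a
#' fixed/flipped pair, warps the flipped image with a spatial transformer,
#' and applies Adam to the masked MSE + smoothness loss. The learning rate
#' follows cosine annealing per epoch; per-epoch training and validation
#' losses are logged (the validation pass never updates weights). With a
#' fixed seed the whole run is reproducible on one machine.
#'
#' @param pairs nonempty list of `registration_pair` objects (training set).
#' @param val_pairs list of validation pairs (possibly empty).
#' @param config a [train_config()].
#' @param model optional initialized [init_registration_model()]; created
#'   from `config$seed` when omitted.
#' @return the trained `registration_model`; `$history` is a tibble with one
#'   row per epoch (`epoch`, `train_loss`, `val_loss`, `lr`).
#' @export
train_registration <- function(pairs, val_pairs = list(),
                               config = train_config(), model = NULL) {
  if (length(pairs) == 0)
    stop_mammosub("training set is empty", "bad_input")
  h <- nrow(pairs[[1]]$fixed); w <- ncol(pairs[[1]]$fixed)
  fx <- stack_pairs(pairs, "fixed")
  mv <- stack_pairs(pairs, "moving")
  mk <- stack_pairs(pairs, "mask")
  if (length(val_pairs)) {
    fxv <- stack_pairs(val_pairs, "fixed")
    mvv <- stack_pairs(val_pairs, "moving")
    mkv <- stack_pairs(val_pairs, "mask")
  } else {
    fxv <- mvv <- mkv <- matrix(0, h * w, 0)
  }
  res <- with_seed_if(config$seed, function() {
    mdl <- if (is.null(model)) {
      init_registration_model(seed = NULL)  # draws from the seeded stream
    } else model
    perm <- t(vapply(seq_len(config$epochs),
                     function(e) sample.int(length(pairs)),
                     integer(length(pairs))))
    fit <- cpp_unet_train(mdl$params, mdl$config$enc_channels,
                          mdl$config$dec_channels,
                          fx, mv, mk, fxv, mvv, mkv, h, w,
                          perm, config$epochs, config$batch_size,
                          config$base_lr, config$lambda_smooth)
    list(mdl = mdl, fit = fit)
  })
  out <- res$mdl
  out$params <- res$fit$params
  out$trained <- TRUE
  out$history <- tibble::tibble(epoch = seq_len(config$epochs),
                                train_loss = res$fit$train_loss,
                                val_loss = res$fit$val_loss,
                                lr = res$fit$lr)
  out
}

#' @export
autoplot.registration_model <- function(object, ...) {
  if (is.null(object$history))
    stop_mammosub("model has no training history", "bad_input")
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
tidy.registration_model <- function(x, ...) {
  if (is.null(x$history))
    return(tibble::tibble(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric(), lr = numeric()))
  x$history
}

#' @export
glance.registration_model <- function(x, ...) {
  tibble::tibble(
    n_params = length(x$params),
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_train_loss = if (is.null(x$history)) NA_real_
                       else x$history$train_loss[nrow(x$history)],
    final_val_loss = if (is.null(x$history)) NA_real_
                     else x$history$val_loss[nrow(x$history)])
}
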