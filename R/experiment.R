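#' Per-pixel endpoint error between two displacement fields
#'
#' @param pred,ref [displacement_field()]s of identical shape.
#' @return matrix of Euclidean endpoint errors in pixels.
#' @export
field_endpoint_error <- function(pred, ref) {
  sqrt((pred$u_row - ref$u_row)^2 + (pred$u_col - ref$u_col)^2)
}

#' Erode a mask to its interior
#'
#' @param mask a [breast_mask()].
#' @param radius erosion radius in pixels.
#' @return the eroded [breast_mask()].
#' @export
mask_interior <- function(mask, radius = 4L) {
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  er <- EBImage::erode(EBImage::Image(img_matrix(mask * 1)), brush)
  breast_mask(matrix(as.numeric(er) > 0.5, nrow(mask), ncol(mask)))
}

#' Scaled-down synthetic analog of the bilateral registration experiment
#'
#' Simulates a seeded cohort of bilateral phantoms (default 96 cases at
#' 128 x 128 with 3 px RMS asymmetry), preprocesses them into fixed/flipped
#' pairs, trains the registration network on a reduced schedule (default
#' 150 epochs, batch 8; train/validation/test split 64/8/24 mirrors the
#' clinical 1000/100/500 proportions), and evaluates the held-out test
#' cases: SAD with and without registration, the paired comparison, and
#' deformation recovery against known smooth fields
#' (`moving = warp(fixed, field)`, with the predicted field compared to the
#' numerically inverted generator field inside the eroded mask).
#'
#' @param seed integer seed driving every random component.
#' @param n_cases cohort size.
#' @param image_size image side length (multiple of 16).
#' @param epochs,batch_size training schedule.
#' @param deform_magnitude RMS phantom asymmetry in pixels.
#' @return list with `records` (test-case SAD table), `report`
#'   (subgroup_report), `history` (learning curve), `model`, and
#'   `recovery` (per-case median endpoint error, px).
#' @export
run_scaled_experiment <- function(seed = 1L, n_cases = 96L,
                                  image_size = 128L, epochs = 150L,
                                  batch_size = 8L, deform_magnitude = 3) {
  seed <- as.integer(seed)
  n_train <- max(1L, round(n_cases * 2 / 3))   # 64/8/24 at the default 96
  n_val <- max(1L, round(n_cases / 12))
  n_test <- n_cases - n_train - n_val

  cohort <- generate_cohort(n_cases, image_size = c(image_size, image_size),
                            deform_magnitude = deform_magnitude, seed = seed)
  pairs <- lapply(seq_len(n_cases), function(k) {
    cs <- cohort$cases[[k]]
    preprocess_pair(cs$right_image, cs$left_image, out_size = image_size,
                    case_id = cohort$manifest$case_id[k])
  })
  idx_train <- seq_len(n_train)
  idx_val <- n_train + seq_len(n_val)
  idx_test <- n_train + n_val + seq_len(n_test)

  tc <- train_config(epochs = epochs, batch_size = batch_size,
                     seed = seed + 1L)
  model <- train_registration(pairs[idx_train], pairs[idx_val], tc)

  covs <- tibble::tibble(
    breast_area_pct = cohort$manifest$area_pct_measured[idx_test],
    density_pct = cohort$manifest$density_pct_measured[idx_test],
    thickness_mm = cohort$manifest$thickness_mm[idx_test])
  records <- evaluate_cohort(model, pairs[idx_test], covs)
  report <- compare_and_summarize(records)

  corr <- image_size / 4
  taper <- border_taper(image_size, image_size, taper_width(corr))
  recovery <- purrr::map_dbl(seq_along(idx_test), function(j) {
    k <- idx_test[j]
    fx <- pairs[[k]]$fixed
    g <- smooth_random_field(c(image_size, image_size), deform_magnitude,
                             corr, seed = seed * 1000L + j)
    g <- displacement_field(g$u_row * taper, g$u_col * taper)
    moving <- warp_image(fx, g)
    pred <- predict_displacement(model, fx, moving)
    err <- field_endpoint_error(pred, invert_field(g))
    interior <- img_matrix(mask_interior(pairs[[k]]$mask, 4L))
    stats::median(err[interior > 0.5])
  })

  list(records = records, report = report, history = model$history,
       model = model,
       recovery = tibble::tibble(case_id = records$case_id,
                                 median_epe_px = recovery))
}
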