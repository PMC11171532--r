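#' Specification of a synthetic bilateral MLO phantom
#'
#' The generator emulates the geometry of a mediolateral-oblique mammogram:
#' chest wall along one vertical image edge, a semi-(super)elliptical breast
#' contour with a soft skin-line falloff, a pectoral wedge in the upper
#' posterior corner, and scattered glandular texture built from Gaussian
#' blobs. Bilateral asymmetry is produced by warping the right breast with a
#' known smooth random displacement field before mirroring it into a left
#' image, so every downstream stage can be validated against ground truth.
#'
#' Covariates mirror the clinical ones: percentage breast area of the image,
#' mammary-gland content ratio (glandular coverage of the breast area), and
#' compressed breast thickness, which maps monotonically to global tissue
#' brightness.
#'
#' @param image_height,image_width image size in pixels.
#' @param breast_area_fraction target breast+pectoral area as a fraction of
#'   the image, strictly in (0, 1).
#' @param density_fraction target glandular coverage fraction of the breast
#'   area, strictly in (0, 1).
#' @param thickness_mm simulated compressed breast thickness (mm); larger
#'   values render brighter tissue.
#' @param deform_magnitude RMS displacement (px) of the bilateral asymmetry
#'   field.
#' @param deform_correlation_length correlation length (px) of the asymmetry
#'   field; default `min(image size) / 4`, i.e. smooth, breast-scale
#'   positioning differences.
#' @param texture_blob_count number of glandular texture blobs.
#' @param noise_sd additive Gaussian noise SD on the `[0, 1]` intensity scale.
#' @param seed integer seed; identical specs with the same seed produce
#'   bit-identical phantoms.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(image_height = 512L, image_width = 512L,
                         breast_area_fraction = 0.344,
                         density_fraction = 0.44,
                         thickness_mm = 45.7,
                         deform_magnitude = 3,
                         deform_correlation_length = NULL,
                         texture_blob_count = 40L,
                         noise_sd = 0.01,
                         seed = NULL) {
  if (image_height < 32 || image_width < 32)
    stop_mammosub("image size must be at least 32 x 32", "bad_spec")
  if (!(breast_area_fraction > 0 && breast_area_fraction < 1))
    stop_mammosub("`breast_area_fraction` must lie strictly in (0, 1)",
                  "bad_spec")
  if (!(density_fraction > 0 && density_fraction < 1))
    stop_mammosub("`density_fraction` must lie strictly in (0, 1)", "bad_spec")
  if (deform_magnitude < 0)
    stop_mammosub("`deform_magnitude` must be >= 0", "bad_spec")
  if (texture_blob_count < 0)
    stop_mammosub("`texture_blob_count` must be >= 0", "bad_spec")
  if (noise_sd < 0)
    stop_mammosub("`noise_sd` must be >= 0", "bad_spec")
  if (is.null(deform_correlation_length))
    deform_correlation_length <- min(image_height, image_width) / 4
  if (deform_correlation_length <= 0)
    stop_mammosub("`deform_correlation_length` must be > 0", "bad_spec")
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 breast_area_fraction = breast_area_fraction,
                 density_fraction = density_fraction,
                 thickness_mm = thickness_mm,
                 deform_magnitude = deform_magnitude,
                 deform_correlation_length = deform_correlation_length,
                 texture_blob_count = as.integer(texture_blob_count),
                 noise_sd = noise_sd,
                 seed = seed),
            class = "phantom_spec")
}

#' Smooth zero-mean random displacement field
#'
#' Gaussian-smoothed white noise, recentred to zero mean per component and
#' rescaled so the empirical RMS displacement magnitude equals `magnitude`
#' exactly. The Gaussian kernel SD equals `correlation_length`.
#'
#' @param shape integer vector `c(height, width)` in pixels.
#' @param magnitude target RMS displacement in pixels (>= 0).
#' @param correlation_length Gaussian smoothing SD in pixels (> 0).
#' @param seed optional integer seed.
#' @return a [displacement_field()].
#' @export
smooth_random_field <- function(shape, magnitude, correlation_length,
                                seed = NULL) {
  if (length(shape) != 2 || any(shape < 1))
    stop_mammosub("`shape` must be two positive integers", "bad_input")
  if (magnitude < 0) stop_mammosub("`magnitude` must be >= 0", "bad_input")
  if (correlation_length <= 0)
    stop_mammosub("`correlation_length` must be > 0", "bad_input")
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (magnitude == 0)
    return(displacement_field(matrix(0, h, w), matrix(0, h, w)))
  with_seed_if(seed, function() {
    ur <- cpp_gaussian_blur(matrix(rnorm(h * w), h, w), correlation_length)
    uc <- cpp_gaussian_blur(matrix(rnorm(h * w), h, w), correlation_length)
    ur <- ur - mean(ur)
    uc <- uc - mean(uc)
    rms <- sqrt(mean(ur^2 + uc^2))
    if (rms == 0) rms <- 1
    displacement_field(ur * magnitude / rms, uc * magnitude / rms)
  })
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# half-superellipse area constant: area = se_area_const(p) * rx * ry
se_area_const <- function(p) {
  2 * gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)
}

# solve the breast contour (superellipse exponent p and posterior radius rx)
# for a target pixel area, then refine rx against the rasterized breast +
# pectoral union so requested and realized area fractions agree closely
solve_breast_geometry <- function(h, w, frac) {
  target <- frac * h * w
  ry <- 0.48 * h
  rx_max <- 0.96 * w
  p <- 2
  rx <- target / (se_area_const(2) * ry)
  if (rx > rx_max) {
    need <- target / (rx_max * ry)
    if (need > se_area_const(16))
      stop_mammosub(
        "`breast_area_fraction` incompatible with image size", "bad_spec")
    p <- stats::uniroot(function(q) se_area_const(q) - need,
                        interval = c(2, 16), tol = 1e-8)$root
    rx <- rx_max
  }
  list(p = p, rx = rx, ry = ry)
}

# implicit radial coordinate of the superellipse breast contour; <= 1 inside
breast_radial <- function(h, w, rx, ry, p) {
  x <- (seq_len(w) - 1) / rx
  y <- abs(seq_len(h) - 1 - (h - 1) / 2) / ry
  (outer(y^p, x^p, `+`))^(1 / p)
}

# pectoral wedge pseudo-radial coordinate (triangle from the upper posterior
# corner); <= 1 inside
wedge_radial <- function(h, w) {
  ww <- 0.35 * w
  hw <- 0.55 * h
  outer((seq_len(h) - 1) / hw, (seq_len(w) - 1) / ww, `+`)
}

# Gaussian blob field used for glandular texture
blob_field <- function(h, w, n, sigma_range, inside) {
  g <- matrix(0, h, w)
  if (n == 0) return(g)
  ij <- which(inside, arr.ind = TRUE)
  if (nrow(ij) == 0) return(g)
  picks <- ij[sample.int(nrow(ij), n, replace = TRUE), , drop = FALSE]
  sig <- runif(n, sigma_range[1], sigma_range[2])
  amp <- runif(n, 0.5, 1)
  for (k in seq_len(n)) {
    ci <- picks[k, 1]; cj <- picks[k, 2]; s <- sig[k]
    r <- ceiling(3 * s)
    i0 <- max(1, ci - r); i1 <- min(h, ci + r)
    j0 <- max(1, cj - r); j1 <- min(w, cj + r)
    di <- (i0:i1) - ci
    dj <- (j0:j1) - cj
    g[i0:i1, j0:j1] <- g[i0:i1, j0:j1] +
      amp[k] * outer(exp(-di^2 / (2 * s^2)), exp(-dj^2 / (2 * s^2)))
  }
  g
}

# displacement taper to zero at the image borders so the chest wall stays
# put; the smoothstep ramp spans half the field's correlation length so the
# taper never makes the field rougher than the field itself
border_taper <- function(h, w, taper_px) {
  di <- pmin(seq_len(h) - 1, h - seq_len(h))
  dj <- pmin(seq_len(w) - 1, w - seq_len(w))
  smoothstep(outer(pmin(di / taper_px, 1), pmin(dj / taper_px, 1), pmin))
}

taper_width <- function(correlation_length) {
  max(8, round(correlation_length / 2))
}

# invert g to the field phi with warp(warp(img, g), phi) ~ img, by the
# fixed-point iteration phi <- -g(x + phi(x))
invert_field <- function(g, iters = 6) {
  phi_r <- -g$u_row
  phi_c <- -g$u_col
  for (k in seq_len(iters)) {
    gr <- cpp_warp_bilinear(g$u_row, phi_r, phi_c)
    gc <- cpp_warp_bilinear(g$u_col, phi_r, phi_c)
    phi_r <- -gr
    phi_c <- -gc
  }
  displacement_field(phi_r, phi_c)
}

#' Generate one bilateral phantom case
#'
#' Builds the right-breast image from contour, pectoral wedge, glandular
#' blobs, and skin-line falloff; the left image is the horizontal mirror of
#' the right warped by a known smooth random field, plus an independent
#' glandular perturbation (amplitude `2 * noise_sd`) and independent pixel
#' noise. `true_field` maps the flipped-left grid onto the right image: it is
#' the (numerically inverted) negative of the generating warp, so that
#' `warp_image(flipped_left, true_field)` realigns the pair.
#'
#' With `deform_magnitude = 0` and `noise_sd = 0` the flipped left image
#' equals the right image bit for bit.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_case`: list with `right_image`, `left_image`,
#'   `true_field`, `right_mask`, `left_mask`, `gland_mask`, and a one-row
#'   `covariates` tibble (measured `breast_area_pct`, `density_pct`,
#'   `thickness_mm`).
#' @export
generate_bilateral_case <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop_mammosub("`spec` must be a phantom_spec", "bad_input")
  with_seed_if(spec$seed, function() generate_case_impl(spec))
}

generate_case_impl <- function(spec) {
  h <- spec$image_height; w <- spec$image_width
  geom <- solve_breast_geometry(h, w, spec$breast_area_fraction)
  rw <- wedge_radial(h, w)

  # refine rx so the rasterized breast+wedge union hits the requested area
  # the ground-truth mask is the tissue support: the contour shrunk by the
  # ~1 px ring where the skin-line ramp falls below the visibility floor
  wedge_shrink <- 1 - 1 / min(0.35 * w, 0.55 * h)
  target <- spec$breast_area_fraction * h * w
  lo <- 0.7 * geom$rx; hi <- min(1.3 * geom$rx, 0.995 * w)
  rx <- geom$rx
  for (k in 1:14) {
    rad <- breast_radial(h, w, rx, geom$ry, geom$p)
    got <- sum(rad <= 1 - 1 / min(rx, geom$ry) | rw <= wedge_shrink)
    if (abs(got - target) / (h * w) < 0.002) break
    if (got < target) lo <- rx else hi <- rx
    rx <- (lo + hi) / 2
  }
  rad <- breast_radial(h, w, rx, geom$ry, geom$p)
  mask <- rad <= 1 - 1 / min(rx, geom$ry) | rw <= wedge_shrink

  wpx <- max(3, 0.015 * w)
  minr <- min(rx, geom$ry)
  edge <- smoothstep((1 - rad) * minr / wpx)
  edge_w <- smoothstep((1 - rw) * min(0.35 * w, 0.55 * h) / wpx)
  # visible skin line: a sharp ~2 px ramp to an intensity floor at the
  # contour keeps the breast boundary detectable at any thickness
  skin <- 0.10 * pmax(smoothstep((1 - rad) * minr / 2),
                      smoothstep((1 - rw) * min(0.35 * w, 0.55 * h) / 2))

  s_thick <- 0.30 + 0.35 * pmin(pmax((spec$thickness_mm - 12) / 72, 0), 1)

  gland_src <- blob_field(h, w, spec$texture_blob_count,
                          c(w / 40, w / 14), rad <= 0.75)
  gv <- gland_src[mask]
  thr <- stats::quantile(gv, 1 - spec$density_fraction, names = FALSE,
                         type = 7)
  gland_mask <- (gland_src >= thr) & mask
  qhi <- stats::quantile(gv, 0.98, names = FALSE)
  tex <- 0.25 * smoothstep((gland_src - thr) / (0.5 * (qhi - thr) + 1e-9))

  right_clean <- pmin(pmax(
    pmax((s_thick - 0.10) * pmax(edge, edge_w) + skin, s_thick * edge_w) +
      0.18 * edge_w + tex * edge, 0), 0.98)

  # asymmetry warp, tapered to zero at the image borders
  g <- smooth_random_field(c(h, w), spec$deform_magnitude,
                           spec$deform_correlation_length, seed = NULL)
  taper <- border_taper(h, w, taper_width(spec$deform_correlation_length))
  g <- displacement_field(g$u_row * taper, g$u_col * taper)

  flipped_left <- cpp_warp_bilinear(right_clean, g$u_row, g$u_col)
  left_mask_flipped <- cpp_warp_bilinear(mask * 1, g$u_row, g$u_col) > 0.5
  true_field <- if (spec$deform_magnitude == 0) {
    displacement_field(matrix(0, h, w), matrix(0, h, w))
  } else {
    invert_field(g)
  }

  # independent glandular perturbation on the left side only
  pert_amp <- 2 * spec$noise_sd
  if (pert_amp > 0) {
    pert <- blob_field(h, w, max(3L, spec$texture_blob_count %/% 4L),
                       c(w / 30, w / 12), rad <= 0.75)
    pmax_val <- max(pert)
    if (pmax_val > 0)
      flipped_left <- flipped_left +
        pert_amp * (pert / pmax_val) * left_mask_flipped
  }
  if (spec$noise_sd > 0) {
    right_final <- pmin(pmax(
      right_clean + matrix(rnorm(h * w, 0, spec$noise_sd), h, w), 0), 1)
    flipped_left <- pmin(pmax(
      flipped_left + matrix(rnorm(h * w, 0, spec$noise_sd), h, w), 0), 1)
  } else {
    right_final <- right_clean
  }

  pitch <- 85 * 2816 / h  # full-field pitch scaled to the phantom grid
  covs <- tibble::tibble(breast_area_pct = 100 * mean(mask),
                         density_pct = 100 * sum(gland_mask) / sum(mask),
                         thickness_mm = spec$thickness_mm)
  structure(list(
    right_image = mammogram_image(right_final, "R",
                                  pixel_pitch_um = pitch,
                                  thickness_mm = spec$thickness_mm,
                                  normalized = TRUE),
    left_image = mammogram_image(flip_horizontal(flipped_left), "L",
                                 pixel_pitch_um = pitch,
                                 thickness_mm = spec$thickness_mm,
                                 normalized = TRUE),
    true_field = true_field,
    right_mask = breast_mask(mask),
    left_mask = breast_mask(flip_horizontal(left_mask_flipped)),
    gland_mask = breast_mask(gland_mask),
    covariates = covs,
    spec = spec), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(
    "<phantom_case> %d x %d; area %.1f%%, density %.1f%%, thickness %.0f mm, deform RMS %.2f px\n",
    nrow(x$right_image), ncol(x$right_image),
    x$covariates$breast_area_pct, x$covariates$density_pct,
    x$covariates$thickness_mm, field_rms(x$true_field)))
  invisible(x)
}

#' Default covariate sampling ranges for synthetic cohorts
#'
#' One row per covariate with the admissible `[min, max]` interval and the
#' centre/spread of the truncated-normal sampler. Defaults follow the
#' distribution of a screening test population: breast area 34.4 +/- 10.7%
#' within \[11.1, 79.8\], gland content 44.0 +/- 16.0% within \[11.5, 85.0\],
#' compressed thickness 45.7 +/- 13.6 mm within \[12, 84\].
#'
#' @return a tibble with columns `covariate`, `min`, `max`, `mean`, `sd`.
#' @export
default_covariate_ranges <- function() {
  tibble::tribble(
    ~covariate,         ~min,  ~max,  ~mean, ~sd,
    "breast_area_pct",  11.1,  79.8,  34.4,  10.7,
    "density_pct",      11.5,  85.0,  44.0,  16.0,
    "thickness_mm",     12,    84,    45.7,  13.6)
}

sample_truncated <- function(n, min, max, mean, sd) {
  if (!is.finite(min) || !is.finite(max) || min >= max)
    stop_mammosub("empty covariate range", "bad_range")
  if (!is.finite(mean) || !is.finite(sd) || sd <= 0)
    return(runif(n, min, max))
  out <- numeric(0)
  while (length(out) < n) {
    cand <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, cand[cand >= min & cand <= max])
  }
  out[seq_len(n)]
}

#' Generate a cohort of bilateral phantom cases
#'
#' Samples per-case covariates from truncated normal distributions inside the
#' configured ranges, then generates each case with its own derived seed.
#'
#' @param n number of cases (>= 1).
#' @param covariate_ranges tibble as returned by
#'   [default_covariate_ranges()]; `mean`/`sd` may be `NA` for uniform
#'   sampling.
#' @param image_size integer `c(height, width)` for all cases.
#' @param deform_magnitude,deform_correlation_length,texture_blob_count,noise_sd
#'   passed to [phantom_spec()] for every case.
#' @param seed integer seed; the same seed reproduces the identical cohort
#'   and manifest.
#' @return list with `cases` (list of `phantom_case`) and `manifest`
#'   (tibble: `case_id`, `right_path`, `left_path`, `thickness_mm`,
#'   `area_pct`, `density_pct` as sampled, plus measured
#'   `area_pct_measured`, `density_pct_measured`).
#' @export
generate_cohort <- function(n, covariate_ranges = default_covariate_ranges(),
                            image_size = c(512L, 512L),
                            deform_magnitude = 3,
                            deform_correlation_length = NULL,
                            texture_blob_count = 40L,
                            noise_sd = 0.01,
                            seed = NULL) {
  if (n < 1) stop_mammosub("`n` must be >= 1", "bad_input")
  cr <- covariate_ranges
  need <- c("breast_area_pct", "density_pct", "thickness_mm")
  if (!all(need %in% cr$covariate))
    stop_mammosub("covariate_ranges must cover breast_area_pct, density_pct, thickness_mm",
                  "bad_range")
  with_seed_if(seed, function() {
    draw <- function(name) {
      r <- cr[cr$covariate == name, ]
      sample_truncated(n, r$min, r$max, r$mean, r$sd)
    }
    area <- draw("breast_area_pct")
    dens <- draw("density_pct")
    thick <- draw("thickness_mm")
    case_seeds <- sample.int(.Machine$integer.max - 1L, n)
    cases <- vector("list", n)
    for (k in seq_len(n)) {
      spec <- phantom_spec(
        image_height = image_size[1], image_width = image_size[2],
        breast_area_fraction = area[k] / 100,
        density_fraction = dens[k] / 100,
        thickness_mm = thick[k],
        deform_magnitude = deform_magnitude,
        deform_correlation_length = deform_correlation_length,
        texture_blob_count = texture_blob_count,
        noise_sd = noise_sd,
        seed = case_seeds[k])
      cases[[k]] <- generate_bilateral_case(spec)
    }
    manifest <- tibble::tibble(
      case_id = sprintf("case_%04d", seq_len(n)),
      right_path = NA_character_,
      left_path = NA_character_,
      thickness_mm = thick,
      area_pct = area,
      density_pct = dens,
      area_pct_measured =
        purrr::map_dbl(cases, ~ .x$covariates$breast_area_pct),
      density_pct_measured =
        purrr::map_dbl(cases, ~ .x$covariates$density_pct))
    list(cases = cases, manifest = manifest)
  })
}

#' Insert a synthetic mass-like lesion
#'
#' Adds a radially symmetric raised-cosine bright disc:
#' `amplitude * cos(pi * d / (2 * radius))^2` for distance `d < radius`, so
#' the intensity increase at the centre equals `amplitude` exactly and pixels
#' outside the disc are untouched.
#'
#' @param image a [mammogram_image()] or matrix.
#' @param mask [breast_mask()] of the same shape; the centre must lie inside.
#' @param center integer `c(row, col)` of the lesion centre.
#' @param radius lesion radius in pixels (>= 0).
#' @param amplitude added intensity at the centre.
#' @return the image with the lesion added (attributes preserved).
#' @export
insert_lesion <- function(image, mask, center, radius, amplitude) {
  h <- nrow(image); w <- ncol(image)
  if (length(center) != 2 || center[1] < 1 || center[1] > h ||
      center[2] < 1 || center[2] > w)
    stop_mammosub("`center` must be c(row, col) inside the image", "bad_input")
  if (!mask[center[1], center[2]])
    stop_mammosub("lesion center lies outside the breast mask", "bad_input")
  if (radius < 0) stop_mammosub("`radius` must be >= 0", "bad_input")
  if (radius == 0) return(image)
  out <- image
  r <- ceiling(radius)
  i0 <- max(1, center[1] - r); i1 <- min(h, center[1] + r)
  j0 <- max(1, center[2] - r); j1 <- min(w, center[2] + r)
  di <- (i0:i1) - center[1]
  dj <- (j0:j1) - center[2]
  d <- sqrt(outer(di^2, dj^2, `+`))
  bump <- ifelse(d < radius, amplitude * cos(pi * d / (2 * radius))^2, 0)
  out[i0:i1, j0:j1] <- out[i0:i1, j0:j1] + bump
  out
}
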