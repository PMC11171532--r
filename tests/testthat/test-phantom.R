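test_that("smooth random fields are deterministic, zero-mean, and hit the target RMS", {
  f1 <- smooth_random_field(c(64, 64), 3, 16, seed = 5)
  f2 <- smooth_random_field(c(64, 64), 3, 16, seed = 5)
  expect_identical(f1, f2)

  f0 <- smooth_random_field(c(32, 48), 0, 8, seed = 1)
  expect_true(all(f0$u_row == 0) && all(f0$u_col == 0))

  rms <- vapply(1:10, function(s)
    field_rms(smooth_random_field(c(64, 64), 3, 16, seed = s)), numeric(1))
  expect_lt(abs(mean(rms) - 3) / 3, 0.2)
  expect_lt(abs(mean(smooth_random_field(c(64, 64), 2, 16, seed = 3)$u_row)),
            1e-10)

  expect_error(smooth_random_field(c(0, 64), 1, 8), "positive")
  expect_error(smooth_random_field(c(64, 64), 1, 0), "correlation_length")
})

test_that("bilateral cases are deterministic and exactly symmetric in the degenerate limit", {
  sp <- phantom_spec(image_height = 96, image_width = 96, seed = 7)
  c1 <- generate_bilateral_case(sp)
  c2 <- generate_bilateral_case(sp)
  expect_identical(c1$right_image, c2$right_image)
  expect_identical(c1$left_image, c2$left_image)
  expect_identical(c1$true_field, c2$true_field)

  sp0 <- phantom_spec(image_height = 96, image_width = 96,
                      deform_magnitude = 0, noise_sd = 0, seed = 3)
  c0 <- generate_bilateral_case(sp0)
  expect_equal(dim(c0$left_image), dim(c0$right_image))
  expect_identical(unclass(flip_horizontal(c0$left_image))[, ],
                   unclass(c0$right_image)[, ])
})

test_that("requested covariates are realized within tolerance", {
  for (dens in c(0.25, 0.65)) {
    sp <- phantom_spec(image_height = 192, image_width = 192,
                       density_fraction = dens, seed = 11)
    cs <- generate_bilateral_case(sp)
    expect_lt(abs(cs$covariates$density_pct / 100 - dens), 0.05)
  }
  errs <- vapply(1:50, function(k) {
    f <- withr::with_seed(k, runif(1, 0.12, 0.75))
    sp <- phantom_spec(image_height = 96, image_width = 96,
                       breast_area_fraction = f, seed = 500 + k)
    generate_bilateral_case(sp)$covariates$breast_area_pct / 100 - f
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.03)
})

test_that("masks are single connected components touching the chest-wall edge", {
  for (k in 1:5) {
    sp <- phantom_spec(image_height = 96, image_width = 96,
                       breast_area_fraction = withr::with_seed(k, runif(1, 0.15, 0.7)),
                       seed = k)
    cs <- generate_bilateral_case(sp)
    m <- unclass(cs$right_mask)[, ]
    lab <- EBImage::bwlabel(EBImage::Image(m * 1))
    expect_equal(max(lab), 1)
    expect_true(any(m[, 1]))          # right breast: chest wall at column 1
    expect_false(any(m[, ncol(m)]))
    ml <- unclass(cs$left_mask)[, ]
    expect_true(any(ml[, ncol(ml)]))  # left breast: chest wall at last column
  }
})

test_that("infeasible breast area errors", {
  expect_error(generate_bilateral_case(
    phantom_spec(image_height = 96, image_width = 96,
                 breast_area_fraction = 0.97, seed = 1)),
    "incompatible")
})

test_that("the ground-truth field realigns the flipped left onto the right image", {
  sp <- phantom_spec(image_height = 128, image_width = 128, noise_sd = 0,
                     seed = 21)
  cs <- generate_bilateral_case(sp)
  flipped <- unclass(flip_horizontal(cs$left_image))[, ]
  realigned <- warp_image(flipped, cs$true_field)
  right <- unclass(cs$right_image)[, ]
  resid <- sad(realigned, right, cs$right_mask)
  raw <- sad(flipped, right, cs$right_mask)
  expect_lt(resid, 0.25 * raw)  # most of the asymmetry is explained
})

test_that("cohorts sample covariates inside the configured ranges, reproducibly", {
  ch <- generate_cohort(40, image_size = c(64, 64), seed = 9)
  expect_equal(nrow(ch$manifest), 40)
  expect_equal(length(ch$cases), 40)
  expect_true(all(ch$manifest$area_pct >= 11.1 & ch$manifest$area_pct <= 79.8))
  expect_true(all(ch$manifest$density_pct >= 11.5 &
                  ch$manifest$density_pct <= 85))
  expect_true(all(ch$manifest$thickness_mm >= 12 &
                  ch$manifest$thickness_mm <= 84))
  ch2 <- generate_cohort(40, image_size = c(64, 64), seed = 9)
  expect_identical(ch$manifest, ch2$manifest)

  bad <- default_covariate_ranges()
  bad$min[1] <- bad$max[1]
  expect_error(generate_cohort(5, covariate_ranges = bad,
                               image_size = c(64, 64), seed = 1),
               "empty")
})

test_that("lesion insertion is local, exact at the centre, and validated", {
  sp <- phantom_spec(image_height = 96, image_width = 96, noise_sd = 0,
                     seed = 13)
  cs <- generate_bilateral_case(sp)
  img <- cs$right_image
  ctr <- c(40, 30)
  expect_true(cs$right_mask[ctr[1], ctr[2]])

  expect_identical(insert_lesion(img, cs$right_mask, ctr, 0, 0.2), img)

  les <- insert_lesion(img, cs$right_mask, ctr, 8, 0.2)
  expect_equal(les[ctr[1], ctr[2]] - img[ctr[1], ctr[2]], 0.2)
  d <- abs(unclass(les)[, ] - unclass(img)[, ])
  far <- matrix(TRUE, 96, 96)
  far[(ctr[1] - 9):(ctr[1] + 9), (ctr[2] - 9):(ctr[2] + 9)] <- FALSE
  expect_true(all(d[far] == 0))

  expect_error(insert_lesion(img, cs$right_mask, c(2, 95), 4, 0.2),
               "outside")

  # a one-sided lesion dominates the local difference image
  flipped <- flip_horizontal(cs$left_image)
  diff <- abs(unclass(les)[, ] - unclass(flipped)[, ])
  inside <- !far & unclass(cs$right_mask)[, ]
  outside <- far & unclass(cs$right_mask)[, ]
  expect_gt(mean(diff[inside]), mean(abs(unclass(img)[, ] -
                                         unclass(flipped)[, ])[outside]))
})
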