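test_that("intensity normalization scales by the full bit-depth range", {
  z <- mammogram_image(matrix(0, 4, 4), "R")
  expect_true(all(normalize_intensity(z) == 0))

  m <- mammogram_image(matrix(c(0, 32768, 65535, 100), 2, 2), "R")
  n <- normalize_intensity(m)
  expect_equal(n[2, 1], 32768 / 65535)
  expect_equal(n[1, 2], 1)
  expect_true(isTRUE(attr(n, "normalized")))
  expect_identical(normalize_intensity(n), n)

  expect_error(normalize_intensity(mammogram_image(matrix(-1, 2, 2), "R",
                                                   normalized = TRUE)),
               "non-negative")
})

test_that("breast masks match generator ground truth and satisfy the geometry contract", {
  for (k in 1:3) {
    sp <- phantom_spec(image_height = 128, image_width = 128,
                       thickness_mm = c(20, 46, 75)[k], seed = 30 + k)
    cs <- generate_bilateral_case(sp)
    dm <- detect_breast_mask(cs$right_image)
    expect_gte(dice_coef(unclass(dm)[, ], unclass(cs$right_mask)[, ]), 0.98)
    lab <- EBImage::bwlabel(EBImage::Image(unclass(dm)[, ] * 1))
    expect_equal(max(lab), 1)
    expect_true(any(unclass(dm)[, 1]))
  }
  expect_error(detect_breast_mask(mammogram_image(matrix(0, 32, 32), "R",
                                                  normalized = TRUE)),
               "no breast")
})

test_that("the geometric chain pads only the nipple side and lands on the target size", {
  # full-resolution clinical geometry: 2016 wide x 2816 tall
  x <- matrix(0, 2816, 2016)
  x[, 1:1000] <- 0.5  # tissue block against the chest wall (column 1)
  img <- mammogram_image(x, "R", normalized = TRUE)
  msk <- breast_mask(x > 0.1)
  out <- preprocess_single(img, msk, out_size = 512L)
  expect_equal(dim(out$image), c(512L, 512L))
  expect_equal(dim(out$mask), c(512L, 512L))
  # padded nipple-side columns are background
  expect_true(all(out$image[, 500:512] == 0))
  expect_true(any(out$image[, 1:5] > 0.4))

  # square input: no padding, resize + crop only
  sq <- mammogram_image(matrix(0.25, 400, 400), "L", normalized = TRUE)
  sq_out <- preprocess_single(sq, breast_mask(matrix(TRUE, 400, 400)),
                              out_size = 128L)
  expect_equal(dim(sq_out$image), c(128L, 128L))
  expect_true(all(abs(sq_out$image - 0.25) < 1e-6))

  wide <- mammogram_image(matrix(0.3, 100, 200), "R", normalized = TRUE)
  expect_error(preprocess_single(wide, breast_mask(matrix(TRUE, 100, 200))),
               "wider than tall")
})

test_that("the chain preserves aspect ratio: a circle stays a circle", {
  n <- 400
  x <- outer(seq_len(n) - 170, seq_len(n) - 140,
             function(a, b) sqrt(a^2 + b^2)) < 90
  img <- mammogram_image(x * 0.8, "R", normalized = TRUE)
  out <- preprocess_single(img, breast_mask(matrix(TRUE, n, n)),
                           out_size = 128L)
  # intensity-weighted second moments (binary thresholding adds aliasing
  # noise that would dominate the eccentricity estimate)
  wgt <- as.vector(out$image)
  ij <- as.matrix(expand.grid(row = seq_len(128), col = seq_len(128)))
  mu <- colSums(ij * wgt) / sum(wgt)
  ctr <- sweep(ij, 2, mu)
  cov <- t(ctr * wgt) %*% ctr / sum(wgt)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  ecc <- sqrt(1 - ev[2] / ev[1])
  expect_lt(ecc, 0.05)
})

test_that("horizontal flipping is an exact involution", {
  x <- mammogram_image(matrix(withr::with_seed(6, runif(30 * 20)), 30, 20),
                       "L", normalized = TRUE)
  expect_identical(flip_horizontal(flip_horizontal(x)), x)
})

test_that("pairs are validated, deterministic, and symmetric pairs have zero SAD", {
  sp0 <- phantom_spec(image_height = 96, image_width = 96,
                      deform_magnitude = 0, noise_sd = 0, seed = 40)
  c0 <- generate_bilateral_case(sp0)
  pr <- preprocess_pair(c0$right_image, c0$left_image, out_size = 96L)
  expect_equal(dim(pr$fixed), c(96L, 96L))
  expect_equal(dim(pr$moving), c(96L, 96L))
  expect_equal(sad(pr$fixed, pr$moving, pr$mask), 0)
  pr2 <- preprocess_pair(c0$right_image, c0$left_image, out_size = 96L)
  expect_identical(pr$fixed, pr2$fixed)
  expect_identical(pr$moving, pr2$moving)
  expect_identical(unclass(pr$mask), unclass(pr2$mask))

  expect_error(preprocess_pair(c0$right_image, c0$right_image), "laterality")
})
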