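test_that("losses match the degenerate closed forms", {
  f <- matrix(withr::with_seed(11, runif(36)), 6, 6)
  full <- matrix(TRUE, 6, 6)
  expect_equal(loss_mse(f, f, full), 0)
  expect_equal(loss_mse(matrix(1, 4, 4), matrix(0, 4, 4),
                        matrix(TRUE, 4, 4)), 1)
  expect_error(loss_mse(f, f, matrix(FALSE, 6, 6)), "empty")

  zero <- displacement_field(matrix(0, 6, 6), matrix(0, 6, 6))
  expect_equal(loss_smoothness(zero), 0)
  const <- displacement_field(matrix(2.5, 6, 6), matrix(-1, 6, 6))
  expect_equal(loss_smoothness(const), 0)

  # linear field u_col = c * (column index) has penalty c^2 / 2
  for (cc in c(0.5, -1.25)) {
    lin <- displacement_field(matrix(0, 8, 8),
                              matrix(rep(cc * (0:7), each = 8), 8, 8))
    expect_equal(loss_smoothness(lin), cc^2 / 2)
  }
})

test_that("total loss is additive and exactly linear in lambda", {
  withr::with_seed(12, {
    f <- matrix(runif(64), 8, 8)
    w <- matrix(runif(64), 8, 8)
    fld <- displacement_field(matrix(rnorm(64), 8, 8),
                              matrix(rnorm(64), 8, 8))
    msk <- matrix(runif(64) > 0.3, 8, 8)
  })
  expect_equal(total_loss(f, w, fld, msk, 0), loss_mse(f, w, msk))
  expect_equal(total_loss(f, w, fld, msk, 1),
               loss_mse(f, w, msk) + loss_smoothness(fld))
  s1 <- total_loss(f, w, fld, msk, 1) - loss_mse(f, w, msk)
  s2 <- total_loss(f, w, fld, msk, 2) - loss_mse(f, w, msk)
  expect_equal(s2, 2 * s1)
  zero <- displacement_field(matrix(0, 8, 8), matrix(0, 8, 8))
  expect_identical(total_loss(f, w, zero, msk, 1), loss_mse(f, w, msk))
})

test_that("the cosine schedule hits its endpoints and midpoint", {
  tc <- train_config(epochs = 800L)
  expect_equal(cosine_annealed_lr(0, tc), 2e-4)
  expect_equal(cosine_annealed_lr(800, tc), 0)
  expect_equal(cosine_annealed_lr(400, tc), 1e-4)
  expect_error(cosine_annealed_lr(801, tc), "epochs")
})

test_that("vectorized losses agree with brute-force loops to 1e-12", {
  withr::with_seed(13, {
    for (rep in 1:25) {
      f <- matrix(runif(64), 8, 8)
      w <- matrix(runif(64), 8, 8)
      ur <- matrix(rnorm(64), 8, 8)
      uc <- matrix(rnorm(64), 8, 8)
      msk <- matrix(runif(64) > 0.4, 8, 8)
      if (!any(msk)) msk[1, 1] <- TRUE
      fld <- displacement_field(ur, uc)
      expect_lt(abs(loss_mse(f, w, msk) - brute_mse(f, w, msk)), 1e-12)
      expect_lt(abs(loss_smoothness(fld) - brute_smoothness(ur, uc)), 1e-12)
      expect_lt(abs(total_loss(f, w, fld, msk, 1.7) -
                    (brute_mse(f, w, msk) + 1.7 * brute_smoothness(ur, uc))),
                1e-12)
      expect_lt(abs(sad(f, w, msk) - brute_sad(f, w, msk)), 1e-12)
    }
  })
})

make_training_pairs <- function(n, size, deform, seed) {
  lapply(seq_len(n), function(k) {
    sp <- phantom_spec(image_height = size, image_width = size,
                       deform_magnitude = deform, noise_sd = 0.005,
                       texture_blob_count = 15L, seed = seed + k)
    cs <- generate_bilateral_case(sp)
    raw_pair(unclass(cs$right_image)[, ],
             unclass(flip_horizontal(cs$left_image))[, ],
             unclass(cs$right_mask)[, ], sprintf("c%02d", k))
  })
}

test_that("short training runs reduce the loss, reproducibly, without touching weights in validation", {
  pairs <- make_training_pairs(8, 32L, deform = 2, seed = 100)
  tc <- train_config(epochs = 12L, batch_size = 4L, seed = 5)
  m1 <- train_registration(pairs[1:6], pairs[7:8], tc)
  expect_equal(nrow(m1$history), 12L)
  expect_lt(m1$history$train_loss[12], m1$history$train_loss[1])
  expect_true(all(is.finite(m1$history$val_loss)))

  m2 <- train_registration(pairs[1:6], pairs[7:8], tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  # validation-only data cannot influence the fit: swap the validation set
  m3 <- train_registration(pairs[1:6], pairs[8], tc)
  expect_identical(m1$params, m3$params)

  expect_error(train_registration(list(), list(), tc), "empty")
})

test_that("training on identical pairs keeps the field near zero", {
  pairs <- make_training_pairs(4, 32L, deform = 0, seed = 200)
  pairs <- lapply(pairs, function(p) { p$moving <- p$fixed; p })
  tc <- train_config(epochs = 15L, batch_size = 4L, seed = 6)
  mdl <- train_registration(pairs, list(), tc)
  f <- predict_displacement(mdl, pairs[[1]]$fixed, pairs[[1]]$moving)
  msk <- as.logical(pairs[[1]]$mask)
  mean_mag <- mean(sqrt(f$u_row^2 + f$u_col^2)[msk])
  expect_lt(mean_mag, 0.2)
})
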