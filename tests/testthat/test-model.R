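test_that("predicted fields honor the shape contract and determinism", {
  mdl <- init_registration_model(seed = 1)
  fx <- matrix(withr::with_seed(1, runif(64 * 64)), 64, 64)
  mv <- matrix(withr::with_seed(2, runif(64 * 64)), 64, 64)
  f1 <- predict_displacement(mdl, fx, mv)
  expect_s3_class(f1, "displacement_field")
  expect_equal(dim(f1$u_row), c(64L, 64L))
  expect_equal(dim(f1$u_col), c(64L, 64L))
  f2 <- predict_displacement(mdl, fx, mv)
  expect_identical(f1, f2)
  expect_error(predict_displacement(mdl, fx, mv[1:32, ]), "shape")
})

test_that("zero-initialized flow head yields the exact zero field", {
  mdl <- init_registration_model(seed = 3)
  fx <- matrix(withr::with_seed(3, runif(32 * 32)), 32, 32)
  mv <- matrix(withr::with_seed(4, runif(32 * 32)), 32, 32)
  f <- predict_displacement(mdl, fx, mv)
  expect_true(all(f$u_row == 0) && all(f$u_col == 0))
})

test_that("warping reproduces identity, integer shifts, and bilinear midpoints", {
  m <- matrix(withr::with_seed(5, runif(12 * 12)), 12, 12)
  zero <- displacement_field(matrix(0, 12, 12), matrix(0, 12, 12))
  expect_identical(warp_image(m, zero), m)

  # constant shift of one column: out(i, j) = m(i, j + 1)
  shift <- displacement_field(matrix(0, 12, 12), matrix(1, 12, 12))
  out <- warp_image(m, shift)
  expect_equal(out[, 1:11], m[, 2:12])

  half <- displacement_field(matrix(0, 2, 2), matrix(c(0.5, 0.5, 0, 0), 2, 2))
  mm <- matrix(c(0, 0, 1, 1), 2, 2)  # adjacent pixels 0 then 1 along a row
  expect_equal(warp_image(mm, half)[1, 1], 0.5)
})

test_that("warp is range-bounded and linear in the image", {
  m <- matrix(withr::with_seed(7, runif(20 * 20)), 20, 20)
  f <- smooth_random_field(c(20, 20), 4, 5, seed = 8)
  out <- warp_image(m, f)
  expect_gte(min(out), min(m))
  expect_lte(max(out), max(m))
  expect_equal(warp_image(3 * m, f), 3 * out)
  bad <- displacement_field(matrix(0, 20, 20), matrix(0, 20, 20))
  bad$u_row[1, 1] <- Inf
  expect_error(warp_image(m, bad), "finite")
})

test_that("analytic warp gradients match finite differences", {
  set.seed(9)
  n <- 5
  m <- matrix(runif(n * n), n, n)
  ur <- matrix(runif(n * n, 0.2, 0.4), n, n)
  uc <- matrix(runif(n * n, 0.2, 0.4), n, n)
  up <- matrix(runif(n * n), n, n)
  loss <- function(mv, a, b) sum(up * warp_image(mv, displacement_field(a, b)))
  g <- warp_gradients(m, displacement_field(ur, uc), up)
  eps <- 1e-6
  for (idx in sample(n * n, 6)) {
    for (comp in c("m", "ur", "uc")) {
      plus <- list(m = m, ur = ur, uc = uc)
      minus <- list(m = m, ur = ur, uc = uc)
      plus[[comp]][idx] <- plus[[comp]][idx] + eps
      minus[[comp]][idx] <- minus[[comp]][idx] - eps
      fd <- (loss(plus$m, plus$ur, plus$uc) -
             loss(minus$m, minus$ur, minus$uc)) / (2 * eps)
      an <- switch(comp, m = g$d_moving[idx], ur = g$d_u_row[idx],
                   uc = g$d_u_col[idx])
      denom <- max(abs(fd), abs(an), 1e-8)
      expect_lt(abs(fd - an) / denom, 1e-4)
    }
  }
})

test_that("model checkpoints round-trip through the weights file + sidecar", {
  mdl <- init_registration_model(seed = 10)
  path <- withr::local_tempfile(fileext = ".rds")
  save_registration_model(mdl, path)
  back <- load_registration_model(path)
  expect_identical(back$params, mdl$params)
  expect_identical(back$config, mdl$config)
  expect_error(load_registration_model("nope.rds"), "nope.rds")
})
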