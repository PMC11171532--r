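test_that("SAD matches hand arithmetic and behaves like a metric on the mask", {
  a <- matrix(c(0, 1, 0.5, 0.25), 2, 2, byrow = FALSE)
  # rows: (0, 0.5), (1, 0.25) -- build explicitly to match the hand example
  a <- matrix(c(0, 0.5, 1, 0.25), 2, 2, byrow = TRUE)
  b <- matrix(c(0.5, 0.5, 0, 0.25), 2, 2, byrow = TRUE)
  full <- matrix(TRUE, 2, 2)
  expect_equal(sad(a, b, full), 0.375)
  expect_equal(sad(a, a, full), 0)
  expect_equal(sad(matrix(1, 3, 3), matrix(0, 3, 3), matrix(TRUE, 3, 3)), 1)
  expect_equal(sad(a, b, full), sad(b, a, full))
  expect_error(sad(a, b, matrix(FALSE, 2, 2)), "empty")
  expect_error(sad(a, matrix(0, 3, 3), full), "shape")
})

test_that("case evaluation decomposes improvement exactly and the identity model is neutral", {
  sp <- phantom_spec(image_height = 64, image_width = 64, seed = 50)
  cs <- generate_bilateral_case(sp)
  pair <- raw_pair(unclass(cs$right_image)[, ],
                   unclass(flip_horizontal(cs$left_image))[, ],
                   unclass(cs$right_mask)[, ])
  mdl <- init_registration_model(seed = 1)  # zero flow -> identity warp
  ev <- evaluate_case(mdl, pair)
  expect_equal(ev$record$improvement,
               ev$record$sad_without - ev$record$sad_with)
  expect_lt(abs(ev$record$improvement), 1e-6)
  expect_equal(ev$record$sad_without,
               sad(pair$fixed, pair$moving, pair$mask))
  # SADs recompute identically from the written difference images
  p1 <- withr::local_tempfile(fileext = ".png")
  write_difference_image(ev$difference_without, p1)
  msk <- as.logical(pair$mask)
  expect_lt(abs(mean(read_difference_image(p1)[msk]) -
                ev$record$sad_without), 1 / 65535)
})

test_that("quartile splits have balanced contiguous groups with the stated directions", {
  rec <- fake_records(500)
  for (cv in c("breast_area_pct", "density_pct", "thickness_mm",
               "sad_without")) {
    g <- quartile_split(rec, cv)
    expect_equal(as.vector(table(g$group)), rep(125L, 4))
    ord <- if (cv == "sad_without") g[order(g[[cv]]), ] else
      g[order(-g[[cv]]), ]
    expect_true(all(diff(ord$group) >= 0))  # contiguous blocks in sort order
  }

  g10 <- quartile_split(fake_records(10), "thickness_mm")
  expect_equal(as.vector(table(g10$group)), c(3L, 3L, 2L, 2L))

  ties <- fake_records(8)
  ties$thickness_mm <- 50
  g <- quartile_split(ties, "thickness_mm")
  expect_equal(g$group, rep(1:4, each = 2))  # stable: by case_id order

  expect_error(quartile_split(rec, "nope"), "unknown covariate")
})

test_that("subgroup summaries carry the full covariate x group x condition structure", {
  rec <- fake_records(500)
  rep_ <- compare_and_summarize(rec)
  expect_equal(nrow(rep_$subgroups), 16L)  # 4 covariates x 4 groups
  expect_equal(sort(unique(rep_$subgroups$covariate)),
               sort(c("breast_area_pct", "density_pct", "thickness_mm",
                      "sad_without")))
  # Table-2 layout: one row per group, without/with columns per covariate
  expect_equal(nrow(rep_$table2), 4L)
  expect_equal(ncol(rep_$table2), 9L)
  expect_equal(nrow(rep_$pairwise), 4 * 6)
  expect_s3_class(glance(rep_), "tbl_df")
  expect_equal(tidy(rep_), rep_$subgroups)
})

test_that("paired testing follows the zero and all-improved conventions", {
  rec0 <- fake_records(30)
  rec0$sad_with <- rec0$sad_without
  rec0$improvement <- 0
  rep0 <- compare_and_summarize(rec0)
  expect_equal(rep0$overall$p_value, 1)

  withr::with_seed(60, {
    s0 <- runif(50, 0.05, 0.15)
    imp <- runif(50, 0.005, 0.03)
  })
  rec1 <- tibble::tibble(case_id = sprintf("c%03d", 1:50), sad_without = s0,
                         sad_with = s0 - imp, improvement = imp,
                         breast_area_pct = runif(50, 12, 70),
                         density_pct = runif(50, 12, 80),
                         thickness_mm = runif(50, 12, 84))
  rep1 <- compare_and_summarize(rec1)
  expect_lt(rep1$overall$p_value, 0.001)
  expect_equal(rep1$overall$fraction_improved, 1)

  rec_small <- fake_records(5)
  w <- testthat::capture_warnings(compare_and_summarize(rec_small))
  expect_true(any(grepl("< 2 cases", w)))
})
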