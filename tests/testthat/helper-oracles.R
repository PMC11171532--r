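# Brute-force per-pixel reference implementations used as independent
# oracles for the vectorized/compiled losses.

brute_mse <- function(fixed, warped, mask) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(fixed)))
    for (j in seq_len(ncol(fixed)))
      if (mask[i, j]) {
        s <- s + (fixed[i, j] - warped[i, j])^2
        n <- n + 1
      }
  s / n
}

brute_smoothness <- function(u_row, u_col) {
  h <- nrow(u_row); w <- ncol(u_row)
  sr <- 0
  for (comp in list(u_row, u_col))
    for (j in seq_len(w))
      for (i in seq_len(h - 1))
        sr <- sr + (comp[i + 1, j] - comp[i, j])^2
  sc <- 0
  for (comp in list(u_row, u_col))
    for (j in seq_len(w - 1))
      for (i in seq_len(h))
        sc <- sc + (comp[i, j + 1] - comp[i, j])^2
  sr / (2 * (h - 1) * w) + sc / (2 * h * (w - 1))
}

brute_sad <- function(a, b, mask) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a)))
      if (mask[i, j]) {
        s <- s + abs(a[i, j] - b[i, j])
        n <- n + 1
      }
  s / n
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# small registration_pair built directly from matrices (bypasses preprocessing)
raw_pair <- function(fixed, moving, mask = NULL, case_id = "case") {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(fixed), ncol(fixed))
  structure(list(fixed = fixed, moving = moving,
                 mask = breast_mask(mask), case_id = case_id),
            class = "registration_pair")
}

# synthetic case-record table with known covariates
fake_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    s0 <- runif(n, 0.02, 0.2)
    imp <- pmin(runif(n, -0.002, 0.06), 0.8 * s0)
    tibble::tibble(
      case_id = sprintf("case_%04d", seq_len(n)),
      sad_without = s0, sad_with = s0 - imp, improvement = imp,
      breast_area_pct = runif(n, 11.1, 79.8),
      density_pct = runif(n, 11.5, 85),
      thickness_mm = runif(n, 12, 84))
  })
}
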