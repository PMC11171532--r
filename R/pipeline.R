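#' Configuration of an end-to-end run
#'
#' Bundles the phantom-cohort settings, the train/validation/test split
#' (default proportions 1000:100:500, scaled to `n_cases`), the training
#' schedule, and the global seed. The default profile is the package's
#' scaled-down analog of the clinical experiment: 96 cases at 128 x 128,
#' 150 epochs, batch 8.
#'
#' @param out_dir run directory (created if needed).
#' @param n_cases number of phantom cases to simulate.
#' @param image_size phantom and network image side length (multiple of 16).
#' @param epochs,batch_size,lambda_smooth,base_lr training schedule; see
#'   [train_config()].
#' @param deform_magnitude,noise_sd phantom asymmetry parameters.
#' @param seed global integer seed recorded in the run metadata.
#' @return a `run_config` object.
#' @export
run_config <- function(out_dir, n_cases = 96L, image_size = 128L,
                       epochs = 150L, batch_size = 8L, lambda_smooth = 1,
                       base_lr = 2e-4, deform_magnitude = 3, noise_sd = 0.01,
                       seed = 1L) {
  if (image_size %% 16 != 0)
    stop_mammosub("`image_size` must be a multiple of 16", "bad_config")
  n_train <- max(1L, round(n_cases * 1000 / 1600))
  n_val <- max(1L, round(n_cases * 100 / 1600))
  n_test <- n_cases - n_train - n_val
  if (n_test < 4)
    stop_mammosub("`n_cases` too small: need at least 4 test cases",
                  "bad_config")
  structure(list(out_dir = out_dir, n_cases = as.integer(n_cases),
                 image_size = as.integer(image_size),
                 n_train = n_train, n_val = n_val, n_test = n_test,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lambda_smooth = lambda_smooth, base_lr = base_lr,
                 deform_magnitude = deform_magnitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "run_config")
}

run_stage <- function(stage, fn) {
  tryCatch(fn(), error = function(e) {
    stop_mammosub(sprintf("stage '%s' failed: %s", stage,
                          conditionMessage(e)), "stage_failure")
  })
}

#' Simulate a phantom cohort to disk
#'
#' Writes 16-bit PNG images and masks, 32-bit float TIFF ground-truth
#' fields, and a CSV manifest into `dir`.
#'
#' @param n number of cases.
#' @param dir output directory.
#' @param image_size side length in pixels.
#' @param deform_magnitude,noise_sd see [phantom_spec()].
#' @param seed integer seed.
#' @return the manifest tibble (with file paths filled in), invisibly the
#'   cases too as attribute is avoided; use [generate_cohort()] directly for
#'   in-memory work.
#' @export
simulate_cohort_to_dir <- function(n, dir, image_size = 512L,
                                   deform_magnitude = 3, noise_sd = 0.01,
                                   seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(n, image_size = c(image_size, image_size),
                            deform_magnitude = deform_magnitude,
                            noise_sd = noise_sd, seed = seed)
  man <- cohort$manifest
  for (k in seq_len(n)) {
    cs <- cohort$cases[[k]]
    id <- man$case_id[k]
    rp <- file.path(dir, paste0(id, "_R.png"))
    lp <- file.path(dir, paste0(id, "_L.png"))
    write_mammogram(cs$right_image, rp)
    write_mammogram(cs$left_image, lp)
    write_mask(cs$right_mask, file.path(dir, paste0(id, "_R_mask.png")))
    write_mask(cs$left_mask, file.path(dir, paste0(id, "_L_mask.png")))
    write_displacement_field(cs$true_field,
                             file.path(dir, paste0(id, "_field.tif")))
    man$right_path[k] <- rp
    man$left_path[k] <- lp
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  man
}

#' Preprocess a manifest of bilateral cases into registration pairs
#'
#' @param manifest manifest tibble (or path to one).
#' @param out_size network input size.
#' @return list of `registration_pair` objects in manifest order.
#' @export
preprocess_manifest <- function(manifest, out_size = 512L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  purrr::map(seq_len(nrow(manifest)), function(k) {
    r <- read_mammogram(manifest$right_path[k], "R",
                        thickness_mm = manifest$thickness_mm[k])
    l <- read_mammogram(manifest$left_path[k], "L",
                        thickness_mm = manifest$thickness_mm[k])
    preprocess_pair(r, l, out_size = out_size,
                    case_id = manifest$case_id[k])
  })
}

#' Run the full simulate / preprocess / train / evaluate pipeline
#'
#' Executes the four stages in order inside `config$out_dir`, persisting
#' every artifact (cohort images and manifest, preprocessed pairs' SAD
#' table, learning curve, model checkpoint, per-case records, difference
#' images, subgroup report, figures) plus the resolved configuration and
#' package version, so a rerun with the same config and seed reproduces the
#' metrics exactly. Stage failures abort with the stage name.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `records`, `report`, `model`, `run_dir`.
#' @export
run_end_to_end <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(config$out_dir, "simulate")
  eval_dir <- file.path(config$out_dir, "evaluate")

  man <- run_stage("simulate", function() {
    simulate_cohort_to_dir(config$n_cases, sim_dir,
                           image_size = config$image_size,
                           deform_magnitude = config$deform_magnitude,
                           noise_sd = config$noise_sd, seed = config$seed)
  })

  pairs <- run_stage("preprocess", function() {
    preprocess_manifest(file.path(sim_dir, "manifest.csv"),
                        out_size = config$image_size)
  })

  idx_train <- seq_len(config$n_train)
  idx_val <- config$n_train + seq_len(config$n_val)
  idx_test <- config$n_train + config$n_val + seq_len(config$n_test)

  model <- run_stage("train", function() {
    tc <- train_config(epochs = config$epochs,
                       batch_size = config$batch_size,
                       lambda_smooth = config$lambda_smooth,
                       base_lr = config$base_lr, seed = config$seed + 1L)
    m <- train_registration(pairs[idx_train], pairs[idx_val], tc)
    write.csv(m$history, file.path(config$out_dir, "learning_curve.csv"),
              row.names = FALSE)
    save_registration_model(m, file.path(config$out_dir, "weights.rds"))
    m
  })

  out <- run_stage("evaluate", function() {
    dir.create(eval_dir, showWarnings = FALSE)
    covs <- tibble::tibble(breast_area_pct = man$area_pct_measured[idx_test],
                           density_pct = man$density_pct_measured[idx_test],
                           thickness_mm = man$thickness_mm[idx_test])
    test_pairs <- pairs[idx_test]
    records <- purrr::map_dfr(seq_along(test_pairs), function(k) {
      ev <- evaluate_case(model, test_pairs[[k]], covs[k, ])
      id <- ev$record$case_id
      write_difference_image(ev$difference_without,
                             file.path(eval_dir,
                                       paste0(id, "_diff_without.png")))
      write_difference_image(ev$difference_with,
                             file.path(eval_dir, paste0(id, "_diff_with.png")))
      ev$record
    })
    write.csv(records, file.path(eval_dir, "case_records.csv"),
              row.names = FALSE)
    report <- compare_and_summarize(records)
    write.csv(report$subgroups, file.path(eval_dir, "subgroup_report.csv"),
              row.names = FALSE)
    writeLines(report_markdown(report),
               file.path(eval_dir, "subgroup_report.md"))
    ggplot2::ggsave(file.path(eval_dir, "sad_comparison.pdf"),
                    plot_sad_comparison(records), width = 4, height = 4)
    ggplot2::ggsave(file.path(eval_dir, "subgroups.pdf"),
                    autoplot(report), width = 7, height = 5)
    ggplot2::ggsave(file.path(eval_dir, "improvement_by_baseline_sad.pdf"),
                    plot_improvement_by_group(records, "sad_without"),
                    width = 5, height = 4)
    ggplot2::ggsave(file.path(config$out_dir, "learning_curve.pdf"),
                    autoplot(model), width = 5, height = 4)
    list(records = records, report = report)
  })

  meta <- unclass(config)
  meta$package_version <- as.character(utils::packageVersion("mammosub"))
  yaml::write_yaml(meta, file.path(config$out_dir, "run.yaml"))
  invisible(list(records = out$records, report = out$report, model = model,
                 run_dir = config$out_dir))
}

# Markdown rendering of a subgroup report (Table-2-style layout)
report_markdown <- function(report) {
  o <- report$overall
  lines <- c(
    "# Subgroup report",
    "",
    sprintf("Overall (n = %d): SAD without %.4f +/- %.4f, with %.4f +/- %.4f, improvement %.4f (p = %.3g).",
            o$n, o$mean_without, o$sd_without, o$mean_with, o$sd_with,
            o$mean_improvement, o$p_value),
    "",
    "| Covariate | Group | n | SAD without (mean +/- SD) | SAD with (mean +/- SD) | Improvement |",
    "|---|---|---|---|---|---|")
  s <- report$subgroups
  for (k in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "| %s | %d | %d | %.4f +/- %.4f | %.4f +/- %.4f | %.4f |",
      s$covariate[k], s$group[k], s$n[k], s$mean_without[k],
      s$sd_without[k], s$mean_with[k], s$sd_with[k],
      s$mean_improvement[k]))
  }
  lines
}
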