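#' Sum of absolute differences (SAD) similarity index
#'
#' Here "SAD" is the average absolute intensity difference between two
#' images over the mask pixels, on the `[0, 1]` intensity scale: a
#' dimensionless value where 0 means identical images on the breast region.
#'
#' @param a,b image matrices of equal shape.
#' @param mask [breast_mask()] or logical matrix; must be nonempty.
#' @return scalar SAD.
#' @export
sad <- function(a, b, mask) {
  if (!identical(dim(img_matrix(a)), dim(img_matrix(b))))
    stop_mammosub("`a` and `b` shapes differ", "shape_mismatch")
  sel <- as.logical(mask)
  if (!any(sel)) stop_mammosub("mask is empty", "empty_mask")
  mean(abs(img_matrix(a) - img_matrix(b))[sel])
}

#' Evaluate one registration pair
#'
#' Predicts the displacement field, warps the flipped image, and computes
#' both difference images and their SADs: `sad_without` compares fixed vs
#' flipped (no registration), `sad_with` compares fixed vs transformed, and
#' `improvement = sad_without - sad_with`.
#'
#' @param model a trained (or initialized) `registration_model`.
#' @param pair a `registration_pair` from [preprocess_pair()].
#' @param covariates optional one-row data frame of case covariates to carry
#'   into the record.
#' @return a `case_evaluation`: list with `record` (one-row tibble), `field`,
#'   `transformed`, `difference_without`, `difference_with`.
#' @export
evaluate_case <- function(model, pair, covariates = NULL) {
  field <- predict_displacement(model, pair$fixed, pair$moving)
  transformed <- warp_image(pair$moving, field)
  diff_without <- abs(img_matrix(pair$fixed) - img_matrix(pair$moving))
  diff_with <- abs(img_matrix(pair$fixed) - transformed)
  s0 <- sad(pair$fixed, pair$moving, pair$mask)
  s1 <- sad(pair$fixed, transformed, pair$mask)
  rec <- tibble::tibble(case_id = pair$case_id, sad_without = s0,
                        sad_with = s1, improvement = s0 - s1)
  if (!is.null(covariates)) rec <- dplyr::bind_cols(rec, covariates)
  structure(list(record = rec, field = field, transformed = transformed,
                 difference_without = diff_without,
                 difference_with = diff_with),
            class = "case_evaluation")
}

#' Evaluate a list of pairs into a case-record table
#'
#' @param model a `registration_model`.
#' @param pairs list of `registration_pair` objects.
#' @param covariates optional data frame with one row per pair.
#' @return tibble of case records (one row per pair).
#' @export
evaluate_cohort <- function(model, pairs, covariates = NULL) {
  purrr::map_dfr(seq_along(pairs), function(k) {
    cov_k <- if (is.null(covariates)) NULL else covariates[k, , drop = FALSE]
    evaluate_case(model, pairs[[k]], cov_k)$record
  })
}

#' Split case records into quartile subgroups
#'
#' Sorts by the covariate (decreasing for breast area, gland content ratio
#' and compressed thickness; increasing for the baseline SAD of the
#' difference image without registration), breaking ties stably by
#' `case_id`, then assigns contiguous blocks Group 1..n_groups whose sizes
#' differ by at most one (larger blocks first).
#'
#' @param records tibble of case records.
#' @param covariate column name to sort by.
#' @param order `"auto"` (direction by covariate as above), `"decreasing"`,
#'   or `"increasing"`.
#' @param n_groups number of groups (default 4).
#' @return `records` with an integer `group` column added.
#' @export
quartile_split <- function(records, covariate, order = "auto",
                           n_groups = 4L) {
  if (!covariate %in% names(records))
    stop_mammosub(sprintf("unknown covariate '%s'", covariate),
                  "bad_covariate")
  if (nrow(records) < n_groups)
    stop_mammosub(sprintf("need at least %d records", n_groups), "bad_input")
  if (order == "auto")
    order <- if (covariate == "sad_without") "increasing" else "decreasing"
  v <- records[[covariate]]
  idx <- if (order == "decreasing") {
    order(-v, records$case_id)
  } else {
    order(v, records$case_id)
  }
  n <- nrow(records)
  base <- n %/% n_groups
  sizes <- base + as.integer(seq_len(n_groups) <= n %% n_groups)
  labels <- rep(seq_len(n_groups), times = sizes)
  out <- records
  out$group <- NA_integer_
  out$group[idx] <- labels
  out
}

wilcox_paired_p <- function(x, y) {
  d <- x - y
  if (all(d == 0)) return(1)  # zero-handling convention: nothing to test
  tryCatch(wilcox.test(x, y, paired = TRUE)$p.value,
           error = function(e) NA_real_)
}

group_summary <- function(records) {
  dplyr::summarise(
    dplyr::group_by(records, .data$group),
    n = dplyr::n(),
    mean_without = mean(.data$sad_without),
    sd_without = sd(.data$sad_without),
    mean_with = mean(.data$sad_with),
    sd_with = sd(.data$sad_with),
    mean_improvement = mean(.data$improvement),
    sd_improvement = sd(.data$improvement),
    p_paired = if (dplyr::n() >= 2)
      wilcox_paired_p(.data$sad_without, .data$sad_with) else NA_real_,
    .groups = "drop")
}

#' Subgroup comparison of SAD with vs without registration
#'
#' For each covariate the records are quartile-split with
#' [quartile_split()] and summarized as mean +/- SD of SAD without/with
#' registration and of the improvement. Significance uses nonparametric
#' defaults: a two-sided paired Wilcoxon signed-rank test of `sad_without`
#' vs `sad_with` (overall and per group; identically-zero improvements give
#' p = 1 by convention), and pairwise two-sided Mann-Whitney tests of the
#' improvement between groups with Holm correction. Set
#' `parametric = TRUE` for paired/two-sample t tests instead. Groups with
#' fewer than 2 cases have their statistic omitted with a warning.
#'
#' @param records tibble of case records from [evaluate_cohort()].
#' @param covariates covariate columns to stratify by.
#' @param parametric use t tests instead of rank tests.
#' @return a `subgroup_report`: list with `overall` (one-row tibble),
#'   `subgroups`, `pairwise`, and `table2` (the 4-covariates x 4-groups
#'   without/with matrix).
#' @export
compare_and_summarize <- function(records,
                                  covariates = c("breast_area_pct",
                                                 "density_pct",
                                                 "thickness_mm",
                                                 "sad_without"),
                                  parametric = FALSE) {
  if (nrow(records) == 0) stop_mammosub("no records", "bad_input")
  overall_p <- if (parametric) {
    if (all(records$improvement == 0)) 1
    else t.test(records$sad_without, records$sad_with,
                paired = TRUE)$p.value
  } else {
    wilcox_paired_p(records$sad_without, records$sad_with)
  }
  overall <- tibble::tibble(
    n = nrow(records),
    mean_without = mean(records$sad_without),
    sd_without = sd(records$sad_without),
    mean_with = mean(records$sad_with),
    sd_with = sd(records$sad_with),
    mean_improvement = mean(records$improvement),
    min_improvement = min(records$improvement),
    max_improvement = max(records$improvement),
    fraction_improved = mean(records$improvement > 0),
    p_value = overall_p)

  subgroups <- purrr::map_dfr(covariates, function(cv) {
    grp <- quartile_split(records, cv)
    s <- group_summary(grp)
    if (any(s$n < 2))
      rlang::warn(sprintf(
        "covariate '%s': groups with < 2 cases, statistic omitted", cv))
    dplyr::bind_cols(tibble::tibble(covariate = cv), s)
  })

  pairwise <- purrr::map_dfr(covariates, function(cv) {
    grp <- quartile_split(records, cv)
    if (length(unique(grp$group)) < 2) return(NULL)
    pw <- if (parametric) {
      pairwise.t.test(grp$improvement, grp$group, p.adjust.method = "holm",
                      pool.sd = FALSE)
    } else {
      suppressWarnings(
        pairwise.wilcox.test(grp$improvement, grp$group,
                             p.adjust.method = "holm"))
    }
    m <- pw$p.value
    df <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
    df <- df[!is.na(df$Freq), ]
    tibble::tibble(covariate = cv,
                   group_a = as.integer(df$Var1),
                   group_b = as.integer(df$Var2),
                   p_holm = df$Freq)
  })

  tab2 <- tidyr::pivot_wider(
    dplyr::select(subgroups, "covariate", "group", "mean_without",
                  "mean_with"),
    names_from = "covariate", values_from = c("mean_without", "mean_with"),
    names_vary = "slowest")

  structure(list(overall = overall, subgroups = subgroups,
                 pairwise = pairwise, table2 = tab2,
                 parametric = parametric),
            class = "subgroup_report")
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat(sprintf(
    "<subgroup_report> n = %d; SAD %.4f +/- %.3f without vs %.4f +/- %.3f with registration (p = %.3g)\n",
    x$overall$n, x$overall$mean_without, x$overall$sd_without,
    x$overall$mean_with, x$overall$sd_with, x$overall$p_value))
  cat(sprintf("  mean improvement %.4f [%.4f, %.4f], improved in %.1f%% of cases\n",
              x$overall$mean_improvement, x$overall$min_improvement,
              x$overall$max_improvement, 100 * x$overall$fraction_improved))
  print(x$subgroups, n = 8)
  invisible(x)
}

#' @export
tidy.subgroup_report <- function(x, ...) x$subgroups

#' @export
glance.subgroup_report <- function(x, ...) x$overall

#' @export
autoplot.subgroup_report <- function(object, records = NULL, ...) {
  df <- tidyr::pivot_longer(object$subgroups,
                            c("mean_without", "mean_with"),
                            names_to = "condition", values_to = "sad")
  df$condition <- ifelse(df$condition == "mean_without",
                         "without registration", "with registration")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$group), .data$sad,
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~covariate) +
    ggplot2::labs(x = "Group", y = "mean SAD", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplot of the SAD improvement across quartile subgroups
#'
#' @param records case-record tibble.
#' @param covariate covariate to stratify by (see [quartile_split()]).
#' @return a ggplot object.
#' @export
plot_improvement_by_group <- function(records, covariate) {
  g <- quartile_split(records, covariate)
  ggplot2::ggplot(g, ggplot2::aes(factor(.data$group), .data$improvement)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("Group (%s)", covariate),
                  y = "SAD improvement") +
    ggplot2::theme_minimal()
}

#' Boxplot of SAD with and without registration
#'
#' @param records case-record tibble.
#' @return a ggplot object.
#' @export
plot_sad_comparison <- function(records) {
  df <- tidyr::pivot_longer(records, c("sad_without", "sad_with"),
                            names_to = "condition", values_to = "sad")
  df$condition <- factor(df$condition, c("sad_without", "sad_with"),
                         c("without", "with"))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$sad)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "SAD") +
    ggplot2::theme_minimal()
}
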