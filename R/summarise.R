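#' Summarise experiment results
#'
#' Aggregates a long-format results table (from [run_condition()] records
#' or [read_results()]) to mean and SD of the classification error — and,
#' for imputed dataset kinds, of the NRMSE — over repetitions, grouped by
#' the requested columns.
#'
#' @param results Results tibble / data frame.
#' @param groups Character vector of grouping columns (default: dataset
#'   kind, feature-selection method, rule, feature-set size, plus any
#'   swept condition column that varies in `results`).
#' @return A tibble with `mean_error`, `sd_error`, `n_reps`,
#'   `mean_nrmse`, `sd_nrmse` per group, of class `mvbench_summary`.
#' @export
summarize_results <- function(results, groups = NULL) {
  if (inherits(results, "condition_result")) results <- results$records
  if (nrow(results) == 0L) stop("no result rows to summarise", call. = FALSE)
  if (is.null(groups)) {
    groups <- c("dataset_kind", "fs_method", "rule", "n_features")
    sweep_cols <- c("mv_rate", "noise_mean", "block_sd", "block_corr",
                    "mask_mode")
    varying <- sweep_cols[vapply(sweep_cols, function(cl)
      length(unique(results[[cl]])) > 1L, logical(1))]
    groups <- c(groups, varying)
  }
  out <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(mean_error = mean(.data$error),
                     sd_error = sd(.data$error),
                     n_reps = dplyr::n_distinct(.data$repetition),
                     mean_nrmse = if (all(is.na(.data$nrmse))) NA_real_
                                  else mean(.data$nrmse, na.rm = TRUE),
                     sd_nrmse = if (all(is.na(.data$nrmse))) NA_real_
                                else sd(.data$nrmse, na.rm = TRUE),
                     .groups = "drop")
  class(out) <- c("mvbench_summary", class(out))
  out
}

#' Plot error curves
#'
#' Mean classification error against the feature-set size (or any other
#' summary column), one line per dataset kind, facetted by rule and
#' feature-selection method — the panel layout of the study's error
#' figures.
#'
#' @param summary An [summarize_results()] tibble.
#' @param x Column mapped to the x axis (default `"n_features"`).
#' @return A ggplot object.
#' @export
plot_error_curves <- function(summary, x = "n_features") {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data[[x]], y = .data$mean_error,
                               colour = .data$dataset_kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(ggplot2::vars(.data$rule),
                        ggplot2::vars(.data$fs_method)) +
    ggplot2::labs(x = x, y = "mean classification error",
                  colour = "dataset") +
    ggplot2::theme_bw()
}

#' Plot NRMSE against MV rate
#'
#' One curve per imputation method: the signal-referenced NRMSE as a
#' function of the missing-value rate, the comparison on which the
#' quality-masking peaking phenomenon shows.
#'
#' @param results Results tibble (needs a swept `mv_rate` column).
#' @return A ggplot object.
#' @export
plot_nrmse_curves <- function(results) {
  if (inherits(results, "condition_result")) results <- results$records
  df <- results |>
    dplyr::filter(!is.na(.data$nrmse)) |>
    dplyr::distinct(.data$dataset_kind, .data$mv_rate, .data$mask_mode,
                    .data$repetition, .data$nrmse) |>
    dplyr::group_by(.data$dataset_kind, .data$mv_rate, .data$mask_mode) |>
    dplyr::summarise(mean_nrmse = mean(.data$nrmse), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mv_rate, y = .data$mean_nrmse,
                                   colour = .data$dataset_kind,
                                   linetype = .data$mask_mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "missing-value rate", y = "mean NRMSE",
                  colour = "method", linetype = "masking") +
    ggplot2::theme_bw()
}

#' @rdname plot_error_curves
#' @param object A `condition_result`.
#' @param ... Unused.
#' @method autoplot condition_result
#' @export
autoplot.condition_result <- function(object, ...) {
  plot_error_curves(summarize_results(object$records))
}
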