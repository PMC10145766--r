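#' Broom-style tidiers for fitted runs
#'
#' `tidy()` returns per-variable permutation importances of a run (when
#' computed); `glance()` returns the one-row evaluation summary.
#'
#' @param x An `sdm_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdm_run <- function(x, ...) {
  if (is.null(x$importance))
    return(tibble::tibble(variable = x$predictors, importance = NA_real_))
  tibble::tibble(variable = names(x$importance),
                 importance = as.numeric(x$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy.sdm_run
#' @export
glance.sdm_run <- function(x, ...) {
  e <- x$evaluation
  tibble::tibble(
    algorithm = x$algorithm,
    pa_set_id = x$pa_set_id %||% NA_integer_,
    replicate_id = x$replicate_id,
    auc = if (is.null(e)) NA_real_ else e$auc,
    mtss_threshold = if (is.null(e)) NA_real_ else e$mtss_threshold,
    sensitivity = if (is.null(e)) NA_real_ else e$sensitivity,
    specificity = if (is.null(e)) NA_real_ else e$specificity,
    tss = if (is.null(e)) NA_real_ else e$tss)
}

#' Bar chart of averaged variable importances
#'
#' @param importance Tibble with columns `variable` and `importance` (e.g.
#'   averaged across selected models).
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = stats::reorder(.data$variable,
                                                  .data$importance),
                               y = .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Permutation importance")
}

#' Boxplot-style summary of the elevational shift
#'
#' @param shift_tbl Tibble of [elevation_shift()] rows with an added
#'   `scenario` column.
#' @return A ggplot object.
#' @export
plot_elevation_shift <- function(shift_tbl) {
  long <- dplyr::bind_rows(
    dplyr::transmute(shift_tbl, scenario = "present",
                     q1 = .data$present_q1, median = .data$present_median,
                     q3 = .data$present_q3, mean = .data$present_mean) |>
      dplyr::distinct(),
    dplyr::transmute(shift_tbl, scenario = .data$scenario,
                     q1 = .data$future_q1, median = .data$future_median,
                     q3 = .data$future_q3, mean = .data$future_mean))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                           width = 0.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median), size = 3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = "Elevation of suitable cells (m)")
}
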