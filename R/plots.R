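#' Heatmap of a density map
#'
#' @param object A `density_map`.
#' @param ... Unused.
#' @return A ggplot: grid heatmap of local mitotic counts or Ki-67 indices,
#'   missing (non-tumour / unqualified) cells blank.
#' @export
autoplot.density_map <- function(object, ...) {
  v <- object$values
  d <- tidyr::expand_grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  d$value <- as.vector(t(v))
  lab <- if (object$kind == "mitotic_2mm2") "mitoses / 2 mm²" else "Ki-67 %"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "grid column", y = "grid row") +
    ggplot2::theme_minimal()
}

#' Bar plot of a slide histogram
#'
#' @param object A `slide_histogram`.
#' @param ... Unused.
#' @return A ggplot of normalised bin frequencies.
#' @export
autoplot.slide_histogram <- function(object, ...) {
  d <- tidy(object)
  xlab <- if (object$kind == "mitotic") "mitoses / 2 mm² (clipped)"
          else "Ki-67 index (%)"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$frequency)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = xlab, y = "frequency") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step plot
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot step curve with its 95% confidence band.
#' @export
autoplot.km_curve <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1, ci_lower = 1, ci_upper = 1),
    object$curve)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_lower),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_upper),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (years)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by group
#'
#' @param cohort Data frame with `time_years`, `event` and a grouping
#'   column (e.g. grade).
#' @param group_col Grouping column name.
#' @return A ggplot with one step curve per group.
#' @export
plot_km_by_group <- function(cohort, group_col = "grade") {
  stopifnot(group_col %in% names(cohort))
  d <- cohort |>
    dplyr::group_by(.data[[group_col]]) |>
    dplyr::group_modify(function(x, key)
      dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                       km_estimate(x)$curve[c("time", "survival")])) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                  colour = factor(.data[[group_col]]))) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (years)", y = "survival probability",
                  colour = group_col) +
    ggplot2::theme_minimal()
}
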