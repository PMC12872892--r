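#' Plot uptake dynamics over sampling events
#'
#' Mean uptake concentration per cultivar over sampling dates, one facet per
#' element, with SEM ribbons — the standard view of temporal uptake dynamics.
#'
#' @param uptake_records tibble with `cultivar`, `date`, `element`,
#'   `uptake_mg_per_l` (e.g. `bundle$uptake_records`).
#' @param elements subset of elements to show; default all present.
#' @return a ggplot object.
#' @export
plot_uptake_dynamics <- function(uptake_records, elements = NULL) {
  df <- uptake_records
  if (!is.null(elements)) df <- dplyr::filter(df, .data$element %in% elements)
  summ <- df |>
    dplyr::group_by(.data$cultivar, .data$element, .data$date) |>
    dplyr::summarise(mean = mean(.data$uptake_mg_per_l),
                     sem = sem(.data$uptake_mg_per_l), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$date, y = .data$mean,
                                     colour = .data$cultivar,
                                     group = .data$cultivar)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             size = 0.2) +
    ggplot2::facet_wrap(~element, scales = "free_y") +
    ggplot2::labs(x = "Sampling date",
                  y = expression(Uptake~(mg~L^-1~transpired)),
                  colour = "Cultivar") +
    ggplot2::theme_minimal()
}

#' Plot prediction deviations by tissue source
#'
#' Signed percent deviation of each prediction source from measured uptake,
#' per element and cultivar; the best source per cell is emphasized.
#'
#' @param deviations tibble from [compare_predictions()] (or
#'   `bundle$deviations`).
#' @return a ggplot object.
#' @export
plot_deviations <- function(deviations) {
  ggplot2::ggplot(deviations,
                  ggplot2::aes(x = .data$element, y = .data$deviation_percent,
                               fill = .data$source,
                               alpha = .data$source == .data$best_source)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~cultivar) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.45),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "Deviation from measured uptake (%)",
                  fill = "Prediction source") +
    ggplot2::theme_minimal()
}

#' @rdname plot_deviations
#' @param object a `report_bundle`.
#' @param ... unused.
#' @method autoplot report_bundle
#' @export
autoplot.report_bundle <- function(object, ...) {
  plot_deviations(object$deviations)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
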