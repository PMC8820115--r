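#' Plot the distribution of laterality indices
#'
#' Histogram of per-bird laterality indices for analyzable birds, filled by
#' classification and faceted by food type. Positive LI means left-eye
#' bias.
#'
#' @param classified Output of [classify_birds()].
#' @param binwidth Histogram bin width on the LI scale (default 0.2).
#' @return A ggplot object.
#' @export
plot_li_distribution <- function(classified, binwidth = 0.2) {
  d <- tibble::as_tibble(classified) |>
    dplyr::filter(.data$classification != "EXCLUDED")
  if (!"food_type" %in% names(d)) d$food_type <- "all"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$li, fill = .data$classification)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0, colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~food_type) +
    ggplot2::scale_fill_manual(values = c(
      LEFT = "#5e81ac", RIGHT = "#bf616a", NONE = "grey75"
    )) +
    ggplot2::labs(
      x = "Laterality index  (L - R) / (L + R)", y = "Birds",
      fill = "Preference"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-bird eye-conditional error counts
#'
#' Paired view of the balanced-design error splits: for each qualifying
#' bird, errors after the preferred vs the non-preferred eye.
#'
#' @param x A `balanced_error_result` from [balanced_error_analysis()].
#' @return A ggplot object.
#' @export
plot_error_breakdown <- function(x) {
  d <- x$breakdown |>
    tidyr::pivot_longer(
      c("errors_after_preferred_eye", "errors_after_nonpreferred_eye"),
      names_to = "condition", values_to = "errors"
    ) |>
    dplyr::mutate(condition = ifelse(
      .data$condition == "errors_after_preferred_eye", "preferred eye", "non-preferred eye"
    ))
  ggplot2::ggplot(d, ggplot2::aes(.data$condition, .data$errors, group = .data$bird_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~preference) +
    ggplot2::labs(
      x = NULL, y = sprintf("Errors (of first %d)", x$cap),
      title = "Eye-conditional pecking errors"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot lat_report
#' @export
autoplot.lat_report <- function(object, ...) {
  plot_li_distribution(object$classified, ...)
}

#' @method autoplot balanced_error_result
#' @export
autoplot.balanced_error_result <- function(object, ...) {
  plot_error_breakdown(object)
}
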