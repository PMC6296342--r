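#' Plot simple slopes as crossing regression lines
#'
#' Draws the fitted outcome-on-smoking lines at moderator values one SD below
#' and above the mean, the conventional picture of a fitted interaction.
#'
#' @param object A [simple_slopes()] result.
#' @param xlab,ylab Axis labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot simple_slopes
autoplot.simple_slopes <- function(object, xlab = "Smoking status",
                                   ylab = "Index (z units)", ...) {
  df <- tidyr::crossing(as_tibble(object), smoking = c(0, 1))
  df$fitted <- df$intercept + df$slope * df$smoking
  ggplot2::ggplot(df, ggplot2::aes(x = .data$smoking, y = .data$fitted,
                                   colour = .data$moderator_level)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = c(0, 1),
                                labels = c("Non-smoker", "Smoker")) +
    ggplot2::labs(x = xlab, y = ylab, colour = "Moderator") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of an interaction scan
#'
#' Interaction coefficient against -log10 nominal interaction p-value,
#' coloured by direction class, with the significance threshold marked.
#'
#' @param object An [scan_loci()] result.
#' @param alpha Significance line to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot ewas_scan
autoplot.ewas_scan <- function(object, alpha = attr(object, "alpha") %||% 0.05,
                               ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$int_p) & !is.na(df$direction), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$int_b,
                                   y = -log10(.data$int_p),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "Smoking × moderator coefficient (logit scale)",
                  y = expression(-log[10] ~ "interaction p"),
                  colour = "Direction") +
    ggplot2::theme_minimal()
}
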