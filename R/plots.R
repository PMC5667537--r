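#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of a coefficient set
#'
#' Point estimates with 95% intervals per habitat, coloured by provenance
#' (modelled / transferred / assumed-zero).
#'
#' @param coeffs A coefficient tibble (see [apply_transfers()]).
#' @return A ggplot object.
#' @export
plot_coefficients <- function(coeffs) {
  df <- dplyr::mutate(
    tibble::as_tibble(coeffs),
    habitat = factor(.data$habitat, levels = rev(.data$habitat))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$habitat,
                                   colour = .data$provenance)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_lo, xmax = .data$conf_hi), height = 0.2
    ) +
    ggplot2::labs(x = "expected species count", y = NULL,
                  colour = "provenance") +
    ggplot2::theme_minimal()
}

#' Histogram of sensitivity percent-change draws
#'
#' @param object A `sensitivity_result`.
#' @param ... Unused.
#' @return A ggplot object with a reference line at 0% change.
#' @method autoplot sensitivity_result
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$percent_change)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "percent change in average biodiversity",
      y = "replicates",
      title = paste0("Sensitivity under ", object$assumption, " (",
                     object$n_reps, " reps; ",
                     signif(100 * object$fraction_negative, 3),
                     "% of runs negative)")
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of the asymmetric percent-shared matrix
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object; rows are the habitat whose species list forms
#'   the denominator.
#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$habitat_x, y = .data$habitat_y,
                                   fill = .data$percent_shared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$percent_shared)),
                       size = 3, na.rm = TRUE) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), na.value = "white") +
    ggplot2::labs(x = "species of habitat...", y = "...shared with habitat",
                  fill = "% shared") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
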