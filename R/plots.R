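#' Manhattan-style plot of PWAS results
#'
#' @param object A `pwas_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pwas_result <- function(object, ...) {
  d <- object$results
  t2 <- object$settings$fdr_tiers[2]
  cut_p <- if (any(d$q <= t2)) max(d$p[d$q <= t2]) else NA_real_
  gg <- ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$pesticide_id, .data$p),
    y = -log10(.data$p)
  )) +
    ggplot2::geom_point(ggplot2::aes(color = .data$implicated)) +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(p))),
                  color = "implicated") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.na(cut_p)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(cut_p),
                                   linetype = "dashed", color = "red")
  }
  gg
}

#' Heatmap of a co-exposure correlation matrix
#'
#' @param r Correlation matrix from [exposure_corr()].
#' @return A ggplot tile heatmap.
#' @export
plot_corr_heatmap <- function(r) {
  d <- as_tibble(r, rownames = "row") %>%
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "r")
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "darkred", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson R") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Dose-response curves from the screen
#'
#' @param ds Output of [dose_summary()].
#' @return A ggplot of mean counts over log dose, one panel per compound.
#' @export
plot_dose_response <- function(ds) {
  ggplot2::ggplot(ds$doses, ggplot2::aes(.data$dose, .data$mean_count)) +
    ggplot2::geom_line(color = "red") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ds$control_mean,
                        linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~compound, scales = "free_y") +
    ggplot2::labs(x = "dose (uM)", y = "reporter-positive cells") +
    ggplot2::theme_minimal()
}

#' Ordered combination bar plot (upset-style counts)
#'
#' @param object A `combo_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of conditions in descending mean count.
#' @exportS3Method ggplot2::autoplot
autoplot.combo_result <- function(object, ...) {
  d <- object$conditions %>%
    mutate(condition = factor(.data$condition, levels = .data$condition))
  ggplot2::ggplot(d, ggplot2::aes(.data$condition, .data$mean_count,
                                  fill = .data$mean_count)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_c(option = "plasma") +
    ggplot2::labs(x = NULL, y = "mean cell count", fill = "count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Mito-stress trace plot
#'
#' @param trace OCR trace tibble (see [mito_stress()]).
#' @return A ggplot of OCR over measurement cycles with segment shading.
#' @export
plot_ocr_trace <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(.data$cycle, .data$ocr,
                                      group = .data$well_id,
                                      color = .data$segment)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "measurement cycle", y = "OCR (normalized)",
                  color = "segment") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
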