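#' Plot a binned ratio distribution
#'
#' Frequency histogram of aneuploid/control ratios per partition, with the
#' canonical reference ratios (0.5 red, 1.0 black, 2.0 purple; 0.67 pink and
#' 1.5 green) marked as vertical dashed lines. The overflow bin is dropped
#' from the display.
#'
#' @param object A `"ratio_bins"` tibble from [bin_ratios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ratio_bins
#' @export
autoplot.ratio_bins <- function(object, ...) {
  dat <- as_tibble(object) %>% filter(is.finite(.data$bin_right))
  refs <- tibble(
    ratio = c(0.5, 0.67, 1.0, 1.5, 2.0),
    colour = c("red", "pink", "black", "green4", "purple")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_left + attr(object, "bin_width") / 2,
                                    y = .data$n)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "steelblue") +
    ggplot2::geom_vline(data = refs,
                        ggplot2::aes(xintercept = .data$ratio),
                        colour = refs$colour, linetype = "dashed") +
    ggplot2::facet_wrap(~partition, scales = "free_y") +
    ggplot2::labs(x = "aneuploid / control expression ratio",
                  y = "genes per bin")
}

#' Plot a differential-expression scatter
#'
#' log2 fold change against mean normalized expression (log10 scale), with
#' significantly up-regulated genes in magenta, down-regulated in green and
#' the rest in black; dashed vertical lines mark the reference ratios.
#'
#' @param object A `"scatter_table"` from [scatter_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scatter_table
#' @export
autoplot.scatter_table <- function(object, ...) {
  dat <- as_tibble(object) %>% filter(!.data$flag)
  refs <- attr(object, "ref_ratios")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$lfc, y = .data$mean_expr,
                                         colour = .data$class)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = log2(refs), linetype = "dashed",
                        colour = c("red", "pink", "black", "green4", "purple")) +
    ggplot2::scale_colour_manual(values = c(up = "magenta3", down = "green4",
                                            ns = "black")) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "log2 fold change (aneuploid / control)",
                  y = "mean normalized expression")
  if ("partition" %in% names(dat)) {
    p <- p + ggplot2::facet_wrap(~partition)
  }
  p
}

#' Plot a transcriptome-size estimate
#'
#' Per-gene estimates (open circles; removed outliers crossed out), the
#' retained mean with an SE error bar, and the no-change reference at 1.0.
#'
#' @param object A `"size_estimate"` from [estimate_size()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot size_estimate
#' @export
autoplot.size_estimate <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate, y = "estimate")) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$retained), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 1, `FALSE` = 4)) +
    ggplot2::annotate("errorbarh",
                      xmin = object$mean - object$se,
                      xmax = object$mean + object$se,
                      y = "estimate", height = 0.2, colour = "red") +
    ggplot2::annotate("point", x = object$mean, y = "estimate",
                      colour = "red", size = 3) +
    ggplot2::labs(x = "relative transcriptome size", y = NULL,
                  shape = "retained")
}
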