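#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an estimated recombination map
#'
#' Posterior-mean rate along each chromosome with the credible band, one
#' colour per sex when present.
#'
#' @param object A `recomb_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recomb_map <- function(object, ...) {
  x <- tibble::as_tibble(object)
  x$mid <- (x$start + x$end) / 2e6
  aes_col <- if ("sex" %in% names(x)) "sex" else NULL
  p <- ggplot2::ggplot(x, ggplot2::aes(.data$mid, .data$mean))
  if (!is.null(aes_col)) {
    p <- p + ggplot2::aes(colour = .data$sex, fill = .data$sex)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
      ymax = .data$upper), alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "recombination rate (cM/Mb)")
}

#' Plot a centromere-relative recombination landscape
#'
#' @param object A `centromere_profile` from [centromere_landscape()].
#' @param ... Unused.
#' @return A ggplot of binned rate against relative distance from the
#'   centromeric tip.
#' @export
autoplot.centromere_profile <- function(object, ...) {
  x <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(x, ggplot2::aes(100 * .data$rel_pos, .data$rate))
  if (any(!is.na(x$sex))) p <- p + ggplot2::aes(colour = .data$sex)
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "distance from centromere (% of chromosome)",
      y = "recombination rate (cM/Mb)")
}

#' Plot a heterochiasmy scan
#'
#' The observed log2 male/female ratio per interval over the permutation null
#' band (mean plus/minus 1.96 sd), with significant intervals highlighted.
#'
#' @param object A `heterochiasmy_result`.
#' @param ... Unused.
#' @return A ggplot faceted by chromosome.
#' @export
autoplot.heterochiasmy_result <- function(object, ...) {
  x <- tibble::as_tibble(object)
  x$mid <- (x$start + x$end) / 2e6
  ggplot2::ggplot(x, ggplot2::aes(.data$mid, .data$d)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$null_mean - 1.96 * .data$null_sd,
      ymax = .data$null_mean + 1.96 * .data$null_sd),
      fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = x[x$significant, ], colour = "red",
      size = 0.8) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2 male/female rate")
}

#' Plot chromosome-wide rates against chromosome size
#'
#' @param chrom_rates Tibble with `rate`, `size` and optional `sex`.
#' @return A ggplot on a log size axis with least-squares lines.
#' @export
plot_chromosome_rates <- function(chrom_rates) {
  p <- ggplot2::ggplot(chrom_rates,
    ggplot2::aes(.data$size / 1e6, .data$rate))
  if ("sex" %in% names(chrom_rates)) {
    p <- p + ggplot2::aes(colour = .data$sex)
  }
  p + ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm",
      formula = y ~ log(x), se = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "chromosome size (Mb)", y = "rate (cM/Mb)")
}
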