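#' Plot ROC curves
#'
#' Step-curve display of one or several direction-aware ROC curves on common
#' axes.
#'
#' @param ... Named ROC tibbles from [roc_curve()] (names become the legend),
#'   or a single (optionally named) list of them.
#' @return A ggplot object.
#' @export
plot_roc <- function(...) {
  curves <- list(...)
  if (length(curves) == 1 && is.list(curves[[1]]) &&
      !is.data.frame(curves[[1]])) {
    curves <- curves[[1]]
  }
  if (is.null(names(curves)) || any(names(curves) == "")) {
    names(curves) <- paste0("curve", seq_along(curves))
  }
  df <- bind_rows(lapply(names(curves), function(nm) {
    mutate(curves[[nm]], method = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$FPR, y = .data$TPR,
                                   colour = .data$method)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Chi-square QQ plot of Poisson goodness-of-fit statistics
#'
#' Observed per-gene Pearson statistics against the matching theoretical
#' chi-square quantiles; a well-calibrated Poisson fit lies on the identity
#' line.
#'
#' @param gof Tibble from [poisson_gof()].
#' @return A ggplot object.
#' @export
plot_gof_qq <- function(gof) {
  ggplot2::ggplot(gof, ggplot2::aes(x = .data$theoretical_quantile,
                                    y = .data$statistic)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(
      x = sprintf("Chi-square(%d) quantile", gof$df[1]),
      y = "Pearson goodness-of-fit statistic") +
    ggplot2::theme_minimal()
}

#' Plot per-lane count distributions before/after normalization
#'
#' Boxplots of log1p counts per lane, a quick visual check that
#' normalization aligned the lane distributions.
#'
#' @param counts A count table.
#' @return A ggplot object.
#' @export
plot_lane_distributions <- function(counts) {
  counts <- validate_counts(counts)
  long <- tidyr::pivot_longer(counts, all_of(lane_ids(counts)),
                              names_to = "lane_id", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lane_id,
                                     y = log1p(.data$count))) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "log(1 + count)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
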