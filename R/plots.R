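#' Plot cumulative-variability curves
#'
#' Boxplots of the per-subdataset variances at each design level with the
#' level means overlaid, optionally contrasting real and randomized
#' curves.
#'
#' @param curves Output of [cumulative_variability()] (possibly rbind-ed
#'   with a [randomized_control()] run).
#' @return A ggplot object.
#' @export
plot_cumulative_variability <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    mv_stop("ggplot2 is required for plotting",
            class = "migvar_parameter_error")
  }
  curves$set <- ifelse(curves$randomized, "randomized", "observed")
  means <- stats::aggregate(variance ~ level + set, curves, mean)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = level, y = variance,
                               colour = set)) +
    ggplot2::geom_boxplot(outlier.size = 0.5,
                          position = ggplot2::position_dodge(width = 0.6),
                          width = 0.5) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(group = set), size = 2,
                        position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(group = set),
                       position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::labs(x = "design level allowed to vary",
                  y = "variance of replicate means") +
    ggplot2::theme_minimal()
}

#' Plot variance components per feature
#'
#' Stacked relative variance shares per level for each feature.
#'
#' @param vartable Output of [decompose_variance()].
#' @return A ggplot object.
#' @export
plot_variance_components <- function(vartable) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    mv_stop("ggplot2 is required for plotting",
            class = "migvar_parameter_error")
  }
  df <- as.data.frame(vartable)
  df$level <- factor(df$level,
                     levels = c("residual", "cell", "replicate",
                                "experiment", "person", "lab"))
  ggplot2::ggplot(df, ggplot2::aes(x = feature, y = share,
                                   fill = level)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative variance share") +
    ggplot2::theme_minimal()
}
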