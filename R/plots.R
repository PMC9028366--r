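#' Plot a recurrence plot
#'
#' Raster view of the binary recurrence matrix (recurrent cells dark),
#' sample index against sample index.
#'
#' @param object A `limb_rp` from [recurrence_plot()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.limb_rp <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$recurrent <- as.vector(m)
  ggplot2::ggplot(df[df$recurrent == 1, ],
                  ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_raster(fill = "grey15") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "time (samples)", y = "time (samples)",
                  title = sprintf("Recurrence plot (epsilon = %.3g)",
                                  object$epsilon)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplots of a recurrence measure by visit and task
#'
#' The standard longitudinal view: one box per task within each visit.
#'
#' @param table Measure table (`subject, visit, task`, measure columns).
#' @param measure Which measure column to plot (default `"ent"`).
#' @return A ggplot.
#' @export
plot_measures <- function(table, measure = "ent") {
  stopifnot(measure %in% names(table))
  table$visit <- factor(table$visit, levels = VISITS)
  ggplot2::ggplot(table, ggplot2::aes(x = .data$visit,
                                      y = .data[[measure]],
                                      fill = .data$task)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8),
                          width = 0.6, outlier.shape = 21) +
    ggplot2::labs(x = "time point", y = measure, fill = "task") +
    ggplot2::theme_minimal()
}

#' Preprocessed limb channels over time
#'
#' @param ms Limb series from [preprocess_session()].
#' @param window_s Optional time window (seconds) to display.
#' @return A ggplot with one facet per limb.
#' @export
plot_channels <- function(ms, window_s = NULL) {
  df <- tidyr::pivot_longer(tibble::as_tibble(ms), -"t",
                            names_to = "limb", values_to = "z")
  if (!is.null(window_s)) df <- df[df$t <= window_s, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$z)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~limb, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "standardized magnitude") +
    ggplot2::theme_minimal()
}
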