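#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_line geom_tile
#'   labs theme_minimal autoplot scale_fill_manual facet_wrap
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot screening-stage accounting
#'
#' Bar chart of read-pair counts per screening stage.
#'
#' @param stats stats tibble from [screen_library()].
#' @return a ggplot object.
#' @export
plot_screen_stats <- function(stats) {
  stats$stage <- factor(stats$stage, levels = stats$stage)
  ggplot(stats, aes(x = .data$stage, y = .data$count)) +
    geom_col(fill = "grey35") +
    labs(x = NULL, y = "read pairs",
         title = "Screening cascade accounting") +
    theme_minimal()
}

#' Plot expression frequencies by tissue and condition
#'
#' @param records frequency tibble from [expression_frequency()].
#' @param freq_cutoff cutoff line to draw (frequent-expression rule).
#' @return a ggplot object.
#' @export
plot_frequency <- function(records, freq_cutoff = 0.10) {
  ggplot(records, aes(x = .data$tissue, y = .data$frequency,
                      fill = .data$condition)) +
    geom_col(position = "dodge") +
    facet_wrap(~.data$transcript) +
    ggplot2::geom_hline(yintercept = freq_cutoff, linetype = 2) +
    scale_fill_manual(values = c(cancer = "#b2182b", normal = "#2166ac")) +
    labs(y = "fraction of samples expressing", x = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heatmap of histone-mark significance
#'
#' @param calls calls tibble from [call_marks()]`$calls`.
#' @return a ggplot object.
#' @export
plot_mark_calls <- function(calls) {
  ggplot(calls, aes(x = .data$cell_line, y = .data$transcript,
                    fill = .data$pattern)) +
    geom_tile(color = "white") +
    scale_fill_manual(values = c(none = "grey90", K4_only = "#66c2a5",
                                 K27_only = "#fc8d62", both = "#8da0cb")) +
    labs(x = NULL, y = NULL, title = "Histone-mark patterns") +
    theme_minimal()
}

#' Autoplot a one-site saturation fit
#'
#' Observed mean discovery counts with the fitted saturating hyperbola.
#'
#' @param object a `one_site_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.one_site_fit <- function(object, ...) {
  grid <- tibble(X = seq(min(object$data$X), max(object$data$X),
                         length.out = 200))
  grid$Y <- predict(object, grid)
  ggplot(object$data, aes(x = .data$X, y = .data$Y)) +
    geom_point() +
    geom_line(data = grid, color = "#b2182b") +
    labs(x = "samples", y = "transcripts discovered",
         title = sprintf("One-site fit: Bmax = %.1f, Kd = %.1f",
                         object$Bmax, object$Kd)) +
    theme_minimal()
}
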