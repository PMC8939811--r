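# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Significant-gene count versus mapping coverage
#'
#' Scatter of per-mapping significant-gene counts against coverage (the
#' classic more-coverage, more-genes trend), with mapping labels.
#'
#' @param report A `comparison_report`.
#' @return A ggplot object.
#' @export
plot_coverage_trend <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  ggplot2::ggplot(
    report$mappings,
    ggplot2::aes(x = .data$coverage_bp, y = .data$n_sig_genes,
                 label = .data$mapping, colour = .data$kind)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Coverage (bp)", y = "Significant genes",
                  colour = "Mapping kind") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_coverage_trend autoplot method for comparison reports.
#' @param object,... autoplot arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.comparison_report <- function(object, ...) plot_coverage_trend(object)

#' Genuine versus permuted set scores from an EPVP run
#'
#' One bar per gene set: the genuine probit-scale set score against the
#' mean +/- SD of the permutation scores, coloured by validation category.
#'
#' @param object An `epvp_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.epvp_result <- function(object, ...) {
  v <- object$validation
  ggplot2::ggplot(v, ggplot2::aes(x = .data$set_id)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$z_genuine,
                                   fill = .data$category), width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$perm_mean - .data$perm_sd,
                   ymax = .data$perm_mean + .data$perm_sd),
      width = 0.25
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$perm_mean), shape = 21,
                        fill = "white") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Set score (probit scale)",
                  fill = "EPVP category") +
    ggplot2::theme_minimal()
}

#' Iteration trace of an IRED run
#'
#' Set-level gain against the gain of the top-gaining gene still present at
#' each iteration; points with a positive set gain are highlighted, so the
#' number of highlighted points before the first non-positive one (right to
#' left) is the robustness count.
#'
#' @param object An `ired_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ired_trace <- function(object, ...) {
  it <- object$iterations
  ggplot2::ggplot(
    it, ggplot2::aes(x = .data$top_remaining_gain, y = .data$set_gain)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_path(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$set_gain > 0), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "black"),
                                 guide = "none") +
    ggplot2::labs(
      x = "Gain of top remaining gene (adjusted Z)",
      y = "Set gain (probit scale)",
      title = paste0(object$set_id, ": lost after ",
                     object$iterations_to_loss, " removal(s)")
    ) +
    ggplot2::theme_minimal()
}
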