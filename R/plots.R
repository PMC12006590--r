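#' Plot volume-dependency curves
#'
#' Feature value against VOI volume for a set of volume curves, faceted per
#' feature — the graphical form used to judge the three dependency patterns
#' (convergence, correlation, random scatter). Requires ggplot2.
#'
#' @param curves named list from [volume_curves()].
#' @param features subset of feature names to plot (default: all).
#' @param file optional output file (pdf/png via `ggplot2::ggsave`).
#' @return the ggplot object, invisibly.
#' @export
plot_volume_curves <- function(curves, features = names(curves),
                               file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot_volume_curves requires ggplot2")
  dat <- do.call(rbind, lapply(features, function(f)
    cbind(curves[[f]], feature = f)))
  p <- ggplot2::ggplot(dat,
         ggplot2::aes(x = volume_ml, y = value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.6) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "VOI volume (ml)", y = "feature value") +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(file))
    ggplot2::ggsave(file, p, width = 10, height = 8)
  invisible(p)
}
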