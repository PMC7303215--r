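# Figure-style summaries of the burden and permutation results.

#' Plot the 32-cell relative burden grid
#'
#' One point per combination x scope x level cell: relative genetic burden
#' (male over female mean, > 1 means male-enriched) against the rank-sum
#' p-value, with the 0.05 significance line.
#'
#' @param object A `wes_burden_summary` from [relative_burden_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wes_burden_summary <- function(object, ...) {
  dat <- object[is.finite(object$relative_burden), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$relative_burden, y = .data$p,
                                    colour = .data$enriched_sex,
                                    shape = .data$level)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$scope)) +
    ggplot2::scale_y_continuous(trans = "log10") +
    ggplot2::labs(x = "relative genetic burden (male / female)",
                  y = "Wilcoxon p-value", colour = "enriched",
                  shape = "level") +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' Histogram of the permuted rank-sum statistics with the observed value
#' marked.
#'
#' @param object A `wes_perm` from [permutation_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wes_perm <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$w)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_w, colour = "red") +
    ggplot2::labs(x = "permuted rank-sum statistic W", y = "count",
                  subtitle = sprintf("C/T = %d/%d = %.4g", object$c,
                                     object$t, object$p_perm)) +
    ggplot2::theme_minimal()
}

#' Render the relative-burden figure to a file
#'
#' @param summary A `wes_burden_summary`.
#' @param path Output image path (format from the extension).
#' @param width,height Figure size in inches.
#' @return `path`, invisibly.
#' @export
render_burden_figure <- function(summary, path, width = 7, height = 4) {
  if (nrow(summary) == 0) abort("empty relative-burden table")
  p <- autoplot(summary)
  ggplot2::ggsave(path, p, width = width, height = height)
  invisible(path)
}
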