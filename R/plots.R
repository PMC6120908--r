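# ggplot2 displays for the result types.

#' Plot a precision-recall curve
#' @param object A `pr_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = sprintf("Precision-recall curve (AP = %.3f)",
                      average_precision(object))
    )
}

#' Plot the validation-AP trace of an adaptive search
#'
#' AP as a function of group size k, one line per window increment W,
#' faceted by window size M.
#'
#' @param object An `snp_search` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snp_search <- function(object, ...) {
  ggplot2::ggplot(object$ap_trace,
                  ggplot2::aes(x = .data$k, y = .data$ap,
                               colour = factor(.data$W),
                               group = factor(.data$W))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~M, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Group size k", y = "Validation AP",
                  colour = "W",
                  title = "Adaptive search: validation AP by (M, W, k)")
}

#' Plot per-split AP distributions from repeated nested CV
#' @param object An `snp_cv` tibble (one or more methods bound together).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snp_cv <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$method, y = 100 * .data$ap)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "Test AP (x100)",
                  title = "Per-split test AP by method")
}

#' Plot a top-k AP curve
#' @param curve Tibble with columns k and ap (e.g. from
#'   [evaluate_topk_curve()]) or k and map (from [er_subtype_task()]).
#' @return A ggplot.
#' @export
plot_topk_curve <- function(curve) {
  ycol <- if ("ap" %in% names(curve)) "ap" else "map"
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Number of top-ranked SNPs",
                  y = if (ycol == "ap") "AP" else "mAP (x100)")
}
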