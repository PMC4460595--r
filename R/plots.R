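#' Plot a feature-threshold sweep
#'
#' Feature value against pyramid threshold, one panel per feature (free y
#' scales: counts, coefficients and energies live on different scales), one
#' line per family.
#'
#' @param object A `gp_sweep` tibble from [feature_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gp_sweep <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$t, y = .data$value, colour = .data$family)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free_y") +
    ggplot2::labs(
      x = "edge-weight threshold t", y = "feature value",
      title = "Graph-structured features across pyramid levels"
    )
}

#' Plot ROC sweep results
#'
#' @param object A `gp_roc` tibble from [roc_sweep()] (rows from several
#'   features can be combined with `dplyr::bind_rows()`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gp_roc <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$feature)
  ) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = "ROC sweep over secondary thresholds"
    )
}

#' Plot per-family decision outcomes
#'
#' @param object A `gp_eval` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A ggplot object: stacked per-family counts of correct, wrong and
#'   undecided queries.
#' @export
autoplot.gp_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_family,
    cols = c("cd", "wd", "nd"),
    names_to = "status", values_to = "count"
  )
  long$status <- factor(long$status, levels = c("cd", "wd", "nd"))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$family, y = .data$count, fill = .data$status)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "family", y = "queries",
      title = "Decisions per family (correct / wrong / none)"
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
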