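#' Tidy a trained model
#'
#' @param x A `gp_model`.
#' @param ... Unused.
#' @return One row per family: member and positive-edge counts plus weight
#'   summaries.
#' @export
tidy.gp_model <- function(x, ...) {
  purrr::map_dfr(x$families, function(g) {
    up <- g$weights[upper.tri(g$weights)]
    tibble(
      family = g$label,
      n_members = length(g$ids),
      n_edges = sum(up > 0),
      max_weight = if (length(up)) max(up) else 0,
      mean_weight = if (any(up > 0)) mean(up[up > 0]) else NA_real_
    )
  })
}

#' @rdname tidy.gp_model
#' @export
glance.gp_model <- function(x, ...) {
  tibble(
    n_families = length(x$families),
    n_sequences = sum(vapply(x$families, function(g) length(g$ids), integer(1))),
    n_levels = x$config$n_levels,
    max_threshold = max(x$config$global_ladder),
    k = x$config$k,
    p = x$config$p
  )
}

#' Tidy an evaluation report
#'
#' @param x A `gp_eval` from [evaluate_predictions()].
#' @param ... Unused.
#' @return `tidy()`: per-family cd/wd/nd counts; `glance()`: one-row summary
#'   with precision, accuracy and the misclassified (wd) count.
#' @export
tidy.gp_eval <- function(x, ...) {
  x$per_family
}

#' @rdname tidy.gp_eval
#' @export
glance.gp_eval <- function(x, ...) {
  tibble(
    n = x$n, cd = x$cd, wd = x$wd, nd = x$nd,
    precision = x$precision, accuracy = x$accuracy,
    misclassified = x$wd,
    feature_evaluations = x$feature_evaluations
  )
}
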