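#' Score predictions against known labels
#'
#' Tallies every query as a correct decision (cd), wrong decision (wd) or no
#' decision (nd, for `NA` predictions — an undecided query is never counted
#' as wrong), and computes precision `cd / (cd + wd)`. When every query is
#' undecided the precision is reported as `NA` rather than 0.
#'
#' @param predictions A `gp_predictions` tibble (or any data frame with
#'   `query_id` and `predicted`).
#' @param truth Data frame with columns `query_id`, `family_id`.
#' @return An object of class `gp_eval`: a list with counts `cd`, `wd`,
#'   `nd`, `n`, `precision`, `accuracy` (`cd / n`), total
#'   `feature_evaluations` (if available), a `per_family` tibble and the
#'   per-query `decisions` tibble.
#' @export
evaluate_predictions <- function(predictions, truth) {
  stopifnot(
    is.data.frame(predictions), is.data.frame(truth),
    all(c("query_id", "family_id") %in% names(truth))
  )
  missing <- setdiff(predictions$query_id, truth$query_id)
  if (length(missing)) {
    abort(
      sprintf(
        "no truth label for quer%s %s.",
        if (length(missing) > 1) "ies" else "y",
        paste(head(missing, 5L), collapse = ", ")
      ),
      class = "ppsnet_input_error"
    )
  }
  decisions <- predictions %>%
    select(dplyr::any_of(c("query_id", "predicted", "tie_path", "n_evaluations"))) %>%
    left_join(
      truth %>% mutate(query_id = as.character(.data$query_id)) %>%
        select("query_id", truth = "family_id"),
      by = "query_id"
    ) %>%
    mutate(status = dplyr::case_when(
      is.na(.data$predicted) ~ "nd",
      .data$predicted == .data$truth ~ "cd",
      TRUE ~ "wd"
    ))
  cd <- sum(decisions$status == "cd")
  wd <- sum(decisions$status == "wd")
  nd <- sum(decisions$status == "nd")
  per_family <- decisions %>%
    count(.data$truth, .data$status) %>%
    tidyr::pivot_wider(
      names_from = "status", values_from = "n",
      values_fill = 0L
    )
  for (col in c("cd", "wd", "nd")) {
    if (!col %in% names(per_family)) per_family[[col]] <- 0L
  }
  per_family <- per_family %>%
    rename(family = "truth") %>%
    select("family", "cd", "wd", "nd") %>%
    arrange(.data$family)
  structure(
    list(
      cd = cd, wd = wd, nd = nd, n = nrow(decisions),
      precision = if (cd + wd > 0) cd / (cd + wd) else NA_real_,
      accuracy = if (nrow(decisions) > 0) cd / nrow(decisions) else NA_real_,
      feature_evaluations = if ("n_evaluations" %in% names(decisions)) {
        sum(decisions$n_evaluations)
      } else {
        NA_integer_
      },
      per_family = per_family,
      decisions = decisions
    ),
    class = "gp_eval"
  )
}

#' @export
print.gp_eval <- function(x, ...) {
  cat(sprintf(
    "<gp_eval: %d queries | cd %d, wd %d, nd %d | precision %s, accuracy %.3f>\n",
    x$n, x$cd, x$wd, x$nd,
    if (is.na(x$precision)) "NA" else sprintf("%.3f", x$precision),
    x$accuracy
  ))
  invisible(x)
}

#' Score-statistic baseline classifiers
#'
#' The non-structural baselines: each query is assigned to the family whose
#' member scores maximise a simple statistic of the query's nonzero EB-scores
#' to that family — the single best score (`"max"`), their sum, or their
#' mean. Families the query has no edge to are excluded; a query with no
#' edges at all is undecided. Ties are broken by ascending label.
#'
#' @param model A `gp_model` (only the family memberships are used).
#' @param query_scores Scores linking queries to members (see [classify()]).
#' @param queries Query ids; default every non-member id in `query_scores`.
#' @param stat One of `"max"`, `"sum"`, `"mean"`.
#' @return A tibble with columns `query_id`, `predicted` (`NA` when
#'   undecided) and `score`.
#' @export
score_baseline <- function(model, query_scores, queries = NULL,
                           stat = c("max", "sum", "mean")) {
  stat <- match.arg(stat)
  fn <- switch(stat, max = max, sum = sum, mean = mean)
  table <- as_score_table(query_scores)
  idx <- pair_index(table)
  if (is.null(queries)) {
    queries <- sort(setdiff(
      unique(c(table$id_a, table$id_b)), model_member_ids(model)
    ))
  }
  labels <- model_labels(model)
  purrr::map_dfr(as.character(queries), function(qid) {
    vals <- vapply(labels, function(lab) {
      eb <- lookup_idx(idx, qid, model$families[[lab]]$ids)
      eb <- eb[eb > 0]
      if (length(eb)) fn(eb) else -Inf
    }, numeric(1))
    best <- max(vals)
    if (!is.finite(best)) {
      tibble(query_id = qid, predicted = NA_character_, score = NA_real_)
    } else {
      tibble(
        query_id = qid,
        predicted = sort(labels[vals == best])[1L],
        score = best
      )
    }
  })
}

#' Count feature evaluations of the two voting schemes
#'
#' Classifies the same queries with the hierarchical funnel and with plain
#' majority voting and reports the total number of (feature, class, level)
#' delta evaluations each performed — a machine-independent proxy for
#' testing cost. Counts are deterministic for a fixed model and query set.
#'
#' @inheritParams classify
#' @return A tibble with columns `scheme`, `evaluations`, `queries`.
#' @export
compare_efficiency <- function(model, query_scores, queries = NULL) {
  hier <- classify(model, query_scores, queries = queries)
  maj <- classify(model, query_scores, queries = queries, method = "majority")
  tibble(
    scheme = c("hierarchical", "majority"),
    evaluations = c(sum(hier$n_evaluations), sum(maj$n_evaluations)),
    queries = nrow(hier)
  )
}

single_feature_classify <- function(model, idx, queries, feature, secondary) {
  purrr::map_dfr(queries, function(qid) {
    atts <- query_attachments_for(model, idx, qid)
    ctx <- new_eval_ctx()
    ps <- pyramid_search_impl(model, ctx, atts, model_labels(model), feature,
      secondary = secondary
    )
    pred <- if (length(ps$labels)) {
      k_max_candidates(ps$deltas[ps$labels] - secondary, 1L)
    } else {
      character(0)
    }
    tibble(
      query_id = qid,
      predicted = if (length(pred)) pred else NA_character_
    )
  })
}

#' Sweep operating points into an ROC curve
#'
#' Classifies the queries once per secondary-threshold grid point and turns
#' the correct/wrong tallies into micro-averaged one-vs-rest rates: the true
#' positive rate is `cd / n` and the false positive rate `wd / (n * (M - 1))`
#' over `M` families. `feature = "combined"` sweeps the full classifier over
#' a `(T_AC, T_RC)` grid; a single feature name sweeps that feature's
#' standalone argmax classifier over its secondary threshold.
#'
#' @param model A `gp_model`.
#' @param query_scores Query scores (see [classify()]).
#' @param truth Data frame `query_id`, `family_id`.
#' @param t_ac_grid,t_rc_grid Secondary-threshold grids (for a single
#'   feature, only `t_ac_grid` is used).
#' @param feature `"combined"` or one of `"AC"`, `"RC"`, `"SM"`, `"TR"`,
#'   `"GE"`.
#' @return A tibble of class `gp_roc` with columns `feature`, `T_ac`,
#'   `T_rc`, `cd`, `wd`, `nd`, `tpr`, `fpr`, sorted by `fpr`.
#' @export
roc_sweep <- function(model, query_scores, truth,
                      t_ac_grid = c(0, 0.02, 0.05, 0.1),
                      t_rc_grid = 0, feature = "combined") {
  stopifnot(feature %in% c("combined", gsf_names()))
  n_other <- length(model$families) - 1L
  if (n_other < 1L) {
    abort("ROC rates need at least two families.", class = "ppsnet_model_error")
  }
  rate_row <- function(preds, T_ac, T_rc) {
    rep <- evaluate_predictions(preds, truth)
    tibble(
      feature = feature, T_ac = T_ac, T_rc = T_rc,
      cd = rep$cd, wd = rep$wd, nd = rep$nd,
      tpr = rep$cd / rep$n, fpr = rep$wd / (rep$n * n_other)
    )
  }
  rows <- if (feature == "combined") {
    grid <- tidyr::expand_grid(T_ac = t_ac_grid, T_rc = t_rc_grid)
    purrr::pmap_dfr(grid, function(T_ac, T_rc) {
      m <- model
      m$config$T_ac <- T_ac
      m$config$T_rc <- T_rc
      rate_row(classify(m, query_scores), T_ac, T_rc)
    })
  } else {
    table <- as_score_table(query_scores)
    idx <- pair_index(table)
    queries <- sort(setdiff(
      unique(c(table$id_a, table$id_b)), model_member_ids(model)
    ))
    purrr::map_dfr(t_ac_grid, function(T_f) {
      rate_row(
        single_feature_classify(model, idx, queries, feature, T_f),
        T_f, NA_real_
      )
    })
  }
  structure(arrange(rows, .data$fpr), class = c("gp_roc", class(tibble())))
}
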