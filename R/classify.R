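# pair-indexed lookup: one hashed environment per classify() call so that
# per-query attachment extraction is O(N) rather than O(table size)
pair_index <- function(table) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(table)) {
    vals <- as.list(table$eb)
    names(vals) <- paste(table$id_a, table$id_b, sep = "\r")
    list2env(vals, env)
  }
  env
}

lookup_idx <- function(idx, a, ids) {
  if (length(ids) == 0L) {
    return(numeric(0))
  }
  keys <- paste(pmin(a, ids), pmax(a, ids), sep = "\r")
  unlist(mget(keys, envir = idx, ifnotfound = 0), use.names = FALSE)
}

as_score_table <- function(query_scores) {
  if (inherits(query_scores, "pps_similarity")) {
    return(query_scores)
  }
  stopifnot(is.data.frame(query_scores))
  if (all(c("id_a", "id_b", "eb") %in% names(query_scores))) {
    query_scores <- filter(query_scores, .data$id_a != .data$id_b, .data$eb > 0)
    if (nrow(query_scores) == 0L) {
      return(new_similarity_table(tibble(
        id_a = character(), id_b = character(), eb = numeric()
      )))
    }
    df <- query_scores %>%
      mutate(
        a = pmin(as.character(.data$id_a), as.character(.data$id_b)),
        b = pmax(as.character(.data$id_a), as.character(.data$id_b))
      ) %>%
      group_by(.data$a, .data$b) %>%
      summarise(eb = max(.data$eb), .groups = "drop") %>%
      rename(id_a = "a", id_b = "b")
    return(new_similarity_table(df))
  }
  if (all(c("query_id", "subject_id", "evalue", "bitscore") %in% names(query_scores))) {
    return(similarity_table(query_scores))
  }
  abort("`query_scores` must be a similarity table, an (id_a, id_b, eb) frame or a hit table.",
    class = "ppsnet_input_error"
  )
}

query_attachments_for <- function(model, idx, query_id) {
  lapply(model$families, function(g) {
    setNames(lookup_idx(idx, query_id, g$ids), g$ids)
  })
}

# ---- hierarchical voting ----------------------------------------------------

classify_query_impl <- function(model, ctx, attachments) {
  cfg <- model$config
  all_classes <- model_labels(model)
  ac <- pyramid_search_impl(model, ctx, attachments, all_classes, "AC",
    secondary = cfg$T_ac
  )
  t_star <- c(
    AC = ac$t_star, RC = NA_real_, SM = NA_real_,
    TR = NA_real_, GE = NA_real_
  )
  if (length(ac$labels) == 0L) {
    # the query interacts with nothing at any AC level: rely on energy alone
    ge <- ge_stage(model, ctx, attachments, all_classes, cfg$k)
    t_star["GE"] <- ge$t_star
    predicted <- k_max_candidates(ge$deltas, 1L)
    return(list(
      predicted = if (length(predicted)) predicted else NA_character_,
      candidates = list(
        AC = character(0), RC = character(0), SM = character(0),
        TR = character(0), GE = ge$labels
      ),
      t_star = t_star,
      votes = ge$labels,
      tie_path = "ge_only",
      n_evaluations = ctx$count
    ))
  }
  rc <- pyramid_search_impl(model, ctx, attachments, ac$labels, "RC",
    secondary = cfg$T_rc
  )
  sm <- kmax_stage(model, ctx, attachments, rc$labels, "SM", cfg$k)
  tr <- kmax_stage(model, ctx, attachments, rc$labels, "TR", cfg$k)
  ge_pool <- sort(union(sm$labels, tr$labels))
  ge <- ge_stage(model, ctx, attachments, ge_pool, cfg$k)
  t_star[c("RC", "SM", "TR", "GE")] <- c(rc$t_star, sm$t_star, tr$t_star, ge$t_star)
  votes <- Reduce(multiset_sum, list(ac$labels, rc$labels, sm$labels, tr$labels, ge$labels))
  psi <- mode_labels(votes)
  tie_path <- "none"
  predicted <- NA_character_
  if (length(psi) == 1L) {
    predicted <- psi
  } else {
    # indecisive: re-vote SM and TR with k = 1 (cached deltas, no new work)
    tie_path <- "kmax1"
    sm1 <- k_max_candidates(sm$deltas, 1L)
    tr1 <- k_max_candidates(tr$deltas, 1L)
    votes2 <- Reduce(multiset_sum, list(sm1, tr1, ge$labels))
    psi2 <- if (length(votes2)) mode_labels(votes2) else character(0)
    if (length(psi2) == 1L) {
      predicted <- psi2
    } else {
      # persistent tie: the energy delta alone arbitrates
      tie_path <- "ge_fallback"
      best <- k_max_candidates(ge$deltas, 1L)
      predicted <- if (length(best)) best else NA_character_
    }
  }
  list(
    predicted = predicted,
    candidates = list(
      AC = ac$labels, RC = rc$labels, SM = sm$labels,
      TR = tr$labels, GE = ge$labels
    ),
    t_star = t_star,
    votes = votes,
    tie_path = tie_path,
    n_evaluations = ctx$count
  )
}

# ---- majority-voting baseline ----------------------------------------------

majority_stage <- function(model, ctx, attachments, feature) {
  cfg <- model$config
  classes <- model_labels(model)
  ladder <- cfg$ladders[[feature]]
  if (feature == "GE" && !cfg$ge_descend) {
    ladder <- min(ladder)
  }
  len <- length(ladder)
  for (i in rev(seq_len(len))) {
    t <- ladder[i]
    r <- if (feature == "RC") rc_r_at(cfg, i, len) else 0L
    deltas <- vapply(
      classes,
      function(cl) delta_eval(model, ctx, attachments, cl, feature, t, r, cfg$p),
      numeric(1)
    )
    names(deltas) <- classes
    if (any(deltas > 0)) {
      return(list(vote = k_max_candidates(deltas, 1L), t_star = t))
    }
  }
  list(vote = character(0), t_star = min(ladder))
}

majority_query_impl <- function(model, ctx, attachments) {
  stages <- lapply(setNames(gsf_names(), gsf_names()), function(f) {
    majority_stage(model, ctx, attachments, f)
  })
  votes <- unlist(lapply(stages, `[[`, "vote"), use.names = FALSE)
  predicted <- NA_character_
  tie_path <- "none"
  if (length(votes)) {
    psi <- mode_labels(votes)
    if (length(psi) == 1L) predicted <- psi else tie_path <- "tie"
  } else {
    tie_path <- "no_votes"
  }
  list(
    predicted = predicted,
    candidates = lapply(stages, `[[`, "vote"),
    t_star = vapply(stages, `[[`, numeric(1), "t_star"),
    votes = votes,
    tie_path = tie_path,
    n_evaluations = ctx$count
  )
}

# ---- user-facing verbs ------------------------------------------------------

#' Classify query sequences against a trained model
#'
#' For each query, hierarchical voting funnels the candidate families through
#' the five features: clustering shortlists families at the highest pyramid
#' level where the query interacts (`t*`), the rich club refines that
#' shortlist, star motifs and triangles each vote for the `k` most influenced
#' shortlisted families, and graph energy votes among those at the bottom of
#' the pyramid. The final label is the mode of the pooled votes, with a
#' two-step tie-break (k = 1 re-vote, then the energy delta alone). A query
#' whose votes cannot name a unique family yields `NA` (no decision) rather
#' than a guess.
#'
#' With `update = TRUE` queries are processed in order and every decided
#' query is attached to its predicted family graph before the next query is
#' classified (instance-based incremental learning). Threshold ladders are
#' fixed at training time and are not re-quantized by updates.
#'
#' @param model A `gp_model` from [train_model()].
#' @param query_scores Scores linking queries to training members: a
#'   `pps_similarity` table, a data frame with `id_a`, `id_b`, `eb`, or a raw
#'   hit table. Query-query scores are used only when `update = TRUE` (an
#'   added query becomes a member later queries can match).
#' @param queries Character vector of query ids; default every id present in
#'   `query_scores` that is not a model member. Processing order matters in
#'   incremental mode.
#' @param method `"hierarchical"` (the pyramid funnel) or `"majority"` (every
#'   feature scans all families independently, then simple majority voting).
#' @param update Apply incremental learning after each decided query.
#' @param update_only_confident Only update on tie-free decisions.
#' @return A tibble of class `gp_predictions` with one row per query:
#'   `query_id`, `predicted` (`NA` = no decision), `tie_path`,
#'   `t_star_ac` ... `t_star_ge`, `n_evaluations` and list-columns
#'   `candidates`, `votes`. When `update = TRUE`, the updated model is
#'   attached as `attr(result, "model")`.
#' @seealso [evaluate_predictions()], [compare_efficiency()]
#' @export
classify <- function(model, query_scores, queries = NULL,
                     method = c("hierarchical", "majority"),
                     update = FALSE, update_only_confident = FALSE) {
  stopifnot(inherits(model, "gp_model"))
  if (length(model$families) == 0L) {
    abort("empty model: no families to classify against.",
      class = "ppsnet_model_error"
    )
  }
  method <- match.arg(method)
  table <- as_score_table(query_scores)
  idx <- pair_index(table)
  if (is.null(queries)) {
    queries <- sort(setdiff(
      unique(c(table$id_a, table$id_b)),
      model_member_ids(model)
    ))
  }
  queries <- as.character(queries)
  impl <- if (method == "hierarchical") classify_query_impl else majority_query_impl
  rows <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    qid <- queries[qi]
    atts <- query_attachments_for(model, idx, qid)
    ctx <- new_eval_ctx()
    res <- impl(model, ctx, atts)
    rows[[qi]] <- tibble(
      query_id = qid,
      predicted = res$predicted,
      tie_path = res$tie_path,
      t_star_ac = unname(res$t_star["AC"]),
      t_star_rc = unname(res$t_star["RC"]),
      t_star_sm = unname(res$t_star["SM"]),
      t_star_tr = unname(res$t_star["TR"]),
      t_star_ge = unname(res$t_star["GE"]),
      n_evaluations = res$n_evaluations,
      candidates = list(res$candidates),
      votes = list(res$votes)
    )
    if (update && !is.na(res$predicted) &&
      (!update_only_confident || res$tie_path == "none")) {
      model <- incremental_update(
        model, qid, res$predicted,
        atts[[res$predicted]]
      )
    }
  }
  out <- bind_rows(rows)
  out <- structure(out, class = c("gp_predictions", class(tibble())))
  attr(out, "method") <- method
  if (update) attr(out, "model") <- model
  out
}

#' Majority-voting baseline classifier
#'
#' Convenience wrapper for `classify(method = "majority")`: every feature
#' scans all families over its own ladder and nominates its single most
#' influenced class; the prediction is the mode of the (at most five) votes,
#' with ties yielding no decision. Used as the non-hierarchical reference for
#' accuracy and efficiency comparisons.
#'
#' @inheritParams classify
#' @return A `gp_predictions` tibble.
#' @export
majority_classify <- function(model, query_scores, queries = NULL) {
  classify(model, query_scores, queries = queries, method = "majority")
}

#' Add a classified query to its predicted family
#'
#' Instance-based incremental learning: the query becomes a new vertex of the
#' predicted family's graph, with its EB-scores as the new edge weights. All
#' other families are untouched, and the result is identical to rebuilding
#' the family graph from scratch on the enlarged member list. Undecided
#' queries cannot be added.
#'
#' @param model A `gp_model`.
#' @param query_id Query sequence id.
#' @param predicted One of the model's family labels (not `NA`).
#' @param scores The query's EB-scores against the predicted family: a named
#'   numeric vector over that family's member ids, or a similarity table to
#'   look them up from.
#' @return A new `gp_model`; the input model is not modified.
#' @export
incremental_update <- function(model, query_id, predicted, scores) {
  stopifnot(inherits(model, "gp_model"))
  if (is.na(predicted) || !predicted %in% model_labels(model)) {
    abort("`predicted` must be a decided model label (no-decision results cannot update).",
      class = "ppsnet_model_error"
    )
  }
  g <- model$families[[predicted]]
  eb <- if (is.numeric(scores)) {
    scores
  } else {
    query_attachment(as_score_table(scores), g, query_id)
  }
  new_g <- attach_query(g, eb, query_id = query_id)
  new_cache <- new.env(parent = emptyenv())
  for (lab in ls(model$cache)) {
    if (lab != predicted) {
      assign(lab, get(lab, envir = model$cache), envir = new_cache)
    }
  }
  model$families[[predicted]] <- new_g
  model$cache <- new_cache
  model$provenance$n_sequences <- model$provenance$n_sequences + 1L
  model
}

#' Grid-search the secondary thresholds on validation data
#'
#' Classifies a validation split at each `(T_AC, T_RC)` grid point and
#' reports the resulting correct/wrong/no-decision counts and precision.
#'
#' @param model A `gp_model`.
#' @param query_scores Validation query scores (see [classify()]).
#' @param truth Data frame with columns `query_id`, `family_id`.
#' @param t_ac_grid,t_rc_grid Numeric vectors of secondary thresholds.
#' @return A tibble with one row per grid point (`T_ac`, `T_rc`, `cd`, `wd`,
#'   `nd`, `precision`), with the best row (highest precision, then fewest
#'   `nd`) as attribute `"best"`.
#' @export
tune_secondary <- function(model, query_scores, truth,
                           t_ac_grid = c(0, 0.01, 0.05),
                           t_rc_grid = c(0, 0.01, 0.05)) {
  grid <- tidyr::expand_grid(T_ac = t_ac_grid, T_rc = t_rc_grid)
  rows <- purrr::pmap_dfr(grid, function(T_ac, T_rc) {
    m <- model
    m$config$T_ac <- T_ac
    m$config$T_rc <- T_rc
    preds <- classify(m, query_scores)
    rep <- evaluate_predictions(preds, truth)
    tibble(
      T_ac = T_ac, T_rc = T_rc, cd = rep$cd, wd = rep$wd, nd = rep$nd,
      precision = rep$precision
    )
  })
  best <- rows %>% arrange(desc(.data$precision), .data$nd, .data$T_ac, .data$T_rc)
  attr(rows, "best") <- best[1, ]
  rows
}
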