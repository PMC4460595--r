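#' Configuration of the graph pyramid classifier
#'
#' The pyramid quantizes the EB-score range of the training graphs into
#' `n_levels` uniformly spaced thresholds over `(0, max edge weight]`; each
#' feature operates on a contiguous slice of that ladder. By default (with
#' `n_levels = 10`): clustering (AC) and rich-club (RC) work on the upper
#' half (levels 6-10) where they are most precise, star motifs (SM) and
#' triangles (TR) on the middle band (levels 3-7), and graph energy (GE) on
#' the lowest levels (1-2) where the graphs are dense enough for the spectrum
#' to be informative.
#'
#' @param n_levels Number of pyramid levels (>= 2).
#' @param T_ac,T_rc Secondary thresholds: a class qualifies at a level only
#'   if its feature delta strictly exceeds the secondary threshold. Defaults 0.
#' @param p Star power used by SM (default 2).
#' @param r_low,r_high Rich-club degree cuts for the lower and upper halves
#'   of the RC ladder (defaults 3 and 5; the switch happens at the RC
#'   ladder's midpoint).
#' @param k Number of classes kept by the k-max stages (default 3).
#' @param slices Optional named list (`AC`, `RC`, `SM`, `TR`, `GE`) of level
#'   indices into the global ladder, overriding the default slices.
#' @param weighted_ge Compute graph energy on the surviving weighted
#'   adjacency instead of the binary one. Default `FALSE`.
#' @param ge_descend Let the GE stage descend its ladder like the others
#'   instead of evaluating only at its lowest level. Default `FALSE`.
#' @return An object of class `pyramid_config`. Ladders are filled in by
#'   [train_model()] / [build_thresholds()].
#' @export
pyramid_config <- function(n_levels = 10L, T_ac = 0, T_rc = 0, p = 2L,
                           r_low = 3L, r_high = 5L, k = 3L, slices = NULL,
                           weighted_ge = FALSE, ge_descend = FALSE) {
  stopifnot(n_levels >= 2L, p >= 1L, r_low >= 0L, r_high >= 0L, k >= 1L)
  structure(
    list(
      n_levels = as.integer(n_levels), T_ac = T_ac, T_rc = T_rc,
      p = as.integer(p), r_low = as.integer(r_low),
      r_high = as.integer(r_high), k = as.integer(k),
      slices = slices, weighted_ge = isTRUE(weighted_ge),
      ge_descend = isTRUE(ge_descend),
      global_ladder = NULL, ladders = NULL
    ),
    class = "pyramid_config"
  )
}

default_slices <- function(n) {
  list(
    AC = seq.int(floor(n / 2) + 1L, n),
    RC = seq.int(floor(n / 2) + 1L, n),
    SM = seq.int(max(1L, floor(0.2 * n) + 1L), min(n, ceiling(0.7 * n))),
    TR = seq.int(max(1L, floor(0.2 * n) + 1L), min(n, ceiling(0.7 * n))),
    GE = seq.int(1L, max(1L, floor(0.2 * n)))
  )
}

#' Build threshold ladders from training graphs
#'
#' The global ladder is `n_levels` uniformly spaced values over
#' `(0, w_max]` where `w_max` is the largest edge weight across all training
#' graphs; per-feature ladders are contiguous slices of it (see
#' [pyramid_config()]).
#'
#' @param graphs A list of `family_graph` objects.
#' @param n_levels Number of levels (>= 2).
#' @param slices Optional per-feature level-index slices.
#' @return A list with `global_ladder` (ascending numeric vector) and
#'   `ladders` (named list of ascending per-feature ladders).
#' @examples
#' g <- example_clustered_graph()
#' build_thresholds(list(g), n_levels = 5)$global_ladder
#' @export
build_thresholds <- function(graphs, n_levels, slices = NULL) {
  stopifnot(n_levels >= 2L)
  w_max <- max(vapply(graphs, function(g) max(g$weights), numeric(1)))
  if (w_max <= 0) {
    abort("all training edge weights are zero: no pyramid can be built.",
      class = "ppsnet_model_error"
    )
  }
  global <- w_max * seq_len(n_levels) / n_levels
  slices <- slices %||% default_slices(n_levels)
  if (!all(gsf_names() %in% names(slices))) {
    abort("`slices` must name AC, RC, SM, TR and GE.", class = "ppsnet_input_error")
  }
  ladders <- lapply(slices[gsf_names()], function(ix) {
    ix <- sort(unique(as.integer(ix)))
    if (any(ix < 1L | ix > n_levels)) {
      abort("slice indices must lie within the global ladder.",
        class = "ppsnet_input_error"
      )
    }
    global[ix]
  })
  list(global_ladder = global, ladders = ladders)
}

#' Train a graph pyramid model
#'
#' Builds one similarity graph per family from the training scores and
#' quantizes the observed EB range into the threshold ladders.
#'
#' @param table A `pps_similarity` table of training-vs-training scores.
#' @param families A data frame mapping `seq_id` to `family_id`.
#' @param config A [pyramid_config()].
#' @return An object of class `gp_model` with fields `families` (named list
#'   of `family_graph`), `config` (ladders filled in) and `provenance`.
#' @export
train_model <- function(table, families, config = pyramid_config()) {
  stopifnot(is.data.frame(families), inherits(config, "pyramid_config"))
  if (!all(c("seq_id", "family_id") %in% names(families))) {
    abort("`families` must have columns seq_id and family_id.",
      class = "ppsnet_input_error"
    )
  }
  fam_split <- split(as.character(families$seq_id), as.character(families$family_id))
  labels <- sort(names(fam_split))
  graphs <- lapply(labels, function(lab) family_graph(table, fam_split[[lab]], lab))
  names(graphs) <- labels
  th <- build_thresholds(graphs, config$n_levels, config$slices)
  config$global_ladder <- th$global_ladder
  config$ladders <- th$ladders
  structure(
    list(
      families = graphs, config = config,
      provenance = list(
        n_families = length(graphs),
        n_sequences = length(unique(families$seq_id)),
        format_version = 1L
      ),
      cache = new.env(parent = emptyenv())
    ),
    class = "gp_model"
  )
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf(
    "<gp_model: %d families, %d sequences, %d pyramid levels (max EB %.4g)>\n",
    length(x$families),
    sum(vapply(x$families, function(g) length(g$ids), integer(1))),
    x$config$n_levels, max(x$config$global_ladder)
  ))
  invisible(x)
}

model_labels <- function(model) names(model$families)

model_member_ids <- function(model) {
  unlist(lapply(model$families, `[[`, "ids"), use.names = FALSE)
}

# rich-club cut for ladder position i (1 = lowest) of a ladder of length len:
# low cut below the midpoint, high cut at and above it.
rc_r_at <- function(config, i, len) {
  if (i > len / 2) config$r_high else config$r_low
}

# ---- evaluation context: per-query memo + model-level base-value cache ------

new_eval_ctx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$memo <- new.env(parent = emptyenv())
  ctx$count <- 0L
  ctx
}

family_cache <- function(model, label) {
  env <- get0(label, envir = model$cache, inherits = FALSE)
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    assign(label, env, envir = model$cache)
  }
  env
}

# thresholded family adjacency (binary, or weighted for the GE variant),
# cached per (family, level) since the training graphs are fixed
family_adjacency <- function(model, label, t, weighted = FALSE) {
  env <- family_cache(model, label)
  key <- paste(if (weighted) "wadj" else "adj", as.character(t), sep = "|")
  a <- get0(key, envir = env, inherits = FALSE)
  if (is.null(a)) {
    w <- model$families[[label]]$weights
    keep <- w >= t & w > 0
    a <- if (weighted) unname(w) * keep else keep * 1
    assign(key, a, envir = env)
  }
  a
}

family_base_value <- function(model, label, feature, t, r, p) {
  env <- family_cache(model, label)
  key <- paste(feature, as.character(t), r, p, sep = "|")
  val <- get0(key, envir = env, inherits = FALSE)
  if (is.null(val)) {
    weighted <- feature == "GE" && model$config$weighted_ge
    val <- feature_on_adjacency(
      family_adjacency(model, label, t, weighted),
      feature,
      r = r, p = p
    )
    assign(key, val, envir = env)
  }
  val
}

# one (feature, class, level) evaluation; memoized per query so tie-break
# recomputations are free and counted once. The augmented adjacency is
# assembled directly from the cached family adjacency and the thresholded
# attachment row, which is equivalent to attach_query() + threshold_view()
# but skips rebuilding the weighted graph each time.
delta_eval <- function(model, ctx, attachments, label, feature, t,
                       r = 0L, p = 2L) {
  key <- paste(feature, label, as.character(t), r, p, sep = "|")
  val <- get0(key, envir = ctx$memo, inherits = FALSE)
  if (!is.null(val)) {
    return(val)
  }
  base <- family_base_value(model, label, feature, t, r, p)
  weighted <- feature == "GE" && model$config$weighted_ge
  a <- family_adjacency(model, label, t, weighted)
  eb <- unname(attachments[[label]])
  q <- if (weighted) eb * (eb >= t & eb > 0) else (eb >= t & eb > 0) * 1
  aug <- rbind(cbind(a, q), c(q, 0), deparse.level = 0)
  val <- feature_on_adjacency(aug, feature, r = r, p = p) - base
  assign(key, val, envir = ctx$memo)
  ctx$count <- ctx$count + 1L
  val
}

# ---- search primitives ------------------------------------------------------

#' Graph pyramid search
#'
#' Scans a feature's threshold ladder from the top down. At the first level
#' where at least one candidate class's feature delta strictly exceeds the
#' secondary threshold, all such classes are returned together with that
#' level `t*`; if no level qualifies, the candidate set is empty and `t*` is
#' the ladder minimum. Strong matches therefore qualify high in the pyramid
#' (global features), weak ones low (local features).
#'
#' @param model A `gp_model`.
#' @param attachments Named list (one element per model family) of query
#'   EB vectors, as built by [query_attachment()].
#' @param classes Candidate class labels (subset of the model's labels).
#' @param feature One of `"AC"`, `"RC"`, `"SM"`, `"TR"`, `"GE"`.
#' @param ladder Ascending threshold vector; default the feature's ladder
#'   from the model config.
#' @param secondary Secondary threshold; a class qualifies only when
#'   `delta > secondary`. Default 0.
#' @return A list with `labels` (sorted character vector, possibly empty),
#'   `t_star` and `deltas` (named deltas at `t_star` for the scanned classes).
#' @examples
#' fx <- example_three_class_model()
#' pyramid_search(fx$model, fx$attachments$q1, feature = "AC")
#' @export
pyramid_search <- function(model, attachments, classes = model_labels(model),
                           feature = "AC", ladder = NULL, secondary = 0) {
  res <- pyramid_search_impl(
    model, new_eval_ctx(), attachments, classes,
    feature, ladder, secondary
  )
  res[c("labels", "t_star", "deltas")]
}

pyramid_search_impl <- function(model, ctx, attachments, classes, feature,
                                ladder = NULL, secondary = 0) {
  stopifnot(feature %in% gsf_names())
  unknown <- setdiff(classes, model_labels(model))
  if (length(unknown)) {
    abort(sprintf("unknown class label(s): %s", paste(unknown, collapse = ", ")),
      class = "ppsnet_input_error"
    )
  }
  cfg <- model$config
  ladder <- ladder %||% cfg$ladders[[feature]]
  len <- length(ladder)
  if (length(classes) == 0L || len == 0L) {
    return(list(
      labels = character(0), t_star = if (len) min(ladder) else NA_real_,
      deltas = numeric(0)
    ))
  }
  for (i in rev(seq_len(len))) {
    t <- ladder[i]
    r <- if (feature == "RC") rc_r_at(cfg, i, len) else 0L
    deltas <- vapply(
      classes,
      function(cl) delta_eval(model, ctx, attachments, cl, feature, t, r, cfg$p),
      numeric(1)
    )
    hit <- deltas > secondary
    if (any(hit)) {
      return(list(
        labels = sort(classes[hit]), t_star = t,
        deltas = setNames(deltas, classes)
      ))
    }
  }
  list(
    labels = character(0), t_star = min(ladder),
    deltas = setNames(rep(0, length(classes)), classes)
  )
}

#' Pick the k most influenced classes
#'
#' Given feature deltas measured at a fixed level, returns the `k` classes
#' with the largest strictly positive delta (all of them if fewer than `k`
#' are positive). Classes whose delta is not positive never vote: no
#' interaction, no vote. Ties are broken deterministically by ascending
#' label order.
#'
#' @param deltas Named numeric vector of per-class feature deltas.
#' @param k Positive integer.
#' @return Character vector of at most `k` labels.
#' @examples
#' k_max_candidates(c(c1 = 5, c2 = 3, c3 = 0), k = 2)
#' @export
k_max_candidates <- function(deltas, k) {
  stopifnot(k >= 1L, is.numeric(deltas))
  if (length(deltas) == 0L) {
    return(character(0))
  }
  if (is.null(names(deltas))) {
    abort("`deltas` must be named by class label.", class = "ppsnet_input_error")
  }
  pos <- deltas[deltas > 0]
  if (length(pos) == 0L) {
    return(character(0))
  }
  ord <- order(-pos, names(pos))
  names(pos)[head(ord, k)]
}

# descend a feature ladder over a candidate pool; at the first level with a
# positive delta apply k-max there
kmax_stage <- function(model, ctx, attachments, classes, feature, k,
                       ladder = NULL) {
  cfg <- model$config
  ladder <- ladder %||% cfg$ladders[[feature]]
  len <- length(ladder)
  if (length(classes) == 0L || len == 0L) {
    return(list(
      labels = character(0),
      t_star = if (len) min(ladder) else NA_real_, deltas = numeric(0)
    ))
  }
  for (i in rev(seq_len(len))) {
    t <- ladder[i]
    deltas <- vapply(
      classes,
      function(cl) delta_eval(model, ctx, attachments, cl, feature, t, 0L, cfg$p),
      numeric(1)
    )
    names(deltas) <- classes
    if (any(deltas > 0)) {
      return(list(labels = k_max_candidates(deltas, k), t_star = t, deltas = deltas))
    }
  }
  list(
    labels = character(0), t_star = min(ladder),
    deltas = setNames(rep(0, length(classes)), classes)
  )
}

# GE stage: evaluated at the lowest level of its ladder (dense graphs are
# where the spectrum is informative) unless config$ge_descend
ge_stage <- function(model, ctx, attachments, classes, k) {
  cfg <- model$config
  ladder <- cfg$ladders[["GE"]]
  if (cfg$ge_descend) {
    return(kmax_stage(model, ctx, attachments, classes, "GE", k))
  }
  t <- min(ladder)
  if (length(classes) == 0L) {
    return(list(labels = character(0), t_star = t, deltas = numeric(0)))
  }
  deltas <- vapply(
    classes,
    function(cl) delta_eval(model, ctx, attachments, cl, "GE", t, 0L, cfg$p),
    numeric(1)
  )
  names(deltas) <- classes
  list(labels = k_max_candidates(deltas, k), t_star = t, deltas = deltas)
}
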