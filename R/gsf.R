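#' Graph-structured features of a thresholded family graph
#'
#' Five scalar features summarise how a similarity network is organised at a
#' pyramid level, each probing a different structural property:
#'
#' * `avg_clustering()` — mean local clustering coefficient (modularity of
#'   neighbourhoods), in `[0, 1]`.
#' * `rich_club()` — density of the subgraph induced by vertices of degree
#'   strictly greater than `r` (the "rich-gets-richer" hub core), in `[0, 1]`.
#' * `star_motifs()` — number of star centres, i.e. vertices of degree at
#'   least `p` (hub census).
#' * `triangles()` — exact triangle count via `trace(A^3) / 6`.
#' * `graph_energy()` — sum of the absolute eigenvalues of the adjacency
#'   matrix (spectral "spread").
#'
#' Degenerate conventions: a vertex with fewer than two neighbours has
#' clustering coefficient 0; a rich club with fewer than two members has
#' coefficient 0; an empty graph has energy 0.
#'
#' @param view A `threshold_view` (see [threshold_view()]).
#' @param r Nonnegative integer degree cut for the rich club.
#' @param p Positive integer star power (minimum centre degree).
#' @return A single numeric value (integer-valued for `star_motifs()` and
#'   `triangles()`).
#' @examples
#' g <- example_clustered_graph()
#' v <- threshold_view(g, 1)
#' avg_clustering(v) # 13/15
#' rich_club(v, r = 1) # 3/5
#' triangles(v) # 2
#' @name gsf
NULL

view_adjacency <- function(view) {
  stopifnot(inherits(view, "threshold_view"))
  view$adjacency
}

# adjacency-level feature kernels (binary or weighted symmetric matrix in)
ac_adj <- function(a) {
  n <- nrow(a)
  if (n == 0L) {
    return(0)
  }
  deg <- rowSums(a)
  closed <- diag(a %*% a %*% a) # 2 * edges among each vertex's neighbours
  cn <- ifelse(deg >= 2, closed / (deg * (deg - 1)), 0)
  mean(cn)
}

rc_adj <- function(a, r) {
  rich <- rowSums(a) > r
  nr <- sum(rich)
  if (nr < 2L) {
    return(0)
  }
  er <- sum(a[rich, rich]) / 2
  2 * er / (nr * (nr - 1))
}

sm_adj <- function(a, p) sum(rowSums(a) >= p)

tr_adj <- function(a) {
  tr <- sum(diag(a %*% a %*% a)) / 6
  if (abs(tr - round(tr)) > 1e-8) {
    abort("trace(A^3)/6 is not an integer: adjacency invariant broken.",
      class = "ppsnet_internal_error"
    )
  }
  as.integer(round(tr))
}

ge_adj <- function(a) {
  if (nrow(a) == 0L || sum(a != 0) == 0L) {
    return(0)
  }
  sum(abs(eigen(a, symmetric = TRUE, only.values = TRUE)$values))
}

#' @rdname gsf
#' @export
avg_clustering <- function(view) ac_adj(view_adjacency(view))

#' @rdname gsf
#' @export
rich_club <- function(view, r) {
  stopifnot(length(r) == 1L, r >= 0)
  rc_adj(view_adjacency(view), r)
}

#' @rdname gsf
#' @export
star_motifs <- function(view, p) {
  stopifnot(length(p) == 1L, p >= 1)
  sm_adj(view_adjacency(view), p)
}

#' @rdname gsf
#' @export
triangles <- function(view) tr_adj(view_adjacency(view))

#' @rdname gsf
#' @export
graph_energy <- function(view) ge_adj(view_adjacency(view))

# thresholded weighted adjacency, for the optional weighted-energy variant
weighted_view_adjacency <- function(graph, t) {
  graph$weights * (graph$weights >= t & graph$weights > 0)
}

#' Graph-energy of a family graph at a level, weighted variant available
#'
#' @param graph A `family_graph`.
#' @param t Threshold.
#' @param weighted Use surviving EB weights instead of the binary adjacency.
#' @return Nonnegative energy value.
#' @export
graph_energy_at <- function(graph, t, weighted = FALSE) {
  if (!weighted) {
    return(graph_energy(threshold_view(graph, t)))
  }
  ge_adj(weighted_view_adjacency(graph, t))
}

feature_on_adjacency <- function(a, feature, r = 0L, p = 2L) {
  switch(feature,
    AC = ac_adj(a),
    RC = rc_adj(a, r),
    SM = sm_adj(a, p),
    TR = tr_adj(a),
    GE = ge_adj(a),
    abort(sprintf("unknown feature '%s'", feature), class = "ppsnet_input_error")
  )
}

# ---- feature dispatch -------------------------------------------------------

gsf_names <- function() c("AC", "RC", "SM", "TR", "GE")

gsf_value <- function(graph, t, feature, r = 1L, p = 2L, weighted_ge = FALSE) {
  if (feature == "GE") {
    return(graph_energy_at(graph, t, weighted = weighted_ge))
  }
  v <- threshold_view(graph, t)
  switch(feature,
    AC = avg_clustering(v),
    RC = rich_club(v, r),
    SM = star_motifs(v, p),
    TR = triangles(v),
    abort(sprintf("unknown feature '%s'", feature), class = "ppsnet_input_error")
  )
}

gsf_delta <- function(graph, eb, t, feature, r = 1L, p = 2L,
                      weighted_ge = FALSE, query_id = ".query.") {
  aug <- attach_query(graph, eb, query_id = query_id)
  gsf_value(aug, t, feature, r = r, p = p, weighted_ge = weighted_ge) -
    gsf_value(graph, t, feature, r = r, p = p, weighted_ge = weighted_ge)
}

#' Query-induced feature changes
#'
#' Each classifier vote is driven by how much a feature changes when the
#' query is attached to a family graph and the combined graph is viewed at
#' threshold `t`: `delta = feature(augmented) - feature(original)`. Triangle
#' and star-motif deltas are always nonnegative (adding a vertex cannot
#' destroy triangles or reduce degrees); clustering, rich-club and energy
#' deltas can take either sign.
#'
#' @param graph A `family_graph`.
#' @param eb Query attachment: nonnegative EB-scores, one per vertex (see
#'   [query_attachment()]).
#' @param t Threshold at which both graphs are viewed.
#' @inheritParams gsf
#' @return A single numeric delta.
#' @examples
#' hq <- example_hub_query()
#' delta_tr(hq$graph, hq$eb, t = 1) # exactly one new triangle
#' @name gsf_delta
NULL

#' @rdname gsf_delta
#' @export
delta_ac <- function(graph, eb, t) gsf_delta(graph, eb, t, "AC")

#' @rdname gsf_delta
#' @export
delta_rc <- function(graph, eb, t, r) gsf_delta(graph, eb, t, "RC", r = r)

#' @rdname gsf_delta
#' @export
delta_sm <- function(graph, eb, t, p) gsf_delta(graph, eb, t, "SM", p = p)

#' @rdname gsf_delta
#' @export
delta_tr <- function(graph, eb, t) gsf_delta(graph, eb, t, "TR")

#' @rdname gsf_delta
#' @param weighted Use the weighted-adjacency energy variant.
#' @export
delta_ge <- function(graph, eb, t, weighted = FALSE) {
  gsf_delta(graph, eb, t, "GE", weighted_ge = weighted)
}

#' Sweep features across thresholds
#'
#' Evaluates every feature of every family graph along a threshold ladder,
#' for threshold-response analyses (which levels each feature is informative
#' at).
#'
#' @param model A `gp_model` (see [train_model()]) or a list of
#'   `family_graph` objects.
#' @param thresholds Numeric vector of thresholds; default is the model's
#'   global ladder.
#' @param r,p Rich-club cut and star power used in the sweep.
#' @return A tibble of class `gp_sweep` with columns `family`, `feature`,
#'   `t`, `value`.
#' @export
feature_sweep <- function(model, thresholds = NULL, r = 1L, p = 2L) {
  graphs <- if (inherits(model, "gp_model")) model$families else model
  if (is.null(thresholds)) {
    if (!inherits(model, "gp_model")) {
      abort("`thresholds` must be given when `model` is a plain graph list.",
        class = "ppsnet_input_error"
      )
    }
    thresholds <- model$config$global_ladder
  }
  rows <- purrr::map_dfr(graphs, function(g) {
    purrr::map_dfr(thresholds, function(th) {
      vals <- vapply(
        gsf_names(),
        function(f) gsf_value(g, th, f, r = r, p = p), numeric(1)
      )
      tibble(family = g$label, feature = gsf_names(), t = th, value = vals)
    })
  })
  structure(rows, class = c("gp_sweep", class(tibble())))
}

#' Write a feature sweep report
#'
#' @param sweep A `gp_sweep` tibble from [feature_sweep()].
#' @param path Output TSV path (columns `family feature t value`).
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(sweep, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
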