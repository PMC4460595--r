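#' Build a protein family similarity graph
#'
#' A family is modelled as a weighted undirected graph: vertices are the
#' family's training sequences and the weight between two vertices is their
#' EB-score (0 on the diagonal and for undetected pairs). Vertex order is the
#' order of `members` and is stable, so adjacency matrices are reproducible.
#'
#' @param table A `pps_similarity` table (see [similarity_table()]).
#' @param members Character vector of unique member sequence ids.
#' @param label Family/class label.
#' @return An object of class `family_graph`: a list with `label`, `ids` and
#'   the symmetric nonnegative `weights` matrix.
#' @examples
#' tab <- similarity_table(tibble::tibble(
#'   query_id = "a", subject_id = "b", evalue = 1e-7, bitscore = 50
#' ))
#' family_graph(tab, c("a", "b"), label = "fam1")
#' @export
family_graph <- function(table, members, label) {
  members <- as.character(members)
  if (length(members) < 1L) {
    abort("`members` must be nonempty.", class = "ppsnet_input_error")
  }
  if (anyDuplicated(members)) {
    abort("`members` must be unique.", class = "ppsnet_input_error")
  }
  n <- length(members)
  w <- matrix(0, n, n, dimnames = list(members, members))
  sub <- table[table$id_a %in% members & table$id_b %in% members, , drop = FALSE]
  if (nrow(sub)) {
    i <- match(sub$id_a, members)
    j <- match(sub$id_b, members)
    w[cbind(i, j)] <- sub$eb
    w[cbind(j, i)] <- sub$eb
  }
  new_family_graph(label, members, w)
}

new_family_graph <- function(label, ids, weights) {
  stopifnot(
    is.matrix(weights), nrow(weights) == length(ids),
    ncol(weights) == length(ids)
  )
  if (any(weights < 0) || any(diag(weights) != 0) || !isSymmetric(unname(weights))) {
    abort("family graph weights must be symmetric, nonnegative, zero-diagonal.",
      class = "ppsnet_input_error"
    )
  }
  dimnames(weights) <- list(ids, ids)
  structure(list(label = label, ids = ids, weights = weights),
    class = "family_graph"
  )
}

#' @export
print.family_graph <- function(x, ...) {
  cat(sprintf(
    "<family_graph '%s': %d vertices, %d positive-weight edges, max EB %.4g>\n",
    x$label, length(x$ids), sum(x$weights[upper.tri(x$weights)] > 0),
    if (length(x$ids) > 1) max(x$weights) else 0
  ))
  invisible(x)
}

#' Unweighted view of a family graph at a pyramid level
#'
#' One level of the graph pyramid: edges whose EB weight reaches the
#' threshold survive (`weight >= t`, the closed boundary of the Heaviside
#' step) and the surviving graph is treated as unweighted. A stored weight of
#' 0 never forms an edge, even at `t = 0`, since zero means "no detectable
#' similarity".
#'
#' @param graph A `family_graph`.
#' @param t Nonnegative threshold.
#' @return An object of class `threshold_view` with fields `ids`, `t` and the
#'   binary symmetric `adjacency` matrix.
#' @export
threshold_view <- function(graph, t) {
  stopifnot(inherits(graph, "family_graph"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    abort("`t` must be a single nonnegative number.", class = "ppsnet_input_error")
  }
  a <- (graph$weights >= t & graph$weights > 0) * 1
  structure(list(ids = graph$ids, t = t, adjacency = a), class = "threshold_view")
}

#' @export
print.threshold_view <- function(x, ...) {
  cat(sprintf(
    "<threshold_view t=%.4g: %d vertices, %d edges>\n",
    x$t, length(x$ids), sum(x$adjacency) / 2
  ))
  invisible(x)
}

#' Attach a query vertex to a family graph
#'
#' Returns a new graph with the query appended as the last vertex and its
#' EB-scores to each member as the new edge weights. The input graph is never
#' modified; dropping the last row/column of the result recovers the original
#' weights exactly.
#'
#' @param graph A `family_graph`.
#' @param eb Numeric vector of nonnegative EB-scores, one per existing vertex
#'   (in vertex order). A named vector is reordered to match.
#' @param query_id Identifier for the new vertex.
#' @return A new `family_graph` with `N + 1` vertices.
#' @export
attach_query <- function(graph, eb, query_id = "query") {
  stopifnot(inherits(graph, "family_graph"))
  n <- length(graph$ids)
  if (!is.null(names(eb))) {
    if (!setequal(names(eb), graph$ids)) {
      abort("names of `eb` must match the graph's vertex ids.",
        class = "ppsnet_input_error"
      )
    }
    eb <- eb[graph$ids]
  }
  if (length(eb) != n) {
    abort(sprintf("`eb` must have length %d (one score per vertex).", n),
      class = "ppsnet_input_error"
    )
  }
  if (any(!is.finite(eb)) || any(eb < 0)) {
    abort("`eb` must be finite and nonnegative.", class = "ppsnet_input_error")
  }
  if (query_id %in% graph$ids) {
    abort("`query_id` collides with an existing vertex id.",
      class = "ppsnet_input_error"
    )
  }
  w <- rbind(cbind(graph$weights, unname(eb)), c(unname(eb), 0))
  new_family_graph(graph$label, c(graph$ids, query_id), w)
}

#' Extract a query's EB-scores against one family
#'
#' @param table A `pps_similarity` table containing query-vs-member scores.
#' @param graph A `family_graph`.
#' @param query_id The query sequence id.
#' @return Named numeric vector of EB-scores in the graph's vertex order
#'   (missing pairs are 0), suitable for [attach_query()].
#' @export
query_attachment <- function(table, graph, query_id) {
  setNames(sim_lookup(table, query_id, graph$ids), graph$ids)
}

# ---- label multisets --------------------------------------------------------

#' Multiset sum of label collections
#'
#' Vote pooling uses multisets: repeated labels are kept, so
#' `|s1 (+) s2| = |s1| + |s2|`. The operation is associative and commutative.
#'
#' @param s1,s2 Character vectors of class labels (possibly with repeats).
#' @return Character vector containing every label of `s1` and `s2` with
#'   multiplicities added.
#' @examples
#' multiset_sum(c("c1", "c2"), c("c2", "c3"))
#' @export
multiset_sum <- function(s1, s2) {
  c(as.character(s1), as.character(s2))
}

#' Most frequent labels of a multiset
#'
#' Returns every label attaining the maximal multiplicity, so callers can
#' detect ties (two or more modes) and trigger tie-breaking.
#'
#' @param s Character vector of labels; must be nonempty.
#' @return Character vector of modal labels, sorted ascending.
#' @export
mode_labels <- function(s) {
  s <- as.character(s)
  if (length(s) == 0L) {
    abort("empty multiset: no votes to take the mode of.",
      class = "ppsnet_no_votes"
    )
  }
  tab <- table(s)
  sort(names(tab)[tab == max(tab)])
}
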