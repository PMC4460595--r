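with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a hub-dominated family score network
#'
#' Generates a self-contained benchmark at the score level (no sequences, no
#' alignment): each family is a clique-candidate set of members whose
#' retained intra-family pairs get log-normal EB-scores, thinned by
#' preferential attachment so that high-degree members keep accumulating
#' edges (the "rich-gets-richer" hub topology of real similarity networks).
#' A small fraction of inter-family pairs receives weaker log-normal scores
#' (spurious cross-family hits); all other pairs are 0. About
#' `query_frac` of each family's members are withheld as queries with known
#' labels; their scores against everything are part of the returned table.
#'
#' Everything is a pure function of the arguments: the same spec (seed
#' included) reproduces the output exactly, and the caller's RNG state is
#' left untouched.
#'
#' @param n_families Number of families (>= 2 for a classification task).
#' @param family_size Members per family (single value or one per family).
#' @param mu_in,mu_out Log-scale means of intra- and inter-family EB-scores.
#'   Separable benchmarks need `mu_in > mu_out`; the default puts them
#'   4 standard deviations apart.
#' @param sigma Log-scale standard deviation.
#' @param hub_gamma Preferential-attachment strength (>= 0): retained pairs
#'   are drawn with probability proportional to
#'   `((deg_i + 1) * (deg_j + 1))^hub_gamma`. 0 = uniform thinning.
#' @param edge_keep_frac Fraction of intra-family pairs retained, in (0, 1].
#' @param cross_frac Fraction of inter-family pairs that get a (weak) score.
#' @param query_frac Fraction of members per family withheld as queries.
#' @param seed RNG seed.
#' @return A list: `table` (a `pps_similarity` over all generated pairs,
#'   queries included), `families` (training membership tibble `seq_id`,
#'   `family_id`), `queries` (tibble `query_id`, `family_id`), and `spec`
#'   (the parameters echoed back).
#' @examples
#' sim <- simulate_score_network(n_families = 3, family_size = 8, seed = 1)
#' sim$queries
#' @export
simulate_score_network <- function(n_families = 20L, family_size = 30L,
                                   mu_in = log(2000), sigma = 0.5,
                                   mu_out = mu_in - 4 * sigma,
                                   hub_gamma = 1, edge_keep_frac = 0.7,
                                   cross_frac = 0.05, query_frac = 0.1,
                                   seed = 1L) {
  stopifnot(
    n_families >= 1L, all(family_size >= 2L), sigma > 0,
    hub_gamma >= 0, edge_keep_frac > 0, edge_keep_frac <= 1,
    cross_frac >= 0, cross_frac <= 1, query_frac >= 0, query_frac < 1
  )
  sizes <- rep_len(as.integer(family_size), n_families)
  fam_labels <- sprintf("fam%02d", seq_len(n_families))
  ids <- unlist(lapply(seq_len(n_families), function(f) {
    sprintf("%s_s%02d", fam_labels[f], seq_len(sizes[f]))
  }))
  fam_of <- rep(fam_labels, sizes)
  with_preserved_rng(seed, {
    rows <- vector("list", n_families + 1L)
    for (f in seq_len(n_families)) {
      members <- ids[fam_of == fam_labels[f]]
      n <- length(members)
      pairs <- combn(n, 2L)
      n_pairs <- ncol(pairs)
      m <- max(1L, round(edge_keep_frac * n_pairs))
      deg <- integer(n)
      remaining <- seq_len(n_pairs)
      chosen <- integer(m)
      for (e in seq_len(m)) {
        w <- ((deg[pairs[1L, remaining]] + 1) *
          (deg[pairs[2L, remaining]] + 1))^hub_gamma
        pick <- remaining[sample.int(length(remaining), 1L, prob = w)]
        chosen[e] <- pick
        deg[pairs[1L, pick]] <- deg[pairs[1L, pick]] + 1L
        deg[pairs[2L, pick]] <- deg[pairs[2L, pick]] + 1L
        remaining <- remaining[remaining != pick]
      }
      rows[[f]] <- tibble(
        id_a = members[pairs[1L, chosen]],
        id_b = members[pairs[2L, chosen]],
        eb = rlnorm(m, meanlog = mu_in, sdlog = sigma)
      )
    }
    # weak cross-family scores on a random fraction of inter-family pairs
    if (n_families > 1L && cross_frac > 0) {
      all_pairs <- combn(length(ids), 2L)
      cross <- which(fam_of[all_pairs[1L, ]] != fam_of[all_pairs[2L, ]])
      k <- round(cross_frac * length(cross))
      if (k > 0L) {
        pick <- sort(sample(cross, k))
        rows[[n_families + 1L]] <- tibble(
          id_a = ids[all_pairs[1L, pick]],
          id_b = ids[all_pairs[2L, pick]],
          eb = rlnorm(k, meanlog = mu_out, sdlog = sigma)
        )
      }
    }
    scores <- bind_rows(rows) %>%
      mutate(
        a = pmin(.data$id_a, .data$id_b),
        b = pmax(.data$id_a, .data$id_b)
      ) %>%
      select(id_a = "a", id_b = "b", eb = "eb") %>%
      arrange(.data$id_a, .data$id_b)
    # withhold ~query_frac of each family as labelled queries
    is_query <- logical(length(ids))
    for (f in seq_len(n_families)) {
      members_ix <- which(fam_of == fam_labels[f])
      nq <- max(1L, round(query_frac * length(members_ix)))
      if (query_frac == 0) nq <- 0L
      if (nq > 0L) is_query[sample(members_ix, nq)] <- TRUE
    }
    list(
      table = new_similarity_table(scores),
      families = tibble(seq_id = ids[!is_query], family_id = fam_of[!is_query]),
      queries = tibble(query_id = ids[is_query], family_id = fam_of[is_query]),
      spec = list(
        n_families = n_families, family_size = sizes, mu_in = mu_in,
        mu_out = mu_out, sigma = sigma, hub_gamma = hub_gamma,
        edge_keep_frac = edge_keep_frac, cross_frac = cross_frac,
        query_frac = query_frac, seed = seed
      )
    )
  })
}

#' Simulate protein families at the sequence level
#'
#' Per family, draws one random ancestor protein and derives members by
#' independent per-site substitutions, so intra-family pairs stay close in
#' alignment score while inter-family pairs look random. Intended to
#' exercise the FASTA -> [align_all()] -> [similarity_table()] path; it is
#' not an evolutionary model (no indels, no rate heterogeneity).
#'
#' @param n_families,family_size Number of families and members per family.
#' @param length Ancestor length (residues).
#' @param mutation_rate Per-site substitution probability in (0, 0.5).
#' @param seed RNG seed.
#' @return A tibble with columns `id`, `family_id`, `sequence`.
#' @export
simulate_sequences <- function(n_families = 3L, family_size = 4L,
                               length = 120L, mutation_rate = 0.1,
                               seed = 1L) {
  stopifnot(mutation_rate > 0, mutation_rate < 0.5, length >= 1L)
  aas <- setdiff(aa_alphabet(), "X")
  with_preserved_rng(seed, {
    rows <- lapply(seq_len(n_families), function(f) {
      anc <- sample(aas, length, replace = TRUE)
      seqs <- vapply(seq_len(family_size), function(s) {
        mut <- runif(length) < mutation_rate
        out <- anc
        if (any(mut)) {
          out[mut] <- vapply(
            anc[mut],
            function(a) sample(setdiff(aas, a), 1L), character(1)
          )
        }
        paste(out, collapse = "")
      }, character(1))
      tibble(
        id = sprintf("fam%02d_s%02d", f, seq_len(family_size)),
        family_id = sprintf("fam%02d", f),
        sequence = seqs
      )
    })
    bind_rows(rows)
  })
}

# ---- worked-example fixtures ------------------------------------------------

edge_weight_matrix <- function(ids, edges, weight = 1) {
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  for (e in edges) {
    i <- match(e[1L], ids)
    j <- match(e[2L], ids)
    w[i, j] <- w[j, i] <- weight
  }
  w
}

#' Five-vertex clustered example graph
#'
#' A small hand-checkable graph: a central vertex `c` connected to `a`, `b`,
#' `d`, `e`, plus edges `a-b` and `d-e` (all unit weight). Its average
#' clustering coefficient at any threshold up to 1 is 13/15 (the centre
#' contributes 1/3, the four leaves 1 each), its rich-club coefficient at
#' `r = 1` is 3/5, and it contains exactly 2 triangles.
#'
#' @return A `family_graph`.
#' @export
example_clustered_graph <- function() {
  ids <- c("a", "b", "c", "d", "e")
  edges <- list(
    c("c", "a"), c("c", "b"), c("c", "d"), c("c", "e"),
    c("a", "b"), c("d", "e")
  )
  new_family_graph("example", ids, edge_weight_matrix(ids, edges))
}

#' Hub-and-query example graph
#'
#' A graph where triangle and star-motif deltas diverge: vertex `a` is a
#' degree-3 hub over `x1..x3`, and `b-c` is the only edge inside the future
#' interaction neighbourhood. The query `q` attaches to `a`, `b`, `c` and
#' `d`: exactly one new triangle forms (`q-b-c`), while `a`'s star power
#' rises from 3 to 4. (The vertices' remaining edges are the minimal
#' concretization consistent with those facts.)
#'
#' @return A list with `graph` (a `family_graph`), `eb` (the query
#'   attachment vector) and `query_id`.
#' @export
example_hub_query <- function() {
  ids <- c("a", "b", "c", "d", "x1", "x2", "x3")
  edges <- list(c("b", "c"), c("a", "x1"), c("a", "x2"), c("a", "x3"))
  graph <- new_family_graph("example", ids, edge_weight_matrix(ids, edges))
  eb <- setNames(c(1, 1, 1, 1, 0, 0, 0), ids)
  list(graph = graph, eb = eb, query_id = "q")
}

#' Three-class pyramid search example
#'
#' A concrete three-family model with a 3-level ladder (thresholds 1, 2, 3)
#' on which the pyramid search can be traced by hand. Every family is a unit
#' motif of five vertices: a triangle (`v1-v2-v3`) plus a separate edge
#' (`v4-v5`), all edge weights 3, giving baseline clustering 3/5 at every
#' level. Five query attachments exercise the search paths:
#'
#' * `q1` attaches (EB 2) to `v4`, `v5` of both `c2` and `c3`: it first
#'   qualifies one level down, yielding candidates `{c2, c3}` at `t* = 2`.
#' * `q2` attaches (EB 3) to `v4`, `v5` of `c1`: qualifies at the top level.
#' * `q3` has zero EB everywhere: empty candidate set, `t*` = ladder minimum.
#' * `q4` attaches (EB 1) to `v4`, `v5` of `c3`: qualifies only at the
#'   lowest level.
#' * `q5` attaches (EB 2) to `v1`, `v4` of `c1`, which closes nothing:
#'   clustering never rises, empty candidate set.
#'
#' @return A list with `model` (a `gp_model`, all feature ladders spanning
#'   all 3 levels) and `attachments` (named list of per-query attachment
#'   lists suitable for [pyramid_search()]).
#' @export
example_three_class_model <- function() {
  labels <- c("c1", "c2", "c3")
  scores <- bind_rows(lapply(labels, function(lab) {
    v <- sprintf("%s_v%d", lab, 1:5)
    tibble(
      id_a = c(v[1], v[1], v[2], v[4]),
      id_b = c(v[2], v[3], v[3], v[5]),
      eb = 3
    )
  }))
  table <- new_similarity_table(arrange(scores, .data$id_a, .data$id_b))
  families <- tibble(
    seq_id = unlist(lapply(labels, function(lab) sprintf("%s_v%d", lab, 1:5))),
    family_id = rep(labels, each = 5L)
  )
  cfg <- pyramid_config(
    n_levels = 3L,
    slices = list(AC = 1:3, RC = 1:3, SM = 1:3, TR = 1:3, GE = 1L)
  )
  model <- train_model(table, families, cfg)
  att <- function(spec) {
    out <- lapply(model$families, function(g) setNames(numeric(length(g$ids)), g$ids))
    for (lab in names(spec)) {
      out[[lab]][names(spec[[lab]])] <- spec[[lab]]
    }
    out
  }
  v <- function(lab, i, eb) setNames(rep(eb, length(i)), sprintf("%s_v%d", lab, i))
  attachments <- list(
    q1 = att(list(c2 = v("c2", 4:5, 2), c3 = v("c3", 4:5, 2))),
    q2 = att(list(c1 = v("c1", 4:5, 3))),
    q3 = att(list()),
    q4 = att(list(c3 = v("c3", 4:5, 1))),
    q5 = att(list(c1 = v("c1", c(1, 4), 2)))
  )
  list(model = model, attachments = attachments)
}
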