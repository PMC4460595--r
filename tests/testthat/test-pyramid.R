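test_that("threshold ladders quantize the weight range uniformly", {
  g <- graph_from_adjacency(matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b"))),
    weight = 100
  )
  th <- build_thresholds(list(g), 10)
  expect_equal(th$global_ladder, seq(10, 100, by = 10))
  # default slices: AC/RC upper half, SM/TR middle band, GE bottom
  expect_equal(th$ladders$AC, seq(60, 100, by = 10))
  expect_equal(th$ladders$SM, seq(30, 70, by = 10))
  expect_equal(th$ladders$GE, c(10, 20))
  # a single edge weight w spans (0, w]
  g2 <- graph_from_adjacency(matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b"))),
    weight = 7
  )
  th2 <- build_thresholds(list(g2), 4)
  expect_equal(max(th2$global_ladder), 7)
  expect_true(min(th2$global_ladder) > 0)
  # every level is covered by at least one slice and each ladder ascends
  covered <- sort(unique(unlist(lapply(
    th$ladders,
    function(l) match(l, th$global_ladder)
  ))))
  expect_equal(covered, 1:10)
  for (l in th$ladders) expect_false(is.unsorted(l, strictly = TRUE))
  # an all-zero training set cannot form a pyramid
  g0 <- family_graph(edges_table(list("x", "y", 1))[0, ], c("a", "b"), "z")
  expect_error(build_thresholds(list(g0), 5), class = "ppsnet_model_error")
})

test_that("pyramid search descends to the first qualifying level", {
  fx <- example_three_class_model()
  ps1 <- pyramid_search(fx$model, fx$attachments$q1, feature = "AC")
  expect_equal(ps1$labels, c("c2", "c3"))
  expect_equal(ps1$t_star, 2) # second rung of the 1, 2, 3 ladder
  ps2 <- pyramid_search(fx$model, fx$attachments$q2, feature = "AC")
  expect_equal(ps2$labels, "c1")
  expect_equal(ps2$t_star, 3) # qualifies at the top
  ps3 <- pyramid_search(fx$model, fx$attachments$q3, feature = "AC")
  expect_equal(ps3$labels, character(0))
  expect_equal(ps3$t_star, 1) # ladder minimum when nothing qualifies
  ps4 <- pyramid_search(fx$model, fx$attachments$q4, feature = "AC")
  expect_equal(ps4$labels, "c3")
  expect_equal(ps4$t_star, 1)
  ps5 <- pyramid_search(fx$model, fx$attachments$q5, feature = "AC")
  expect_equal(ps5$labels, character(0)) # interaction without closure
  expect_error(
    pyramid_search(fx$model, fx$attachments$q1, classes = "nope"),
    class = "ppsnet_input_error"
  )
})

test_that("k-max candidate selection is a sorted head of the positive deltas", {
  expect_equal(k_max_candidates(c(c1 = 5, c2 = 3, c3 = 0), 2), c("c1", "c2"))
  expect_equal(k_max_candidates(c(c1 = 0, c2 = 0), 2), character(0))
  expect_equal(k_max_candidates(c(b = 2, a = 2, c = 1), 2), c("a", "b")) # label tie-break
  set.seed(13)
  for (rep in 1:50) {
    d <- setNames(round(runif(6, -2, 5), 2), paste0("c", 1:6))
    k <- sample(1:6, 1)
    got <- k_max_candidates(d, k)
    pos <- d[d > 0]
    ref <- names(pos)[order(-pos, names(pos))]
    expect_equal(got, head(ref, k))
  }
})

# two families with distinct motifs and a query that ties the first vote
# round: star-motif evidence favours one class, triangle evidence the other,
# so the decision falls through to the graph-energy arbiter
ge_fallback_fixture <- function() {
  tab <- edges_table(
    list("a1", "b1", 3), list("c1", "d1", 3),
    list("a2", "b2", 3), list("b2", "c2", 3)
  )
  families <- tibble::tibble(
    seq_id = c("a1", "b1", "c1", "d1", "a2", "b2", "c2", "d2"),
    family_id = rep(c("f1", "f2"), each = 4)
  )
  cfg <- pyramid_config(
    n_levels = 2, r_low = 1, r_high = 1,
    slices = list(AC = 1:2, RC = 1:2, SM = 1:2, TR = 1:2, GE = 1)
  )
  model <- train_model(tab, families, cfg)
  q <- edges_table(
    list("q", "a1", 3), list("q", "b1", 3), list("q", "c1", 3),
    list("q", "a2", 3), list("q", "b2", 3), list("q", "c2", 3)
  )
  list(model = model, scores = q)
}

test_that("hierarchical voting decides clear cases and surfaces no-decisions", {
  fx <- ge_fallback_fixture()
  # a query touching only f1 is a clear decision with no tie path
  clear <- edges_table(list("q", "a1", 3), list("q", "b1", 3), list("q", "c1", 3))
  res <- classify(fx$model, clear)
  expect_equal(res$predicted, "f1")
  expect_equal(res$tie_path, "none")
  cand <- res$candidates[[1]]
  expect_true(all(cand$RC %in% cand$AC))
  expect_true(all(cand$SM %in% cand$RC))
  expect_true(all(cand$TR %in% cand$RC))
  expect_true(all(cand$GE %in% union(cand$SM, cand$TR)))
  # a query with zero score everywhere cannot be decided
  none <- classify(fx$model, edges_table(list("q", "zz", 1)), queries = "q")
  expect_true(is.na(none$predicted))
})

test_that("persistent vote ties are arbitrated by the energy delta", {
  fx <- ge_fallback_fixture()
  res <- classify(fx$model, fx$scores)
  expect_equal(res$tie_path, "ge_fallback")
  # independent check: the winner is the class whose energy rises most
  idx <- ppsnet:::pair_index(fx$scores)
  ge <- vapply(c("f1", "f2"), function(lab) {
    g <- fx$model$families[[lab]]
    delta_ge(g, setNames(ppsnet:::lookup_idx(idx, "q", g$ids), g$ids),
      t = min(fx$model$config$ladders$GE)
    )
  }, numeric(1))
  expect_equal(res$predicted, names(which.max(ge)))
  # the star/triangle disagreement that caused the tie is on record
  cand <- res$candidates[[1]]
  expect_setequal(cand$AC, c("f1", "f2"))
  expect_setequal(cand$RC, c("f1", "f2"))
})

test_that("classification is deterministic, tie path included", {
  fx <- ge_fallback_fixture()
  r1 <- classify(fx$model, fx$scores)
  r2 <- classify(fx$model, fx$scores)
  expect_identical(
    r1[setdiff(names(r1), "candidates")],
    r2[setdiff(names(r2), "candidates")]
  )
  expect_identical(r1$candidates, r2$candidates)
})

test_that("the candidate funnel narrows on random separable models", {
  set.seed(97)
  engaged <- 0L
  for (rep in 1:25) {
    sim <- simulate_score_network(
      n_families = 4, family_size = 8,
      edge_keep_frac = 0.8, seed = rep
    )
    cfg <- pyramid_config(
      n_levels = 4, r_low = 1, r_high = 2,
      slices = list(AC = 1:4, RC = 1:4, SM = 1:4, TR = 1:4, GE = 1:2)
    )
    model <- train_model(sim$table, sim$families, cfg)
    res <- classify(model, sim$table, queries = sim$queries$query_id)
    for (i in seq_len(nrow(res))) {
      cand <- res$candidates[[i]]
      if (res$tie_path[i] != "ge_only") {
        engaged <- engaged + 1L
        expect_true(all(cand$RC %in% cand$AC))
        expect_true(all(cand$SM %in% cand$RC))
        expect_true(all(cand$TR %in% cand$RC))
        expect_true(all(cand$GE %in% union(cand$SM, cand$TR)))
      }
    }
  }
  expect_gte(engaged, 30) # the funnel genuinely engages, not vacuously
})

test_that("majority voting agrees on easy cases but evaluates more", {
  fx <- ge_fallback_fixture()
  clear <- edges_table(list("q", "a1", 3), list("q", "b1", 3), list("q", "c1", 3))
  hier <- classify(fx$model, clear)
  maj <- majority_classify(fx$model, clear)
  expect_equal(maj$predicted, hier$predicted)
  sim <- simulate_score_network(n_families = 6, family_size = 10, seed = 5)
  model <- train_model(sim$table, sim$families)
  h <- classify(model, sim$table, queries = sim$queries$query_id)
  m <- classify(model, sim$table, queries = sim$queries$query_id, method = "majority")
  # whenever the clustering stage prunes at least one family, the funnel
  # does strictly less work
  pruned <- vapply(
    h$candidates,
    function(cc) length(cc$AC) < length(model$families), logical(1)
  )
  expect_true(all(h$n_evaluations[pruned] < m$n_evaluations[pruned]))
})

test_that("incremental updates equal a from-scratch rebuild and touch one family", {
  sim <- simulate_score_network(n_families = 3, family_size = 8, seed = 9)
  model <- train_model(sim$table, sim$families)
  qid <- sim$queries$query_id[1]
  fam <- sim$queries$family_id[1]
  other <- setdiff(names(model$families), fam)
  before_other <- lapply(model$families[other], `[[`, "weights")
  up <- incremental_update(model, qid, fam, sim$table)
  # rebuild equivalence
  members2 <- c(model$families[[fam]]$ids, qid)
  rebuilt <- family_graph(sim$table, members2, fam)
  expect_equal(up$families[[fam]]$weights, rebuilt$weights)
  expect_equal(length(up$families[[fam]]$ids), length(model$families[[fam]]$ids) + 1L)
  # untouched families identical; original model unchanged
  expect_identical(lapply(up$families[other], `[[`, "weights"), before_other)
  expect_false(qid %in% model$families[[fam]]$ids)
  expect_error(incremental_update(model, qid, NA_character_, sim$table),
    class = "ppsnet_model_error"
  )
  # an identical twin of the added query lands in the same family
  twin_scores <- sim$table %>%
    dplyr::filter(.data$id_a == qid | .data$id_b == qid) %>%
    dplyr::mutate(
      id_a = ifelse(.data$id_a == qid, "twin", .data$id_a),
      id_b = ifelse(.data$id_b == qid, "twin", .data$id_b)
    )
  twin_scores <- dplyr::bind_rows(
    twin_scores,
    tibble::tibble(id_a = qid, id_b = "twin", eb = max(sim$table$eb))
  )
  res <- classify(up, twin_scores, queries = "twin")
  expect_equal(res$predicted, fam)
})

test_that("strong matches place t* in the upper half of the ladder on separable data", {
  sim <- simulate_score_network(n_families = 5, family_size = 12, seed = 21)
  model <- train_model(sim$table, sim$families)
  res <- classify(model, sim$table, queries = sim$queries$query_id)
  rep <- evaluate_predictions(res, sim$queries)
  expect_gte(rep$accuracy, 0.95)
  mid <- max(model$config$global_ladder) / 2
  correct <- res$predicted == sim$queries$family_id[match(res$query_id, sim$queries$query_id)]
  expect_true(all(res$t_star_ac[which(correct)] >= mid))
})
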