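test_that("the clustered example graph reproduces its hand-computed features", {
  g <- example_clustered_graph()
  v <- threshold_view(g, 1)
  # centre c: 4 neighbours, 2 edges among them -> C_c = 1/3; leaves all 1
  a <- v$adjacency
  nb <- which(a["c", ] == 1)
  e_c <- sum(a[nb, nb]) / 2
  expect_equal(e_c, 2)
  expect_equal(2 * e_c / (4 * 3), 1 / 3)
  expect_equal(avg_clustering(v), 13 / 15)
  expect_equal(rich_club(v, 1), 3 / 5)
  expect_equal(triangles(v), 2L)
})

test_that("features take their textbook values on canonical graphs", {
  k4 <- view_from_adjacency(matrix(1, 4, 4, dimnames = list(paste0("v", 1:4), paste0("v", 1:4))) - diag(4))
  expect_equal(avg_clustering(k4), 1)
  expect_equal(triangles(k4), 4L) # choose(4, 3)
  star <- matrix(0, 5, 5, dimnames = list(paste0("v", 1:5), paste0("v", 1:5)))
  star[1, 2:5] <- star[2:5, 1] <- 1
  vs <- view_from_adjacency(star)
  expect_equal(avg_clustering(vs), 0)
  expect_equal(star_motifs(vs, 4), 1L)
  expect_equal(star_motifs(vs, 5), 0L)
  k5 <- view_from_adjacency(matrix(1, 5, 5, dimnames = list(paste0("v", 1:5), paste0("v", 1:5))) - diag(5))
  expect_equal(rich_club(k5, 1), 1)
  empty <- view_from_adjacency(matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])))
  expect_equal(rich_club(empty, 0), 0)
  expect_equal(graph_energy(empty), 0)
  # path a-b-c: one interior star centre at p = 2
  path <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path["a", "b"] <- path["b", "a"] <- path["b", "c"] <- path["c", "b"] <- 1
  expect_equal(star_motifs(view_from_adjacency(path), 2), 1L)
})

test_that("graph energy matches closed-form spectra", {
  k2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(graph_energy(view_from_adjacency(k2)), 2) # eigenvalues +-1
  tri <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3])) - diag(3)
  expect_equal(graph_energy(view_from_adjacency(tri)), 4) # 2, -1, -1
  path <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path["a", "b"] <- path["b", "a"] <- path["b", "c"] <- path["c", "b"] <- 1
  expect_equal(graph_energy(view_from_adjacency(path)), 2 * sqrt(2)) # +-sqrt2, 0
})

test_that("the hub-query example separates triangle and star information", {
  hq <- example_hub_query()
  v <- threshold_view(hq$graph, 1)
  expect_equal(star_motifs(v, 3), 1L) # only hub a
  expect_equal(triangles(v), 0L)
  expect_equal(delta_tr(hq$graph, hq$eb, 1), 1L) # q-b-c closes
  aug <- attach_query(hq$graph, hq$eb, hq$query_id)
  deg_a <- sum(threshold_view(aug, 1)$adjacency["a", ])
  expect_equal(deg_a, 4) # star power of a rises 3 -> 4
  expect_equal(delta_sm(hq$graph, hq$eb, 1, 4), 2L) # a and q both reach 4
})

test_that("query deltas on small complete graphs match hand evaluation", {
  k3 <- graph_from_adjacency(matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3])) - diag(3))
  zero <- setNames(numeric(3), letters[1:3])
  expect_equal(delta_ac(k3, zero, 0), (3 * 1 + 0) / 4 - 1) # -1/4
  expect_equal(delta_ge(k3, zero, 0), 0)
  expect_equal(delta_tr(k3, zero, 0), 0L)
  full <- setNames(rep(1, 3), letters[1:3])
  expect_equal(delta_ac(k3, full, 0), 0) # K3 + full query = K4
  expect_equal(delta_tr(k3, full, 0), 3L) # choose(3, 2) new triangles
  # pendant edge on K2: energy rises from 2 to 2 sqrt 2
  k2 <- graph_from_adjacency(matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(delta_ge(k2, c(a = 1, b = 0), 0), 2 * sqrt(2) - 2)
  # K4 plus a fully attached query gains choose(4, 2) triangles
  k4 <- graph_from_adjacency(matrix(1, 4, 4, dimnames = list(paste0("v", 1:4), paste0("v", 1:4))) - diag(4))
  expect_equal(delta_tr(k4, setNames(rep(1, 4), paste0("v", 1:4)), 0), 6L)
})

test_that("all five features agree with brute-force oracles on random graphs", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    a <- rand_adjacency(n, 0.3)
    v <- view_from_adjacency(a)
    expect_equal(avg_clustering(v), oracle_ac(a), tolerance = 1e-9)
    r <- sample(0:4, 1)
    p <- sample(1:4, 1)
    expect_equal(rich_club(v, r), oracle_rc(a, r), tolerance = 1e-9)
    expect_equal(star_motifs(v, p), oracle_sm(a, p))
    expect_equal(triangles(v), oracle_tr(a))
    expect_equal(graph_energy(v), oracle_ge(a), tolerance = 1e-9)
  }
})

test_that("clustering and triangle counts agree with igraph", {
  set.seed(31)
  for (rep in 1:25) {
    a <- rand_adjacency(sample(3:12, 1), 0.35)
    ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    v <- view_from_adjacency(a)
    expect_equal(
      avg_clustering(v),
      mean(igraph::transitivity(ig, type = "localundirected", isolates = "zero")),
      tolerance = 1e-12
    )
    expect_equal(triangles(v), sum(igraph::count_triangles(ig)) / 3)
  }
})

test_that("random query deltas match the oracle on both graphs", {
  set.seed(19)
  for (rep in 1:40) {
    n <- sample(3:10, 1)
    a <- rand_adjacency(n, 0.35)
    g <- graph_from_adjacency(a)
    q <- rbinom(n, 1, 0.5)
    eb <- setNames(as.numeric(q), rownames(a))
    aug <- augment_adjacency(a, q)
    r <- sample(0:3, 1)
    p <- sample(1:4, 1)
    expect_equal(delta_ac(g, eb, 1), oracle_ac(aug) - oracle_ac(a), tolerance = 1e-9)
    expect_equal(delta_rc(g, eb, 1, r), oracle_rc(aug, r) - oracle_rc(a, r), tolerance = 1e-9)
    expect_equal(delta_sm(g, eb, 1, p), oracle_sm(aug, p) - oracle_sm(a, p))
    expect_equal(delta_tr(g, eb, 1), oracle_tr(aug) - oracle_tr(a))
    expect_equal(delta_ge(g, eb, 1), oracle_ge(aug) - oracle_ge(a), tolerance = 1e-9)
    # adding a vertex can never destroy triangles or shrink degrees
    expect_gte(delta_tr(g, eb, 1), 0)
    expect_gte(delta_sm(g, eb, 1, p), 0)
  }
})

test_that("counts decrease along the pyramid and the spectrum balances", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    a <- rand_adjacency(n, 0.5)
    w <- a * matrix(sample(1:10, n * n, TRUE), n)
    w <- pmax(w, t(w)) * a
    g <- graph_from_adjacency(a)
    g$weights <- w
    ts <- sort(sample(1:10, 3))
    tr_vals <- vapply(ts, function(t) triangles(threshold_view(g, t)), integer(1))
    sm_vals <- vapply(ts, function(t) star_motifs(threshold_view(g, t), 2), integer(1))
    expect_false(is.unsorted(rev(tr_vals)))
    expect_false(is.unsorted(rev(sm_vals)))
    # SM is nonincreasing in p at fixed t
    v <- threshold_view(g, ts[1])
    sm_p <- vapply(1:5, function(p) star_motifs(v, p), integer(1))
    expect_false(is.unsorted(rev(sm_p)))
    # eigenvalues of an adjacency sum to zero, so GE = 2 * positive part
    ev <- eigen(v$adjacency, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev), 0, tolerance = 1e-9)
    expect_equal(graph_energy(v), 2 * sum(ev[ev > 0]), tolerance = 1e-9)
  }
})

test_that("feature sweeps tabulate every family, feature and level", {
  fx <- example_three_class_model()
  sw <- feature_sweep(fx$model)
  expect_s3_class(sw, "gp_sweep")
  expect_equal(nrow(sw), 3 * 5 * 3) # families x features x levels
  expect_setequal(unique(sw$feature), c("AC", "RC", "SM", "TR", "GE"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_sweep(sw, tf)
  back <- utils::read.delim(tf)
  expect_equal(nrow(back), nrow(sw))
  expect_equal(names(back), c("family", "feature", "t", "value"))
})
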