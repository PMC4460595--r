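# Brute-force reference implementations and small graph builders.
# Each oracle follows the written definition directly (per-node loops,
# triple enumeration, singular values), independent of the package's
# matrix-algebra implementations.

rand_adjacency <- function(n, p = 0.3) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- rbinom(length(up), 1, p)
  a <- a + t(a)
  ids <- paste0("v", seq_len(n))
  dimnames(a) <- list(ids, ids)
  a
}

view_from_adjacency <- function(a, t = 1) {
  structure(list(ids = rownames(a), t = t, adjacency = a * 1),
    class = "threshold_view"
  )
}

graph_from_adjacency <- function(a, weight = 1, label = "test") {
  ppsnet:::new_family_graph(label, rownames(a), a * weight)
}

oracle_ac <- function(a) {
  n <- nrow(a)
  if (n == 0) {
    return(0)
  }
  cn <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] != 0)
    if (length(nb) < 2) next
    e <- 0
    for (x in seq_along(nb)) {
      for (y in seq_len(x - 1)) {
        if (a[nb[x], nb[y]] != 0) e <- e + 1
      }
    }
    cn[i] <- 2 * e / (length(nb) * (length(nb) - 1))
  }
  mean(cn)
}

oracle_rc <- function(a, r) {
  deg <- apply(a, 1, function(row) sum(row != 0))
  rich <- which(deg > r)
  if (length(rich) < 2) {
    return(0)
  }
  e <- 0
  for (x in seq_along(rich)) {
    for (y in seq_len(x - 1)) {
      if (a[rich[x], rich[y]] != 0) e <- e + 1
    }
  }
  2 * e / (length(rich) * (length(rich) - 1))
}

oracle_sm <- function(a, p) {
  deg <- apply(a, 1, function(row) sum(row != 0))
  sum(deg >= p)
}

oracle_tr <- function(a) {
  n <- nrow(a)
  if (n < 3) {
    return(0L)
  }
  count <- 0L
  trips <- combn(n, 3)
  for (k in seq_len(ncol(trips))) {
    i <- trips[1, k]
    j <- trips[2, k]
    l <- trips[3, k]
    if (a[i, j] != 0 && a[j, l] != 0 && a[i, l] != 0) count <- count + 1L
  }
  count
}

# for a symmetric matrix the singular values are the absolute eigenvalues
oracle_ge <- function(a) {
  if (sum(a != 0) == 0) {
    return(0)
  }
  sum(svd(a)$d)
}

# attach a query row to a raw adjacency (unit weights)
augment_adjacency <- function(a, q) {
  ids <- c(rownames(a), "q")
  aug <- rbind(cbind(a, q), c(q, 0))
  dimnames(aug) <- list(ids, ids)
  aug
}

# small helper: score table from an explicit edge list
edges_table <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(e) {
    data.frame(
      id_a = as.character(e[[1]]), id_b = as.character(e[[2]]),
      eb = as.numeric(e[[3]])
    )
  }))
  ppsnet:::as_score_table(tibble::as_tibble(df))
}
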