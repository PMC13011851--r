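# Independent brute-force oracles and random-instance generators used by the
# property suites. Everything here is deliberately naive (enumeration, dense
# matrix algebra) and shares no code path with the package implementations.

toy_corpus <- function(sets) acu_corpus(sets)

# Random corpus: each item included independently; empty transactions redrawn.
random_corpus <- function(n, n_items, p = 0.4, seed = 1) {
  vocab <- sprintf("IT%d", seq_len(n_items))
  set.seed(seed)
  sets <- lapply(seq_len(n), function(i) {
    repeat {
      s <- vocab[runif(n_items) < p]
      if (length(s) > 0) return(s)
    }
  })
  acu_corpus(setNames(sets, sprintf("t%03d", seq_len(n))))
}

# Exhaustive frequent-itemset enumeration over all subsets of size <= max_size.
oracle_itemsets <- function(corpus, min_support, max_size) {
  vocab <- corpus_vocabulary(corpus)
  n <- n_transactions(corpus)
  out <- list()
  for (k in seq_len(min(max_size, length(vocab)))) {
    combs <- utils::combn(vocab, k, simplify = FALSE)
    for (s in combs) {
      cnt <- sum(vapply(corpus$items, function(t) all(s %in% t), TRUE))
      if (cnt / n >= min_support - 1e-12)
        out[[length(out) + 1]] <- list(items = s, count = cnt)
    }
  }
  out
}

itemset_keys <- function(items_list)
  sort(unname(vapply(items_list, paste, "", collapse = "+")))

# Exhaustive rule enumeration under the antecedent-support convention.
oracle_rules <- function(corpus, min_support, min_confidence, max_antecedent) {
  vocab <- corpus_vocabulary(corpus)
  n <- n_transactions(corpus)
  contains <- function(s) sum(vapply(corpus$items, function(t) all(s %in% t), TRUE))
  out <- character(0)
  for (k in seq_len(min(max_antecedent, length(vocab) - 1))) {
    for (a in utils::combn(vocab, k, simplify = FALSE)) {
      n_a <- contains(a)
      if (n_a / n < min_support - 1e-12) next
      for (cons in setdiff(vocab, a)) {
        conf <- contains(c(a, cons)) / n_a
        if (conf >= min_confidence - 1e-12)
          out <- c(out, paste(paste(a, collapse = "+"), cons, sep = "=>"))
      }
    }
  }
  sort(out)
}

# --- graph oracles (dense adjacency matrix in, plain numerics out) ----------

graph_from_edges <- function(edges, weight = NULL) {
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  m <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (is.null(weight)) weight <- rep(1L, nrow(edges))
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    m[i, j] <- m[j, i] <- as.integer(weight[e])
  }
  diag(m) <- 1L  # harmless: build_graph only reads the upper triangle
  suppressMessages(build_graph(m, min_weight = 1L))
}

complete_graph <- function(n, labels = sprintf("N%02d", seq_len(n))) {
  graph_from_edges(t(utils::combn(labels, 2)))
}

adjacency_of <- function(g) {
  n <- length(g$nodes)
  a <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (e in seq_along(g$from)) a[g$from[e], g$to[e]] <- a[g$to[e], g$from[e]] <- 1
  a
}

# Random connected simple graph as an acu_graph (retry G(n, p) until connected).
random_connected_graph <- function(n, p = NULL, seed = 1) {
  if (is.null(p)) p <- min(1, 1.8 * log(n) / n)
  set.seed(seed)
  labels <- sprintf("N%02d", seq_len(n))
  repeat {
    pairs <- t(utils::combn(labels, 2))
    keep <- runif(nrow(pairs)) < p
    if (sum(keep) == 0) next
    g <- graph_from_edges(pairs[keep, , drop = FALSE])
    if (length(g$nodes) == n && all(is.finite(oracle_distances(adjacency_of(g))))) return(g)
  }
}

# Floyd-Warshall all-pairs distances.
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  dimnames(d) <- dimnames(a)
  d
}

# Shortest-path counts via adjacency-matrix powers: all walks of length
# dist(u, v) between u and v are shortest paths.
oracle_path_counts <- function(a, d) {
  n <- nrow(a)
  maxd <- max(d[is.finite(d)])
  pow <- vector("list", maxd)
  pow[[1]] <- a
  if (maxd >= 2) for (k in 2:maxd) pow[[k]] <- pow[[k - 1]] %*% a
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) sigma[i, j] <- pow[[d[i, j]]][i, j]
  }
  sigma
}

# Pair-summation betweenness: independent of Brandes accumulation.
oracle_betweenness <- function(a) {
  d <- oracle_distances(a)
  sigma <- oracle_path_counts(a, d)
  n <- nrow(a)
  bc <- numeric(n)
  for (u in seq_len(n - 1)) for (w in (u + 1):n) {
    if (u == w || !is.finite(d[u, w])) next
    for (v in seq_len(n)) {
      if (v == u || v == w) next
      if (is.finite(d[u, v]) && is.finite(d[v, w]) && d[u, v] + d[v, w] == d[u, w])
        bc[v] <- bc[v] + sigma[u, v] * sigma[v, w] / sigma[u, w]
    }
  }
  setNames(bc, rownames(a))
}

oracle_closeness <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  setNames(vapply(seq_len(n), function(v) {
    reach <- setdiff(which(is.finite(d[v, ])), v)
    if (length(reach) == 0) 0 else length(reach) / sum(d[v, reach])
  }, 0), rownames(a))
}

oracle_eigenvector <- function(a) {
  e <- eigen(a, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  setNames(v / max(v), rownames(a))
}

oracle_clustering <- function(a) {
  tri <- diag(a %*% a %*% a) / 2
  deg <- rowSums(a)
  setNames(ifelse(deg < 2, 0, tri / (deg * (deg - 1) / 2)), rownames(a))
}

# 39-node graph in which `hub` has the given degree and every non-neighbor of
# the hub hangs at distance two (off a single neighbor).
backsolve_graph <- function(hub, degree, n = 39) {
  others <- sprintf("X%02d", seq_len(n - 1))
  nb <- others[seq_len(degree)]
  far <- setdiff(others, nb)
  edges <- rbind(cbind(hub, nb),
                 if (length(far) > 0) cbind(nb[1], far))
  graph_from_edges(edges)
}
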