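# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

new_acu_graph <- function(nodes, from, to, weight) {
  adj <- vector("list", length(nodes))
  for (e in seq_along(from)) {
    adj[[from[e]]] <- c(adj[[from[e]]], to[e])
    adj[[to[e]]] <- c(adj[[to[e]]], from[e])
  }
  adj <- lapply(adj, function(x) sort(unique(x)))
  structure(list(nodes = nodes, from = from, to = to,
                 weight = weight, adj = adj),
            class = "acu_graph")
}

#' @export
print.acu_graph <- function(x, ...) {
  cat(sprintf("<acu_graph> %d nodes, %d weighted edges\n",
              length(x$nodes), length(x$from)))
  invisible(x)
}

#' Build the co-prescription network from a co-occurrence matrix
#'
#' Undirected simple graph with one edge per point pair co-prescribed at least
#' `min_weight` times; the edge weight is the raw co-occurrence count. Items
#' left without any edge (isolates) are dropped with a message, mirroring how
#' very rare points fall out of published co-prescription networks.
#'
#' @param m symmetric count matrix from [cooccurrence_matrix()]
#' @param min_weight minimum co-occurrence count for an edge (>= 1)
#' @return an `acu_graph`
#' @export
build_graph <- function(m, min_weight = 1L) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), min_weight >= 1)
  items <- colnames(m)
  idx <- which(upper.tri(m) & m >= min_weight, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty graph: no point pair reaches min_weight = ", min_weight)
  used <- sort(unique(c(idx[, 1], idx[, 2])))
  dropped <- setdiff(seq_along(items), used)
  if (length(dropped) > 0L)
    message("dropping ", length(dropped), " isolate node(s): ",
            paste(items[dropped], collapse = ", "))
  remap <- match(seq_along(items), used)
  new_acu_graph(items[used],
                from = remap[idx[, 1]], to = remap[idx[, 2]],
                weight = as.numeric(m[idx]))
}

#' Convert to an igraph object
#' @param g an `acu_graph`
#' @return an [igraph::graph] with edge attribute `weight`
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "acu_graph"))
  ig <- igraph::graph_from_edgelist(
    cbind(g$nodes[g$from], g$nodes[g$to]), directed = FALSE)
  igraph::E(ig)$weight <- g$weight
  igraph::permute(ig, match(igraph::V(ig)$name, g$nodes))
}

#' Node degrees
#' @param g an `acu_graph`
#' @return named integer vector; always sums to twice the edge count
#' @export
degree_table <- function(g) {
  stopifnot(inherits(g, "acu_graph"))
  stats::setNames(lengths(g$adj), g$nodes)
}

# Sum of incident edge weights per node.
strength_table <- function(g) {
  s <- numeric(length(g$nodes))
  for (e in seq_along(g$from)) {
    s[g$from[e]] <- s[g$from[e]] + g$weight[e]
    s[g$to[e]] <- s[g$to[e]] + g$weight[e]
  }
  stats::setNames(s, g$nodes)
}

bfs_distances <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  queue <- s; head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) if (is.infinite(d[w])) {
      d[w] <- d[v] + 1
      queue <- c(queue, w)
    }
  }
  d
}

#' All-pairs shortest-path distances
#'
#' Unweighted breadth-first search from every node. Disconnected pairs get
#' `Inf`.
#' @param g an `acu_graph`
#' @return symmetric numeric matrix with zero diagonal
#' @export
graph_distances <- function(g) {
  stopifnot(inherits(g, "acu_graph"))
  n <- length(g$nodes)
  d <- matrix(Inf, n, n, dimnames = list(g$nodes, g$nodes))
  for (s in seq_len(n)) d[s, ] <- bfs_distances(g$adj, s)
  d
}

#' Closeness centrality
#'
#' Classical closeness `(n - 1) / sum of distances` on a connected graph. On a
#' disconnected graph it is computed per component as
#' `(n_comp - 1) / sum of within-component distances` and the result carries a
#' `disconnected = TRUE` attribute plus a warning.
#'
#' @param g an `acu_graph`
#' @param dist optional precomputed matrix from [graph_distances()]
#' @return named numeric vector in `[0, 1]`
#' @export
closeness_centrality <- function(g, dist = graph_distances(g)) {
  n <- nrow(dist)
  disconnected <- any(is.infinite(dist))
  out <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(dist[v, ]) & seq_len(n) != v)
    out[v] <- if (length(reach) == 0L) 0 else length(reach) / sum(dist[v, reach])
  }
  out <- stats::setNames(out, rownames(dist))
  if (disconnected) {
    warning("graph is disconnected; closeness computed per component")
    attr(out, "disconnected") <- TRUE
  }
  out
}

#' Betweenness centrality (Brandes accumulation)
#'
#' Unnormalized shortest-path betweenness on the unweighted graph; each
#' unordered node pair is counted once and endpoints are excluded, so values
#' match the convention of published acupoint-network centrality tables
#' (values well above 1 on hub nodes).
#'
#' @param g an `acu_graph`
#' @return named numeric vector
#' @export
betweenness_centrality <- function(g) {
  stopifnot(inherits(g, "acu_graph"))
  adj <- g$adj
  n <- length(adj)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    d <- rep(-1L, n); d[s] <- 0L
    pred <- vector("list", n)
    queue <- s; head <- 1L; order_visited <- integer(0)
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (d[w] < 0L) { d[w] <- d[v] + 1L; queue <- c(queue, w) }
        if (d[w] == d[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in pred[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc / 2, g$nodes)  # undirected: each pair visited from both ends
}

#' Eigenvector centrality by power iteration
#'
#' Power iteration on the (binary) adjacency matrix of a connected graph,
#' rescaled after convergence so the maximum score is exactly 1 (the
#' convention in which the top hub prints as 1).
#'
#' @param g a connected `acu_graph`
#' @param tol convergence tolerance on the max-normalized iterate
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   iteration count
#' @return named numeric vector with max = 1
#' @export
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(g, "acu_graph"))
  adj <- g$adj
  n <- length(adj)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    xn <- vapply(seq_len(n), function(v) sum(x[adj[[v]]]), 0)
    xn <- xn / max(xn)
    if (max(abs(xn - x)) < tol)
      return(stats::setNames(xn, g$nodes))
    x <- xn
  }
  stop("eigenvector centrality did not converge after ", max_iter, " iterations")
}

#' Local clustering coefficients
#'
#' Watts-Strogatz local clustering: triangles through a node divided by
#' `deg * (deg - 1) / 2`; nodes of degree < 2 contribute 0.
#' @param g an `acu_graph`
#' @return named numeric vector in `[0, 1]`
#' @export
local_clustering <- function(g) {
  stopifnot(inherits(g, "acu_graph"))
  adj <- g$adj
  n <- length(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2L) next
    links <- 0L
    for (i in seq_len(k - 1L))
      links <- links + sum(adj[[nb[i]]] %in% nb[(i + 1L):k])
    out[v] <- links / (k * (k - 1) / 2)
  }
  stats::setNames(out, g$nodes)
}

#' Mean clustering coefficient and average path length
#'
#' `C` is the mean of the local clustering coefficients ([local_clustering()]);
#' `L` is the mean shortest-path distance over unordered CONNECTED node pairs.
#'
#' @param g an `acu_graph` with at least one edge
#' @param dist optional precomputed distance matrix
#' @return list with elements `C` and `L`
#' @export
clustering_and_path_length <- function(g, dist = graph_distances(g)) {
  up <- dist[upper.tri(dist)]
  finite <- up[is.finite(up)]
  list(C = mean(local_clustering(g)),
       L = if (length(finite) == 0L) NA_real_ else mean(finite))
}

# Uniform random simple graph with n nodes and m edges (Erdos-Renyi G(n, m)),
# returned as an adjacency list.
random_gnm_adj <- function(n, m, pairs) {
  chosen <- pairs[, sample.int(ncol(pairs), m), drop = FALSE]
  adj <- vector("list", n)
  for (e in seq_len(m)) {
    i <- chosen[1L, e]; j <- chosen[2L, e]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

adj_to_graph <- function(adj, nodes = as.character(seq_along(adj))) {
  from <- integer(0); to <- integer(0)
  for (v in seq_along(adj)) for (w in adj[[v]]) if (w > v) {
    from <- c(from, v); to <- c(to, w)
  }
  new_acu_graph(nodes, from, to, rep(1, length(from)))
}

#' Small-world assessment against an Erdos-Renyi ensemble
#'
#' Computes the observed mean path length `L`, mean clustering `C` and their
#' ratio `L / C`, and compares them with the means over an ensemble of uniform
#' random G(n, m) graphs with the same node and edge counts. For random
#' replicates (which can be disconnected) `L` is measured on the largest
#' connected component. A co-prescription network organized around core points
#' shows a much SMALLER L/C than its random baseline, because clustering stays
#' high while paths stay short.
#'
#' @param g an `acu_graph`
#' @param n_replicates ensemble size (default 1000)
#' @param seed RNG seed for the ensemble (Mersenne-Twister)
#' @return object of class `small_world_report`: list with `L_obs`, `C_obs`,
#'   `ratio_obs`, `L_rand_mean`, `C_rand_mean`, `ratio_rand`, `n_replicates`,
#'   `seed`, `n_nodes`, `n_edges`; `ratio_obs` is `NA` (with a warning) when
#'   `C_obs` is 0
#' @export
small_world_report <- function(g, n_replicates = 1000L, seed = 1L) {
  stopifnot(inherits(g, "acu_graph"), n_replicates >= 1L)
  obs <- clustering_and_path_length(g)
  if (obs$C == 0) warning("observed clustering coefficient is 0; L/C undefined")
  n <- length(g$nodes); m <- length(g$from)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- t(pairs)  # 2 x choose(n,2)
  Ls <- numeric(n_replicates); Cs <- numeric(n_replicates)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      adj <- random_gnm_adj(n, m, pairs)
      rg <- adj_to_graph(adj)
      d <- graph_distances(rg)
      Cs[r] <- mean(local_clustering(rg))
      # largest-component L
      comp <- component_labels(adj)
      big <- which.max(tabulate(comp))
      inside <- which(comp == big)
      dd <- d[inside, inside, drop = FALSE]
      up <- dd[upper.tri(dd)]
      Ls[r] <- if (length(up) == 0L) NA_real_ else mean(up)
    }
  })
  structure(list(
    L_obs = obs$L, C_obs = obs$C,
    ratio_obs = if (obs$C > 0) obs$L / obs$C else NA_real_,
    L_rand_mean = mean(Ls, na.rm = TRUE),
    C_rand_mean = mean(Cs),
    ratio_rand = if (mean(Cs) > 0) mean(Ls, na.rm = TRUE) / mean(Cs) else NA_real_,
    n_replicates = n_replicates, seed = seed,
    n_nodes = n, n_edges = m,
    rng = "Mersenne-Twister"), class = "small_world_report")
}

#' @export
print.small_world_report <- function(x, ...) {
  cat(sprintf("<small_world_report> %d nodes / %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  observed: L = %.3f, C = %.3f, L/C = %.3f\n",
              x$L_obs, x$C_obs, x$ratio_obs))
  cat(sprintf("  G(n,m) baseline (%d replicates, seed %d): L = %.3f, C = %.3f, L/C = %.3f\n",
              x$n_replicates, x$seed, x$L_rand_mean, x$C_rand_mean, x$ratio_rand))
  invisible(x)
}

component_labels <- function(adj) {
  n <- length(adj)
  lab <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s; head <- 1L; lab[s] <- comp
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) if (lab[w] == 0L) { lab[w] <- comp; queue <- c(queue, w) }
    }
  }
  lab
}

#' k-core decomposition
#'
#' Standard peeling: repeatedly remove the minimum-degree node, recording for
#' each node the largest k such that it belongs to the k-core (the maximal
#' subgraph in which every node has at least k neighbors inside it). The
#' maximum core defines the core prescription set.
#'
#' @param g an `acu_graph`
#' @return list of class `core_decomposition`: `coreness` (named integer),
#'   `k_max`, and `core_set` (nodes with coreness = `k_max`)
#' @export
kcore_decomposition <- function(g) {
  stopifnot(inherits(g, "acu_graph"))
  adj <- g$adj
  n <- length(adj)
  deg <- lengths(adj)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  for (step in seq_len(n)) {
    cand <- which(alive)
    v <- cand[order(deg[cand], cand)][1L]
    k <- max(k, deg[v])
    core[v] <- k
    alive[v] <- FALSE
    for (w in adj[[v]]) if (alive[w]) deg[w] <- deg[w] - 1L
  }
  core <- stats::setNames(core, g$nodes)
  structure(list(coreness = core, k_max = max(core),
                 core_set = g$nodes[core == max(core)]),
            class = "core_decomposition")
}

#' @export
print.core_decomposition <- function(x, ...) {
  cat(sprintf("<core_decomposition> k_max = %d; %d node(s) in the maximum core: %s\n",
              x$k_max, length(x$core_set), paste(x$core_set, collapse = ", ")))
  invisible(x)
}

#' Community detection by weighted modularity maximization
#'
#' Louvain multilevel optimization of weighted modularity (via igraph), with a
#' fixed seed for deterministic output.
#'
#' @param g an `acu_graph` with at least one edge
#' @param seed RNG seed
#' @param resolution modularity resolution parameter (1 = classical)
#' @return list of class `community_partition`: `assignment` (named integer),
#'   `n_communities`, `modularity`, `seed`, `resolution`
#' @export
detect_communities <- function(g, seed = 1L, resolution = 1) {
  stopifnot(inherits(g, "acu_graph"))
  ig <- as_igraph(g)
  cl <- with_seed(seed, igraph::cluster_louvain(
    ig, weights = igraph::E(ig)$weight, resolution = resolution))
  member <- stats::setNames(as.integer(igraph::membership(cl)), g$nodes)
  structure(list(assignment = member,
                 n_communities = length(unique(member)),
                 modularity = igraph::modularity(ig, member,
                                                 weights = igraph::E(ig)$weight,
                                                 resolution = resolution),
                 seed = seed, resolution = resolution),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, modularity %.4f (seed %d)\n",
              x$n_communities, x$modularity, x$seed))
  invisible(x)
}

#' Fruchterman-Reingold force-directed layout
#'
#' Standard attractive (`d^2 / k`) / repulsive (`k^2 / d`) force schedule in a
#' unit-area frame with `k = sqrt(area / n)` and linear cooling, reproducible
#' from the seed. Layout is for reporting/export only; no metric depends on
#' it. A single node is placed at the origin.
#'
#' @param g an `acu_graph`
#' @param iterations number of force iterations
#' @param seed RNG seed for initial placement
#' @param area layout area (default 1, the unit square)
#' @return data.frame with columns `node`, `x`, `y`; attribute `bounding_box`
#' @export
fr_layout <- function(g, iterations = 200L, seed = 1L, area = 1) {
  stopifnot(inherits(g, "acu_graph"), iterations >= 1L)
  n <- length(g$nodes)
  if (n == 1L) {
    out <- data.frame(node = g$nodes, x = 0, y = 0, stringsAsFactors = FALSE)
    attr(out, "bounding_box") <- c(xmin = 0, xmax = 0, ymin = 0, ymax = 0)
    return(out)
  }
  k <- sqrt(area / n)
  pos <- with_seed(seed, matrix(stats::runif(2 * n, -0.5, 0.5), n, 2))
  t0 <- 0.1 * sqrt(area)
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2)
    for (v in seq_len(n - 1L)) for (w in (v + 1L):n) {
      delta <- pos[v, ] - pos[w, ]
      d <- max(sqrt(sum(delta^2)), 1e-9)
      rep_f <- (k^2 / d) * (delta / d)
      disp[v, ] <- disp[v, ] + rep_f
      disp[w, ] <- disp[w, ] - rep_f
    }
    for (e in seq_along(g$from)) {
      v <- g$from[e]; w <- g$to[e]
      delta <- pos[v, ] - pos[w, ]
      d <- max(sqrt(sum(delta^2)), 1e-9)
      att_f <- (d^2 / k) * (delta / d)
      disp[v, ] <- disp[v, ] - att_f
      disp[w, ] <- disp[w, ] + att_f
    }
    temp <- t0 * (1 - (it - 1) / iterations)
    for (v in seq_len(n)) {
      d <- sqrt(sum(disp[v, ]^2))
      if (d > 0) pos[v, ] <- pos[v, ] + disp[v, ] / d * min(d, temp)
    }
  }
  out <- data.frame(node = g$nodes, x = pos[, 1], y = pos[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "bounding_box") <- c(xmin = min(pos[, 1]), xmax = max(pos[, 1]),
                                 ymin = min(pos[, 2]), ymax = max(pos[, 2]))
  out
}

#' Full centrality table
#'
#' Degree, unnormalized betweenness, closeness and max-normalized eigenvector
#' centrality for every node, in the column order of published core-acupoint
#' tables, ordered by degree descending (ties by code). Also carries the
#' weighted degree (`strength`) as an auxiliary column.
#'
#' @param g an `acu_graph`
#' @param eigen_tol,eigen_max_iter passed to [eigenvector_centrality()]
#' @return data.frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`, `eigenvector`, `strength`
#' @export
centrality_table <- function(g, eigen_tol = 1e-10, eigen_max_iter = 1000L) {
  dist <- graph_distances(g)
  connected <- all(is.finite(dist))
  df <- data.frame(
    node = g$nodes,
    degree = as.integer(degree_table(g)),
    betweenness = as.numeric(betweenness_centrality(g)),
    closeness = as.numeric(suppressWarnings(closeness_centrality(g, dist))),
    eigenvector = if (connected)
      as.numeric(eigenvector_centrality(g, eigen_tol, eigen_max_iter))
    else NA_real_,
    strength = as.numeric(strength_table(g)),
    stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$node), , drop = FALSE]
  rownames(df) <- NULL
  df
}
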