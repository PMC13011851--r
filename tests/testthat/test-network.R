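triangle <- function() graph_from_edges(cbind(c("A1", "B1", "A1"), c("B1", "C1", "C1")))
path3 <- function() graph_from_edges(cbind(c("A1", "B1"), c("B1", "C1")))

test_that("graph construction thresholds edges and drops isolates", {
  m <- matrix(0L, 3, 3, dimnames = list(c("A1", "B1", "C1"), c("A1", "B1", "C1")))
  m["A1", "B1"] <- m["B1", "A1"] <- 2L
  m["A1", "C1"] <- m["C1", "A1"] <- 1L
  diag(m) <- 3L

  g1 <- suppressMessages(build_graph(m, 1))
  expect_equal(length(g1$nodes), 3L)
  expect_equal(length(g1$from), 2L)

  expect_message(g2 <- build_graph(m, 2), "C1")
  expect_equal(g2$nodes, c("A1", "B1"))
  expect_equal(length(g2$from), 1L)
  expect_equal(g2$weight, 2)

  m0 <- m; m0[upper.tri(m0)] <- 0L; m0[lower.tri(m0)] <- 0L
  expect_error(build_graph(m0, 1), "empty graph")
})

test_that("degrees satisfy the handshake lemma on toys and random graphs", {
  expect_equal(unname(degree_table(triangle())), c(2L, 2L, 2L))
  star <- graph_from_edges(cbind("HUB1", sprintf("L%d", 1:4)))
  d <- degree_table(star)
  expect_equal(d[["HUB1"]], 4L)
  expect_equal(sort(unname(d[names(d) != "HUB1"])), rep(1L, 4))
  for (seed in 1:5) {
    g <- random_connected_graph(12, seed = seed)
    expect_equal(sum(degree_table(g)), 2L * length(g$from))
  }
})

test_that("BFS distances agree with Floyd-Warshall and basic metric axioms", {
  d <- graph_distances(path3())
  expect_equal(d["A1", "C1"], 2)
  expect_equal(unname(diag(d)), rep(0, 3))

  k4 <- complete_graph(4)
  dk <- graph_distances(k4)
  expect_true(all(dk[upper.tri(dk)] == 1))

  for (seed in 1:5) {
    g <- random_connected_graph(15, seed = 20 + seed)
    expect_equal(graph_distances(g), oracle_distances(adjacency_of(g)))
  }

  # disconnected pairs flagged as Inf
  two <- graph_from_edges(cbind(c("A1", "C1"), c("B1", "D1")))
  expect_true(is.infinite(graph_distances(two)["A1", "C1"]))
})

test_that("closeness matches the classical definition and printed back-solves", {
  expect_equal(unname(closeness_centrality(complete_graph(5))), rep(1, 5))

  # hub with degree d in a connected 39-node graph, everyone else at distance 2
  for (case in list(c("ST36", 37), c("CV12", 31), c("PC6", 27))) {
    g <- backsolve_graph(case[1], as.integer(case[2]))
    cl <- closeness_centrality(g)
    expect_equal(unname(cl[case[1]]),
                 38 / (as.integer(case[2]) + 2 * (38 - as.integer(case[2]))))
  }

  expect_warning(closeness_centrality(graph_from_edges(
    cbind(c("A1", "C1"), c("B1", "D1")))), "disconnected")
})

test_that("betweenness uses unordered-pair counting and matches the path-count oracle", {
  bc <- betweenness_centrality(path3())
  expect_equal(unname(bc[c("A1", "B1", "C1")]), c(0, 1, 0))

  star <- graph_from_edges(cbind("HUB1", sprintf("L%d", 1:5)))
  expect_equal(betweenness_centrality(star)[["HUB1"]], choose(5, 2))

  for (seed in 1:5) {
    g <- random_connected_graph(12, seed = 40 + seed)
    expect_equal(betweenness_centrality(g),
                 oracle_betweenness(adjacency_of(g)), tolerance = 1e-9)
  }
})

test_that("eigenvector centrality is max-normalized and matches dense eigendecomposition", {
  # k-regular connected graphs have the uniform principal eigenvector
  expect_equal(unname(eigenvector_centrality(complete_graph(6))), rep(1, 6))
  cyc <- graph_from_edges(cbind(sprintf("N%d", 1:5), sprintf("N%d", c(2:5, 1))))
  expect_equal(unname(eigenvector_centrality(cyc)), rep(1, 5))

  for (seed in 1:5) {
    g <- random_connected_graph(10, seed = 60 + seed)
    expect_equal(eigenvector_centrality(g, tol = 1e-12),
                 oracle_eigenvector(adjacency_of(g)), tolerance = 1e-8)
  }
  expect_error(eigenvector_centrality(path3(), tol = 0, max_iter = 3L),
               "did not converge")
})

test_that("clustering coefficient and path length follow the Watts-Strogatz convention", {
  expect_equal(clustering_and_path_length(triangle()), list(C = 1, L = 1))
  expect_equal(clustering_and_path_length(path3()), list(C = 0, L = 4 / 3))

  for (seed in 1:5) {
    g <- random_connected_graph(14, seed = 80 + seed)
    got <- clustering_and_path_length(g)
    a <- adjacency_of(g)
    expect_equal(got$C, mean(oracle_clustering(a)), tolerance = 1e-12)
    d <- oracle_distances(a)
    expect_equal(got$L, mean(d[upper.tri(d)]), tolerance = 1e-12)
  }
})

test_that("small-world report: complete graph degenerates to ratio 1, ER baseline saturates", {
  sw <- small_world_report(complete_graph(10), n_replicates = 3, seed = 1)
  expect_equal(sw$L_obs, 1)
  expect_equal(sw$C_obs, 1)
  expect_equal(sw$ratio_obs, 1)
  # G(n, m) with m = choose(n, 2) is the complete graph: baseline L, C -> 1
  expect_equal(sw$L_rand_mean, 1)
  expect_equal(sw$C_rand_mean, 1)

  g <- random_connected_graph(12, seed = 5)
  s1 <- small_world_report(g, n_replicates = 20, seed = 9)
  s2 <- small_world_report(g, n_replicates = 20, seed = 9)
  expect_equal(s1, s2)  # ensemble reproducible from seed
  expect_true(is.finite(s1$ratio_rand))
})

test_that("k-core peeling satisfies nesting and the minimum-within-core degree bound", {
  k4 <- complete_graph(4)
  kc <- kcore_decomposition(k4)
  expect_equal(unname(kc$coreness), rep(3L, 4))
  expect_equal(kc$k_max, 3L)

  # K4 plus a pendant: pendant peels at 1, the clique stays the maximum core
  pend <- graph_from_edges(rbind(t(utils::combn(sprintf("K%d", 1:4), 2)),
                                 c("K1", "P1")))
  kcp <- kcore_decomposition(pend)
  expect_equal(kcp$coreness[["P1"]], 1L)
  expect_equal(sort(kcp$core_set), sprintf("K%d", 1:4))

  star <- graph_from_edges(cbind("HUB1", sprintf("L%d", 1:5)))
  expect_equal(unname(kcore_decomposition(star)$coreness), rep(1L, 6))

  # nesting + defining property on random graphs
  for (seed in 1:5) {
    g <- random_connected_graph(15, seed = 120 + seed)
    kc <- kcore_decomposition(g)
    adj <- setNames(g$adj, g$nodes)
    for (k in seq_len(kc$k_max)) {
      inside <- names(kc$coreness)[kc$coreness >= k]
      expect_true(all(names(kc$coreness)[kc$coreness >= k + 1] %in% inside))
      for (v in inside) {
        nb <- g$nodes[g$adj[[match(v, g$nodes)]]]
        expect_gte(sum(nb %in% inside), k)
      }
    }
    # cross-check against igraph's coreness
    expect_equal(unname(kc$coreness), unname(igraph::coreness(as_igraph(g))))
  }
})

test_that("community detection splits joined cliques and is deterministic under seed", {
  cl5 <- t(utils::combn(sprintf("A%d", 1:5), 2))
  cl5b <- t(utils::combn(sprintf("B%d", 1:5), 2))
  g <- graph_from_edges(rbind(cl5, cl5b, c("A1", "B1")))
  cm <- detect_communities(g, seed = 3)
  expect_equal(cm$n_communities, 2L)
  expect_length(unique(cm$assignment[sprintf("A%d", 1:5)]), 1L)
  expect_length(unique(cm$assignment[sprintf("B%d", 1:5)]), 1L)
  expect_gt(cm$modularity, 0.3)
  expect_equal(detect_communities(g, seed = 3), cm)

  expect_equal(detect_communities(complete_graph(5))$n_communities, 1L)
})

test_that("force-directed layout is seed-deterministic with the pair at equilibrium spacing", {
  g <- random_connected_graph(10, seed = 2)
  l1 <- fr_layout(g, iterations = 50, seed = 11)
  l2 <- fr_layout(g, iterations = 50, seed = 11)
  expect_identical(l1, l2)
  expect_true(all(is.finite(c(l1$x, l1$y))))

  single_m <- matrix(c(1L, 1L, 1L, 1L), 2, 2, dimnames = list(c("A1", "B1"), c("A1", "B1")))
  single <- suppressMessages(build_graph(single_m, 1))
  # two connected nodes settle near the force-balance distance k = sqrt(area/n)
  pair <- fr_layout(single, iterations = 400, seed = 5)
  sep <- sqrt(diff(pair$x)^2 + diff(pair$y)^2)
  k <- sqrt(1 / 2)
  expect_lt(abs(sep - k), 0.2 * k)

  one <- fr_layout(structure(list(nodes = "A1", from = integer(0), to = integer(0),
                                  weight = numeric(0), adj = list(integer(0))),
                             class = "acu_graph"), seed = 1)
  expect_equal(c(one$x, one$y), c(0, 0))
})

test_that("graph exports are well-formed XML round-trippable by igraph", {
  g <- random_connected_graph(8, seed = 3)
  ct <- centrality_table(g)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml, node_attrs = ct)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(back), length(g$nodes))
  expect_equal(igraph::gsize(back), length(g$from))
  expect_equal(sort(igraph::V(back)$degree), sort(ct$degree))

  gexf <- withr::local_tempfile(fileext = ".gexf")
  write_gexf(g, gexf, node_attrs = ct)
  x <- xml2::read_xml(gexf)  # parses => well-formed
  expect_equal(length(xml2::xml_find_all(x, "//*[local-name()='node']")),
               length(g$nodes))

  el <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(g, el)
  df <- read.delim(el)
  expect_equal(nrow(df), length(g$from))
})

test_that("centrality table carries all metrics in degree order", {
  g <- random_connected_graph(12, seed = 77)
  ct <- centrality_table(g)
  expect_equal(names(ct), c("node", "degree", "betweenness", "closeness",
                            "eigenvector", "strength"))
  expect_true(!is.unsorted(rev(ct$degree)))
  expect_equal(max(ct$eigenvector), 1)
  expect_equal(sum(ct$degree), 2 * length(g$from))
})
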