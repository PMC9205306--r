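test_that("edges are exactly the significant correlations", {
  cs <- toy_corr(data.frame(
    trait_a = c("A", "A", "B"), trait_b = c("B", "C", "C"),
    r = c(0.9, -0.8, 0.1), n = 20, p = c(0.001, 0.01, 0.7)))
  g <- build_network(cs, alpha = 0.05)
  el <- apply(igraph::as_edgelist(g), 1, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(el, c("A-B", "A-C"))
  expect_equal(sort(igraph::E(g)$weight), c(0.8, 0.9))
  expect_setequal(igraph::E(g)$sign, c("+", "-"))

  # all insignificant: nodes retained, zero edges
  cs2 <- toy_corr(data.frame(trait_a = "A", trait_b = "B", r = 0.1,
                             n = 10, p = 0.8),
                  trait_names = LETTERS[1:10])
  g2 <- build_network(cs2, alpha = 0.05)
  expect_equal(igraph::vcount(g2), 10)
  expect_equal(igraph::ecount(g2), 0)

  # alpha = 1: complete graph on defined pairs
  set.seed(1)
  cs3 <- pearson_pairwise(matrix(rnorm(50), 10, 5,
                                 dimnames = list(NULL, LETTERS[1:5])))
  expect_equal(igraph::ecount(build_network(cs3, alpha = 1)), choose(5, 2))
})

test_that("normalized degree matches its definition including the published cells", {
  g <- igraph::make_graph(~ A - B, A - C, A - D, A - E, F - G)
  g <- igraph::add_vertices(g, 3)  # pad to a 10-node network
  d <- degree_centrality(g)
  expect_equal(round(unname(d["A"]), 2), 0.44)   # k = 4 in a 10-node network
  expect_equal(round(unname(d["F"]), 2), 0.11)   # k = 1
  expect_true(all(d >= 0 & d <= 1))
  # complete graph: all 1
  expect_true(all(degree_centrality(igraph::make_full_graph(6)) == 1))
  # removing an edge never increases degree
  g2 <- igraph::delete_edges(g, 1)
  expect_true(all(degree_centrality(g2) <= d))
})

test_that("betweenness and closeness match hand-enumerated shortest paths", {
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  b <- betweenness_centrality(star)
  expect_equal(unname(b), c(1, 0, 0, 0))

  path4 <- igraph::make_graph(~ A - B, B - C, C - D)
  expect_equal(unname(betweenness_centrality(path4)),
               c(0, 2 / 3, 2 / 3, 0))

  star5 <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star5)$name <- paste0("v", 1:5)
  cl <- closeness_centrality(star5)
  expect_equal(cl$closeness, c(1, rep(4 / 7, 4)))

  path3 <- igraph::make_graph(~ A - B, B - C)
  cl3 <- closeness_centrality(path3)
  expect_equal(cl3$closeness[cl3$trait == "B"], 1)
  expect_equal(cl3$closeness[cl3$trait == "A"], 2 / 3)

  full <- igraph::make_full_graph(5)
  igraph::V(full)$name <- paste0("v", 1:5)
  expect_true(all(closeness_centrality(full)$closeness == 1))

  # isolated nodes: closeness undefined, flagged by component
  g <- igraph::make_graph(~ A - B, C)
  cl <- closeness_centrality(g)
  expect_true(is.na(cl$closeness[cl$trait == "C"]))
  expect_error(betweenness_centrality(igraph::make_full_graph(2)), "fewer")
})

test_that("centralities ignore weights and are invariant to relabeling", {
  g <- random_connected_graph(7, seed = 5)
  gw <- g
  igraph::E(gw)$weight <- runif(igraph::ecount(g), 0.1, 0.9)
  expect_equal(betweenness_centrality(g), betweenness_centrality(gw))
  expect_equal(closeness_centrality(g)$closeness,
               closeness_centrality(gw)$closeness)
  perm <- sample(7)
  gp <- igraph::permute(g, perm)
  expect_equal(sort(unname(betweenness_centrality(g))),
               sort(unname(betweenness_centrality(gp))))
})

test_that("modularity matches hand-derived values and the definition oracle", {
  # one module: Q = 0
  tri2 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                 igraph::make_full_graph(3))
  igraph::V(tri2)$name <- paste0("v", 1:6)
  expect_equal(modularity_score(tri2, rep(0L, 6)), 0)
  # two disjoint triangles split by triangle: Q = 0.5
  expect_equal(modularity_score(tri2, c(0, 0, 0, 1, 1, 1)), 0.5)
  # two triangles joined by a bridge: Q = 6/7 - 1/2
  bridged <- igraph::add_edges(tri2, c(3, 4))
  expect_equal(modularity_score(bridged, c(0, 0, 0, 1, 1, 1)),
               6 / 7 - 0.5, tolerance = 1e-12)
  # matches the e_ii - a_i^2 oracle on random graphs and partitions
  set.seed(8)
  for (i in 1:10) {
    g <- random_connected_graph(sample(4:8, 1), seed = 100 + i)
    lab <- sample(0:2, igraph::vcount(g), replace = TRUE)
    expect_equal(modularity_score(g, lab), oracle_q(g, lab + 1),
                 tolerance = 1e-12)
  }
  expect_error(modularity_score(tri2, c(a = 1)), "unlabeled|label")
})

test_that("spinglass recovers unambiguous structure and reports consistent Q", {
  cliques <- igraph::disjoint_union(igraph::make_full_graph(5),
                                    igraph::make_full_graph(5))
  igraph::V(cliques)$name <- paste0("v", 1:10)
  igraph::E(cliques)$weight <- 1
  expect_warning(part <- spinglass_partition(cliques, seed = 1),
                 "disconnected")
  expect_equal(part$Q, 0.5)
  expect_equal(length(unique(part$membership)), 2L)
  expect_equal(ari(part$membership, rep(1:2, each = 5)), 1)
  # labels contiguous from 0; Q self-consistent to 1e-12
  expect_setequal(unique(part$membership), 0:1)
  expect_equal(part$Q, modularity_score(cliques, part$membership),
               tolerance = 1e-12)
  # determinism under a fixed seed
  p2 <- suppressWarnings(spinglass_partition(cliques, seed = 1))
  expect_identical(part$membership, p2$membership)
})
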