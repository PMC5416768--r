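path3 <- function() {
  regnetwork(data.frame(from = c("a", "b"), to = c("b", "c")),
             tf_nodes = c("a", "b", "c"))
}

test_that("out-degree counts distinct outgoing non-loop edges", {
  star <- regnetwork(data.frame(from = "t", to = paste0("g", 1:5)))
  od <- out_degree(star)
  expect_equal(unname(od["t"]), 5)
  expect_equal(unname(od[paste0("g", 1:5)]), rep(0, 5))

  # handshake identity and self-loop exclusion on random graphs
  for (i in 1:10) {
    net <- random_dignet(sample(5:25, 1), runif(1, 0.05, 0.3), seed = 100 + i)
    expect_equal(sum(out_degree(net)),
                 sum(net$edges$from != net$edges$to))
  }

  loopy <- regnetwork(data.frame(from = c("t", "t"), to = c("t", "g")))
  expect_equal(unname(out_degree(loopy)["t"]), 1)
  expect_equal(loopy$n_self_loops, 1)
})

test_that("betweenness matches hand-enumerated small instances", {
  bc <- betweenness_centrality(path3())
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))

  star <- regnetwork(data.frame(from = "t", to = paste0("g", 1:4)))
  expect_equal(unname(betweenness_centrality(star)), rep(0, 5))

  # two shortest paths sharing endpoints: a->b->d, a->c->d
  diamond <- regnetwork(data.frame(from = c("a", "a", "b", "c"),
                                   to = c("b", "c", "d", "d")))
  bc2 <- betweenness_centrality(diamond)
  expect_equal(unname(bc2[c("a", "b", "c", "d")]), c(0, 0.5, 0.5, 0))
})

test_that("eccentricity follows the finite-reachable-set convention", {
  expect_equal(unname(eccentricity(path3())[c("a", "b", "c")]), c(2, 1, 0))
  single <- regnetwork(data.frame(from = character(0), to = character(0)),
                       nodes = "x", tf_nodes = character(0))
  expect_equal(unname(eccentricity(single)), 0)
  # directed cycle: every node reaches all others, max distance n - 1
  n <- 6
  cyc <- regnetwork(data.frame(from = paste0("v", 1:n),
                               to = paste0("v", c(2:n, 1))))
  expect_equal(unname(eccentricity(cyc)), rep(n - 1, n))
})

test_that("clustering coefficient handles triangles, paths and conventions", {
  tri <- regnetwork(data.frame(from = c("a", "b", "c"),
                               to = c("b", "c", "a")))
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))
  expect_equal(unname(clustering_coefficient(path3())["b"]), 0)
  expect_equal(unname(clustering_coefficient(path3())["a"]), 0) # k < 2
})

test_that("all four metrics equal the brute-force oracle on random graphs", {
  n_graphs <- 50
  for (i in seq_len(n_graphs)) {
    n <- 4 + (i %% 27) # sizes 4..30
    p <- c(0.05, 0.1, 0.2, 0.35)[1 + (i %% 4)]
    net <- random_dignet(n, p, seed = 7000 + i)
    expect_equal(betweenness_centrality(net), oracle_betweenness(net),
                 tolerance = 1e-10)
    expect_equal(eccentricity(net), oracle_eccentricity(net))
    expect_equal(clustering_coefficient(net), oracle_clustering(net),
                 tolerance = 1e-12)
    expect_equal(sum(out_degree(net)), nrow(net$edges) - net$n_self_loops)
    # total betweenness equals the oracle's pairwise accounting
    expect_equal(sum(betweenness_centrality(net)),
                 sum(oracle_betweenness(net)), tolerance = 1e-9)
  }
})

test_that("undirected-mode metrics also match the oracle", {
  for (i in 1:10) {
    net <- random_dignet(sample(5:20, 1), 0.15, seed = 7700 + i)
    expect_equal(betweenness_centrality(net, directed = FALSE),
                 oracle_betweenness(net, directed = FALSE), tolerance = 1e-10)
    expect_equal(eccentricity(net, directed = FALSE),
                 oracle_eccentricity(net, directed = FALSE))
  }
})

test_that("metrics agree with igraph on random directed graphs", {
  skip_if_not_installed("igraph")
  for (i in 1:10) {
    net <- random_dignet(sample(6:25, 1), 0.15, seed = 8800 + i)
    g <- igraph::graph_from_data_frame(net$edges,
                                       vertices = net$nodes, directed = TRUE)
    expect_equal(betweenness_centrality(net),
                 igraph::betweenness(g, directed = TRUE, normalized = FALSE)[net$nodes],
                 tolerance = 1e-10)
    ig_cc <- igraph::transitivity(igraph::as_undirected(g, mode = "collapse"),
                                  type = "local", isolates = "zero")
    names(ig_cc) <- net$nodes
    expect_equal(clustering_coefficient(net), ig_cc, tolerance = 1e-12)
  }
})

test_that("hierarchy levels follow the longest-path rule after condensation", {
  chain <- regnetwork(data.frame(from = c("t1", "t2"), to = c("t2", "t3")),
                      tf_nodes = c("t1", "t2", "t3"))
  expect_equal(hierarchy_levels(chain), c(t1 = 3, t2 = 2, t3 = 1))

  # 2-cycle collapses into one component, sharing a level
  cyc <- regnetwork(data.frame(from = c("t1", "t2"), to = c("t2", "t1")),
                    tf_nodes = c("t1", "t2"))
  lv <- hierarchy_levels(cyc)
  expect_equal(unname(lv["t1"]), unname(lv["t2"]))

  # TF regulating only non-TF genes sits at the bottom
  mixed <- regnetwork(data.frame(from = c("t1", "t2"), to = c("t2", "g1")),
                      tf_nodes = c("t1", "t2"))
  expect_equal(hierarchy_levels(mixed), c(t1 = 2, t2 = 1))

  # cycle feeding a chain: levels count the longest path below
  net <- regnetwork(data.frame(from = c("a", "b", "b", "c"),
                               to = c("b", "a", "c", "d")),
                    tf_nodes = c("a", "b", "c", "d"))
  lv2 <- hierarchy_levels(net)
  expect_equal(unname(lv2[c("c", "d")]), c(2, 1))
  expect_equal(unname(lv2["a"]), unname(lv2["b"]))
  expect_equal(unname(lv2["a"]), 3)
})

test_that("hierarchy terminates on dense cyclic TF graphs", {
  for (i in 1:5) {
    net <- random_dignet(15, 0.3, seed = 900 + i)
    lv <- hierarchy_levels(net)
    tfs <- net$nodes[net$is_tf[net$nodes]]
    expect_equal(sort(names(lv)), sort(tfs))
    expect_true(all(lv >= 1))
  }
})

test_that("external hierarchy levels are validated and returned", {
  chain <- regnetwork(data.frame(from = c("t1", "t2"), to = c("t2", "t3")),
                      tf_nodes = c("t1", "t2", "t3"))
  ext <- data.frame(node = c("t1", "t2", "t3"), level = c(9, 5, 1))
  expect_equal(hierarchy_levels(chain, ext), c(t1 = 9, t2 = 5, t3 = 1))
  expect_error(hierarchy_levels(chain, ext[1:2, ]), class = "rs_validation")
})

test_that("ortholog mapping deduplicates and reports unmapped queries", {
  tab <- data.frame(source = c("gA", "gB"), target = c("gA2", "gB2"))
  res <- map_orthologs(c("gA", "gX"), tab)
  expect_equal(res$mapped, "gA2")
  expect_equal(res$unmapped, "gX")
  expect_equal(map_orthologs(character(0), tab),
               list(mapped = character(0), unmapped = character(0)))
  # two sources collapsing onto one target
  tab2 <- data.frame(source = c("g1", "g2"), target = c("gT", "gT"))
  expect_equal(map_orthologs(c("g1", "g2"), tab2)$mapped, "gT")
  # non-function tables are rejected
  tab3 <- data.frame(source = c("g1", "g1"), target = c("a", "b"))
  expect_error(map_orthologs("g1", tab3), class = "rs_invalid_parameter")
})

test_that("node_metrics assembles a coherent per-node table", {
  net <- simulate_regnet(50, 10, 4, seed = 6)
  mt <- node_metrics(net)
  expect_equal(nrow(mt), 50)
  expect_equal(mt$out_degree, unname(out_degree(net)[mt$node]))
  expect_true(all(is.na(mt$hierarchy[!mt$is_tf])))
  expect_true(all(!is.na(mt$hierarchy[mt$is_tf])))
  expect_error(node_metrics(net, metrics = "pagerank"),
               class = "rs_invalid_parameter")
})
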