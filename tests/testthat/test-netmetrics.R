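# Builds a small ensemble_network by hand from an edge tibble, bypassing the
# inference pipeline, so the graph-metric code can be tested on exact graphs.
graph_fixture <- function(edges_df) {
  edges <- tibble::tibble(
    otu1 = edges_df$from, otu2 = edges_df$to,
    merged_p = 0.001, q_value = 0.01, support = 4L,
    direction = edges_df$direction %||% rep("copresence", nrow(edges_df)),
    retained = TRUE)
  nodes <- sort(unique(c(edges$otu1, edges$otu2)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$otu1, to = edges$otu2,
               direction = edges$direction), directed = FALSE,
    vertices = data.frame(name = nodes))
  structure(list(edges = edges, graph = g,
                 nodes = tibble::tibble(otu_id = nodes, taxonomy = NA),
                 config = inference_config(), n_candidates = nrow(edges),
                 n_pairs = NA_real_),
            class = "ensemble_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("clusters are positive-edge components with singletons uncorrelated", {
  tri2 <- graph_fixture(data.frame(
    from = c("a", "b", "c", "x", "y", "z", "a"),
    to   = c("b", "c", "a", "y", "z", "x", "x"),
    direction = c(rep("copresence", 6), "exclusion")))
  lab <- find_clusters(tri2)
  cl <- lab$nodes$cluster
  names(cl) <- lab$nodes$otu_id
  expect_equal(length(unique(cl[c("a", "b", "c")])), 1)
  expect_equal(length(unique(cl[c("x", "y", "z")])), 1)
  # the exclusion edge a-x must not merge the two clusters
  expect_false(cl[["a"]] == cl[["x"]])
  # node with only exclusion edges is uncorrelated
  lone <- graph_fixture(data.frame(from = c("a", "b", "p"),
                                   to = c("b", "c", "q"),
                                   direction = c("copresence", "copresence",
                                                 "exclusion")))
  lc <- find_clusters(lone)$nodes
  expect_true(all(lc$cluster[lc$otu_id %in% c("p", "q")] == "uncorrelated"))
})

test_that("node metrics match closed forms on canonical graphs", {
  star <- graph_fixture(data.frame(from = rep("hub", 4),
                                   to = paste0("leaf", 1:4)))
  m <- node_metrics(star)
  hub <- m[m$otu_id == "hub", ]
  expect_equal(unname(hub$degree), 4)
  expect_equal(unname(hub$betweenness), 1)  # normalized by (n-1)(n-2)/2
  expect_equal(unname(hub$closeness), 1)
  expect_equal(unname(hub$local_clustering), 0)
  tri <- graph_fixture(data.frame(from = c("a", "b", "c"),
                                  to = c("b", "c", "a")))
  expect_equal(unname(node_metrics(tri)$local_clustering), rep(1, 3))
  ring4 <- graph_fixture(data.frame(from = c("a", "b", "c", "d"),
                                    to = c("b", "c", "d", "a")))
  expect_equal(length(unique(round(node_metrics(ring4)$betweenness, 12))), 1)
  # every betweenness in a complete graph is zero
  k5 <- t(combn(paste0("v", 1:5), 2))
  complete <- graph_fixture(data.frame(from = k5[, 1], to = k5[, 2]))
  expect_equal(unname(node_metrics(complete)$betweenness), rep(0, 5))
})

test_that("cluster statistics satisfy the density identities and match printed forms", {
  expect_equal(round(density_from_mean_degree(33, 4.12), 3), 0.129)
  expect_equal(round(density_from_mean_degree(65, 6.46), 3), 0.101)
  expect_equal(round(mean_degree_from_density(65, 0.101), 2), 6.46)
  tri2 <- graph_fixture(data.frame(
    from = c("a", "b", "c", "x", "y", "z"),
    to = c("b", "c", "a", "y", "z", "x")))
  st <- cluster_stats(tri2)
  expect_equal(nrow(st), 2)
  expect_equal(st$n_nodes, c(3, 3))
  expect_equal(st$avg_neighbors, c(2, 2))
  expect_equal(st$density, c(1, 1))
  expect_equal(st$clustering_coefficient, c(1, 1))
  expect_equal(st$centralization, c(0, 0))  # regular graph
  expect_equal(st$density, st$avg_neighbors / (st$n_nodes - 1))
  # star cluster -> centralization 1
  star <- graph_fixture(data.frame(from = rep("hub", 4),
                                   to = paste0("leaf", 1:4)))
  expect_equal(cluster_stats(star)$centralization, 1)
  # centralization undefined below 3 nodes
  pair <- graph_fixture(data.frame(from = "a", to = "b"))
  expect_true(is.na(cluster_stats(pair)$centralization))
})

test_that("cluster statistics are invariant to node relabeling", {
  set.seed(12)
  eg <- t(combn(paste0("n", 1:7), 2))
  keep <- sample(nrow(eg), 12)
  net <- graph_fixture(data.frame(from = eg[keep, 1], to = eg[keep, 2]))
  st1 <- cluster_stats(net)
  relab <- setNames(paste0("m", sample(7)), paste0("n", 1:7))
  net2 <- graph_fixture(data.frame(from = unname(relab[eg[keep, 1]]),
                                   to = unname(relab[eg[keep, 2]])))
  st2 <- cluster_stats(net2)
  cols <- c("n_nodes", "n_edges", "avg_neighbors", "clustering_coefficient",
            "centralization", "density")
  expect_equal(dplyr::arrange(st1[cols], n_nodes, n_edges, density),
               dplyr::arrange(st2[cols], n_nodes, n_edges, density))
})

test_that("hub detection requires the top fraction in all three centralities", {
  star <- graph_fixture(data.frame(from = rep("hub", 5),
                                   to = paste0("leaf", 1:5)))
  h <- detect_hubs(star, top_fraction = 0.1)
  expect_equal(h$otu_id, "hub")
  # at a coarser fraction the cutoff lands on the tied leaves, which the
  # tie rule then admits alongside the centre
  expect_true("hub" %in% detect_hubs(star, top_fraction = 0.4)$otu_id)
  # fully regular cluster: ties at the cutoff admit everyone
  tri <- graph_fixture(data.frame(from = c("a", "b", "c"),
                                  to = c("b", "c", "a")))
  expect_equal(sort(detect_hubs(tri, 0.1)$otu_id), c("a", "b", "c"))
  # planted hub in the inferred network
  fix <- planted_network()
  hubs <- detect_hubs(find_clusters(fix$net))
  expect_true("OTU_1" %in% hubs$otu_id)
})

test_that("habitat preference tags by mean relative abundance with a tie rule", {
  m <- matrix(c(10, 10, 0, 0,
                0, 0, 10, 10,
                5, 5, 5, 5), 3, 4, byrow = TRUE,
              dimnames = list(c("O1", "O2", "O3"), paste0("S", 1:4)))
  md <- tibble::tibble(sample_id = paste0("S", 1:4),
                       habitat = c("rhizosphere", "rhizosphere",
                                   "bulk", "bulk"))
  tab <- otu_table(m, metadata = md)
  hp <- suppressWarnings(habitat_preference(tab))
  expect_equal(hp$preference[hp$otu_id == "O1"], "rhizosphere")
  expect_equal(hp$preference[hp$otu_id == "O2"], "bulk")
  # exactly equal means -> none
  expect_equal(hp$preference[hp$otu_id == "O3"], "none")
  expect_error(habitat_preference(otu_table(m)), "metadata")
  # planted habitat-tagged blocks recover their tag
  fix <- planted_network()
  hp2 <- habitat_preference(fix$table, paste0("OTU_", 1:20))
  truth <- rep(c("rhizosphere", "bulk"), each = 10)
  expect_gte(mean(hp2$preference == truth), 0.95)
})
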