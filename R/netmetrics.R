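#' Label network clusters
#'
#' Clusters are the connected components of the positive (copresence) edge
#' subgraph, numbered by decreasing size (`cluster_1`, `cluster_2`, ...).
#' Nodes with no positive edge are labelled `"uncorrelated"`.
#'
#' @param net An `ensemble_network`.
#' @return The network with a `cluster` column added to `nodes` (and as a
#'   vertex attribute on the graph).
#' @export
find_clusters <- function(net) {
  stopifnot(inherits(net, "ensemble_network"))
  g <- net$graph
  pos <- igraph::subgraph_from_edges(
    g, igraph::E(g)[igraph::E(g)$direction == "copresence"],
    delete.vertices = FALSE)
  comp <- igraph::components(pos)
  sizes <- comp$csize
  lab <- rep(NA_character_, igraph::vcount(pos))
  ord <- order(sizes, decreasing = TRUE)
  rank_of <- match(seq_along(sizes), ord)
  lab <- ifelse(sizes[comp$membership] <= 1, "uncorrelated",
                paste0("cluster_", rank_of[comp$membership]))
  names(lab) <- igraph::V(pos)$name
  net$nodes$cluster <- unname(lab[net$nodes$otu_id])
  net$graph <- igraph::set_vertex_attr(g, "cluster", value =
                                         lab[igraph::V(g)$name])
  net
}

#' Per-node centrality metrics
#'
#' Degree, betweenness (normalised by `(n-1)(n-2)/2` within each connected
#' component), closeness (inverse mean within-component geodesic) and local
#' clustering coefficient (fraction of possible links among neighbours;
#' 0 for nodes with fewer than two neighbours), computed on the positive
#' subgraph components when the network has been cluster-labelled, else on
#' the full graph.
#'
#' @param net An `ensemble_network`.
#' @return A tibble: `otu_id`, `cluster` (if labelled), `degree`,
#'   `betweenness`, `closeness`, `local_clustering`.
#' @export
node_metrics <- function(net) {
  stopifnot(inherits(net, "ensemble_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0) {
    return(tibble(otu_id = character(), cluster = character(),
                  degree = numeric(), betweenness = numeric(),
                  closeness = numeric(), local_clustering = numeric()))
  }
  comp <- igraph::components(g)
  res <- lapply(seq_len(comp$no), function(ci) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vs)
    n <- igraph::vcount(sub)
    btw <- igraph::betweenness(sub, directed = FALSE, normalized = n > 2)
    clo <- if (n > 1) igraph::closeness(sub, normalized = TRUE) else
      rep(NA_real_, n)
    lc <- igraph::transitivity(sub, type = "local", isolates = "zero")
    tibble(otu_id = igraph::V(sub)$name,
           degree = igraph::degree(sub),
           betweenness = unname(btw),
           closeness = unname(clo),
           local_clustering = lc)
  })
  out <- bind_rows(res)
  if ("cluster" %in% names(net$nodes)) {
    out <- left_join(out, net$nodes[, c("otu_id", "cluster")], by = "otu_id")
    out <- out[, c("otu_id", "cluster", "degree", "betweenness", "closeness",
                   "local_clustering")]
  }
  out
}

#' Per-cluster network statistics
#'
#' For each cluster (intra-cluster edges only): node count, edge count,
#' average number of neighbours `2E/n`, mean local clustering coefficient,
#' degree centralization in the Cytoscape form
#' `(n/(n-2)) * (max_deg/(n-1) - density)` (undefined, `NA`, for n < 3),
#' and density `2E/(n(n-1))`.
#'
#' @param net A cluster-labelled `ensemble_network` (see [find_clusters()]).
#' @return A tibble with one row per cluster.
#' @export
cluster_stats <- function(net) {
  stopifnot(inherits(net, "ensemble_network"))
  if (!"cluster" %in% names(net$nodes)) net <- find_clusters(net)
  cl <- setdiff(sort(unique(net$nodes$cluster)), "uncorrelated")
  rows <- lapply(cl, function(cc) {
    ids <- net$nodes$otu_id[net$nodes$cluster == cc]
    sub <- igraph::induced_subgraph(net$graph, ids)
    n <- igraph::vcount(sub)
    e <- igraph::ecount(sub)
    dens <- if (n > 1) 2 * e / (n * (n - 1)) else NA_real_
    maxd <- max(igraph::degree(sub))
    tibble(cluster = cc, n_nodes = n, n_edges = e,
           avg_neighbors = 2 * e / n,
           clustering_coefficient =
             mean(igraph::transitivity(sub, type = "local",
                                       isolates = "zero")),
           centralization = if (n >= 3)
             (n / (n - 2)) * (maxd / (n - 1) - dens) else NA_real_,
           density = dens)
  })
  bind_rows(rows)
}

#' Consistency helpers for density and mean degree
#'
#' In any simple graph, density and mean degree are linked by
#' `density = mean_degree / (n - 1)`; these helpers convert one into the
#' other, e.g. to check published per-cluster network parameters against
#' each other.
#'
#' @param n_nodes Number of nodes.
#' @param mean_degree Average number of neighbours.
#' @param density Graph density.
#' @return A single number.
#' @export
density_from_mean_degree <- function(n_nodes, mean_degree) {
  mean_degree / (n_nodes - 1)
}

#' @rdname density_from_mean_degree
#' @export
mean_degree_from_density <- function(n_nodes, density) {
  density * (n_nodes - 1)
}

#' Detect hub nodes
#'
#' Within each cluster, hubs are the nodes ranking in the top
#' `top_fraction` by *all three* of degree, betweenness and closeness
#' (average ranks for ties; ties at the cutoff are included, so a fully
#' regular cluster returns either all or none of its nodes).
#'
#' @param net A cluster-labelled `ensemble_network`.
#' @param top_fraction Fraction of each cluster to admit per metric.
#' @return A tibble of hub nodes with their cluster and metrics.
#' @export
detect_hubs <- function(net, top_fraction = 0.10) {
  metrics <- node_metrics(if ("cluster" %in% names(net$nodes)) net
                          else find_clusters(net))
  metrics <- metrics[metrics$cluster != "uncorrelated", , drop = FALSE]
  if (nrow(metrics) == 0) return(metrics)
  top_in <- function(v, k) {
    thr <- sort(v, decreasing = TRUE)[k]
    v >= thr
  }
  out <- metrics |>
    group_by(.data$cluster) |>
    filter({
      k <- max(1L, ceiling(top_fraction * n()))
      top_in(.data$degree, k) & top_in(.data$betweenness, k) &
        top_in(.data$closeness, k)
    }) |>
    ungroup()
  out
}

#' Habitat preference of network nodes
#'
#' Tags each OTU with the habitat in which its mean relative abundance is
#' greater, together with the margin (difference of means) and a
#' Mann-Whitney p-value for the habitat contrast. An exact tie gives
#' `"none"`.
#'
#' @param x The source [otu_table()] with habitat metadata.
#' @param otus OTU ids to tag (e.g. `net$nodes$otu_id`); default all.
#' @return A tibble: `otu_id`, `preference`, one mean column per habitat,
#'   `margin`, `p_value`.
#' @export
habitat_preference <- function(x, otus = NULL) {
  stopifnot(inherits(x, "otu_table"))
  if (is.null(x$metadata) || !"habitat" %in% names(x$metadata)) {
    abort("Sample metadata with a `habitat` column is required.")
  }
  props <- to_relative(x)$proportions
  otus <- otus %||% rownames(props)
  hab <- x$metadata$habitat
  levs <- sort(unique(hab))
  rows <- lapply(otus, function(o) {
    v <- props[o, ]
    means <- vapply(levs, function(h) mean(v[hab == h]), 1)
    pref <- if (length(unique(means)) == 1) "none" else levs[which.max(means)]
    pv <- if (length(levs) == 2) {
      suppressWarnings(wilcox.test(v[hab == levs[1]], v[hab == levs[2]])$p.value)
    } else NA_real_
    res <- tibble(otu_id = o, preference = pref,
                  margin = max(means) - min(means), p_value = pv)
    for (h in levs) res[[paste0("mean_", h)]] <- means[[h]]
    res
  })
  bind_rows(rows)
}
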