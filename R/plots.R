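#' Plot an ensemble co-occurrence network
#'
#' Force-directed layout of the retained edges; nodes coloured by cluster
#' (run [find_clusters()] first for labels) and sized by degree, edges drawn
#' solid for copresence and dashed for mutual exclusion.
#'
#' @param object An `ensemble_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ensemble_network <- function(object, seed = 1, ...) {
  g <- object$graph
  if (igraph::vcount(g) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "empty network") +
             ggplot2::theme_void())
  }
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(otu_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                  degree = igraph::degree(g))
  cl <- igraph::vertex_attr(g, "cluster")
  nodes$cluster <- if (!is.null(cl)) cl else "unlabelled"
  el <- igraph::as_data_frame(g, what = "edges")
  ed <- tibble(x = nodes$x[match(el$from, nodes$otu_id)],
               y = nodes$y[match(el$from, nodes$otu_id)],
               xend = nodes$x[match(el$to, nodes$otu_id)],
               yend = nodes$y[match(el$to, nodes$otu_id)],
               direction = if (nrow(el) > 0) el$direction else character())
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$direction),
      colour = "grey60") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree,
                   colour = .data$cluster)) +
    ggplot2::scale_size_continuous(range = c(1.5, 6)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "Cluster", size = "Degree",
                  linetype = "Direction")
}

#' Plot per-sample alpha diversity
#'
#' @param div Tibble from [alpha_diversity()] (metadata columns joined).
#' @param metric Column to plot.
#' @param by Grouping column on the x axis (e.g. `"treatment"`).
#' @param facet_by Optional faceting column (e.g. `"habitat"`).
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(div, metric = "shannon", by = "treatment",
                                 facet_by = "habitat") {
  p <- ggplot2::ggplot(div, ggplot2::aes(x = .data[[by]],
                                         y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = by, y = paste0(metric,
                                     if (metric == "shannon") " (bits)" else ""))
  if (!is.null(facet_by) && facet_by %in% names(div)) {
    p <- p + ggplot2::facet_wrap(facet_by)
  }
  p
}

#' Plot gene-OTU correlation summary
#'
#' Bar chart of the number of positively and negatively correlated OTUs per
#' gene at the stored significance level.
#'
#' @param object A `gene_otu_correlations` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gene_otu_correlations <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary, c("n_positive", "n_negative"),
                              names_to = "sign", values_to = "n")
  long$sign <- ifelse(long$sign == "n_positive", "positive", "negative")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$n,
                                     fill = .data$sign)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = paste0("OTUs at q < ", object$alpha),
                  fill = "Correlation")
}
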