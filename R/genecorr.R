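#' Correlate OTU abundances with N-cycle gene abundances
#'
#' Computes the Spearman correlation between each OTU's relative abundance
#' and each gene's qPCR abundance over the matched samples (bulk soil by
#' default, where functional-gene quantification is typically performed),
#' applies Benjamini-Hochberg correction across all gene x OTU pairs (or
#' per gene with `per_gene_fdr = TRUE`), and summarises the significant
#' correlations per gene by sign. Being rank-based, the results are
#' invariant to monotone transforms of the gene values, so absolute copy
#' numbers and percent-of-16S values give identical output.
#'
#' @param x An [otu_table()].
#' @param genes Gene tibble (`sample_id` + one numeric column per gene), as
#'   from [read_gene_table()] or [generate_gene_abundances()].
#' @param habitat Habitat to restrict samples to; `NULL` for no restriction.
#' @param alpha Significance level on q-values.
#' @param per_gene_fdr Correct within each gene instead of jointly.
#' @return A `gene_otu_correlations` object: list with `pairs` (tibble:
#'   `gene`, `otu_id`, `rho`, `p_value`, `q_value`, `sign`) and `summary`
#'   (per-gene counts of positively/negatively correlated OTUs at
#'   `q < alpha`). [tidy()] returns `pairs`, [glance()] totals.
#' @export
correlate_genes <- function(x, genes, habitat = "bulk", alpha = 0.05,
                            per_gene_fdr = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  keep <- rep(TRUE, ncol(x$counts))
  if (!is.null(habitat)) {
    if (is.null(x$metadata) || !"habitat" %in% names(x$metadata)) {
      abort("Habitat restriction needs metadata with a `habitat` column.")
    }
    keep <- x$metadata$habitat == habitat
  }
  sub <- subset_samples_tab(x, keep)
  shared <- intersect(sample_ids(sub), genes$sample_id)
  if (length(shared) < 5) abort("Need at least 5 shared samples.")
  sub <- subset_samples_tab(sub, match(shared, sample_ids(sub)))
  gm <- genes[match(shared, genes$sample_id), , drop = FALSE]
  props <- to_relative(sub)$proportions
  gene_names <- setdiff(names(gm), "sample_id")
  rows <- list()
  for (g in gene_names) {
    gv <- gm[[g]]
    if (length(unique(gv)) == 1) {
      inform(paste0("correlate_genes: gene '", g, "' is constant; skipped."))
      next
    }
    gr <- rank(gv)
    for (o in rownames(props)) {
      ov <- props[o, ]
      if (length(unique(ov)) == 1) next
      rho <- suppressWarnings(cor(gr, rank(ov)))
      pv <- suppressWarnings(
        stats::cor.test(gv, ov, method = "spearman", exact = FALSE)$p.value)
      rows[[length(rows) + 1]] <- tibble(gene = g, otu_id = o, rho = rho,
                                         p_value = pv)
    }
  }
  pairs <- bind_rows(rows)
  if (nrow(pairs) == 0) abort("No testable gene-OTU pairs.")
  if (per_gene_fdr) {
    pairs <- pairs |> group_by(.data$gene) |>
      mutate(q_value = bh_fdr(.data$p_value)) |> ungroup()
  } else {
    pairs$q_value <- bh_fdr(pairs$p_value)
  }
  pairs$sign <- ifelse(pairs$rho > 0, "+", ifelse(pairs$rho < 0, "-", "0"))
  sig <- pairs[pairs$q_value < alpha, , drop = FALSE]
  summary <- pairs |> group_by(gene = .data$gene) |>
    summarise(n_positive = sum(.data$q_value < alpha & .data$rho > 0),
              n_negative = sum(.data$q_value < alpha & .data$rho < 0),
              .groups = "drop")
  structure(list(pairs = pairs, summary = summary, alpha = alpha,
                 n_samples = length(shared), habitat = habitat),
            class = "gene_otu_correlations")
}

#' @export
print.gene_otu_correlations <- function(x, ...) {
  cat("<gene_otu_correlations> ", nrow(x$pairs), " pairs over ",
      x$n_samples, " samples", sep = "")
  if (!is.null(x$habitat)) cat(" (", x$habitat, ")", sep = "")
  cat("; ", sum(x$pairs$q_value < x$alpha), " significant at q < ",
      x$alpha, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gene_otu_correlations <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.gene_otu_correlations <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs),
         n_significant = sum(x$pairs$q_value < x$alpha),
         n_positive = sum(x$summary$n_positive),
         n_negative = sum(x$summary$n_negative),
         alpha = x$alpha, n_samples = x$n_samples)
}
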