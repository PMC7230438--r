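#' Alpha-diversity metrics
#'
#' `shannon_index()` is the Shannon entropy in bits, `-sum(p * log2(p))` over
#' positive proportions; `observed_richness()` counts OTUs with at least one
#' read; `chao1_estimate()` is the classical Chao1 richness estimate
#' `S_obs + F1^2 / (2 F2)` (F1 singletons, F2 doubletons), switching to the
#' bias-corrected `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` when there are no
#' doubletons.
#'
#' @param x Numeric vector of counts (or proportions for `shannon_index`).
#' @return A single number.
#' @export
shannon_index <- function(x) {
  if (any(x < 0) || all(x == 0)) abort("Need a non-negative, non-empty column.")
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @rdname shannon_index
#' @export
observed_richness <- function(x) sum(x > 0)

#' @rdname shannon_index
#' @export
chao1_estimate <- function(x) {
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Per-sample alpha diversity table
#'
#' @param x An [otu_table()], typically rarefied to a common depth first.
#' @return A tibble with `sample_id`, `shannon` (bits), `richness` and
#'   `chao1`, joined to the sample metadata when present.
#' @export
alpha_diversity <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  res <- tibble(
    sample_id = colnames(x$counts),
    shannon = apply(x$counts, 2, shannon_index),
    richness = apply(x$counts, 2, observed_richness),
    chao1 = apply(x$counts, 2, chao1_estimate))
  if (!is.null(x$metadata)) res <- left_join(res, x$metadata, by = "sample_id")
  res
}

#' Bray-Curtis distance matrix between samples
#'
#' `BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` on relative abundances.
#'
#' @param x An [otu_table()] or `rel_abundance_table`.
#' @return A symmetric sample-by-sample distance matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(x) {
  p <- as_proportions(x)
  if (ncol(p) < 2) abort("Need at least 2 samples.")
  as.matrix(vegan::vegdist(t(p), method = "bray"))
}

perm_test_result <- function(method, statistic, p, n_perm, seed) {
  structure(list(method = method, statistic = statistic, p_value = p,
                 n_permutations = n_perm, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$method, ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4), " (", x$n_permutations,
      " permutations)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value,
         n_permutations = x$n_permutations)
}

#' @exportS3Method generics::glance
glance.perm_test <- function(x, ...) tidy(x)

check_groups <- function(labels, n) {
  labels <- as.factor(labels)
  if (length(labels) != n) abort("One label per sample is required.")
  if (nlevels(droplevels(labels)) < 2) abort("Need at least 2 groups.")
  droplevels(labels)
}

#' Permutation tests on a distance matrix
#'
#' `permanova_test()` runs the pseudo-F test of ADONIS/PERMANOVA and
#' `anosim_test()` the ANOSIM rank test, both with seeded label permutations
#' and the add-one p-value convention
#' `p = (1 + #(perm >= obs)) / (1 + n_perm)`.
#'
#' @param d Square distance matrix (e.g. from [bray_curtis_matrix()]).
#' @param labels Group label per sample (>= 2 groups).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return A `perm_test` object with `statistic` (pseudo-F or ANOSIM R),
#'   `p_value`, `n_permutations`, `seed`.
#' @export
permanova_test <- function(d, labels, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  labels <- check_groups(labels, nrow(d))
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(group = labels)
  fit <- vegan::adonis2(stats::as.dist(d) ~ group, data = df,
                        permutations = n_perm)
  perm_test_result("PERMANOVA", fit$F[1], fit$`Pr(>F)`[1], n_perm, seed)
}

#' @rdname permanova_test
#' @export
anosim_test <- function(d, labels, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  labels <- check_groups(labels, nrow(d))
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(d), labels, permutations = n_perm)
  perm_test_result("ANOSIM", fit$statistic, fit$signif, n_perm, seed)
}
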