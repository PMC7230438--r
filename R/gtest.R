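#' Benjamini-Hochberg adjusted p-values
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param n Family size; defaults to `length(p)`. Larger values treat the
#'   supplied p-values as a subset of a wider tested family (the remaining
#'   members implicitly non-significant).
#' @return Vector of q-values in the original order.
#' @export
bh_fdr <- function(p, n = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH", n = max(n, length(p)))
}

# G statistic of independence for a 2 x k table given as two count rows.
g_statistic <- function(row1, row2) {
  obs <- rbind(row1, row2)
  e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  i <- obs > 0
  2 * sum(obs[i] * log(obs[i] / e[i]))
}

williams_q <- function(obs) {
  n <- sum(obs)
  r <- nrow(obs); k <- ncol(obs)
  1 + ((n * sum(1 / rowSums(obs)) - 1) * (n * sum(1 / colSums(obs)) - 1)) /
    (6 * n * (r - 1) * (k - 1))
}

#' Per-OTU G-test of independence across treatment groups
#'
#' Replicate samples are pooled per group; each OTU is tested on the 2 x k
#' contingency table whose first row holds the OTU's pooled counts per group
#' and second row the remaining reads per group. `G = 2 sum O ln(O/E)` over
#' non-zero cells, df = k - 1, p from the chi-square upper tail, and
#' Benjamini-Hochberg q-values across OTUs.
#'
#' @param x An [otu_table()] (conventionally the rarefied table).
#' @param groups Group label per sample, or the name of a metadata column
#'   (default `"treatment"`).
#' @param alpha Significance level used in the summary ([glance()]).
#' @param williams Apply the Williams continuity correction to G.
#' @return A tibble of class `diff_abund` with columns `otu_id`, `G`, `df`,
#'   `p_value`, `q_value`; `glance()` reports the number of OTUs with
#'   `q < alpha` and their percent of total reads.
#' @export
g_test_per_otu <- function(x, groups = "treatment", alpha = 0.05,
                           williams = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  if (is.character(groups) && length(groups) == 1) {
    if (is.null(x$metadata) || !groups %in% names(x$metadata)) {
      abort(paste0("Metadata column '", groups, "' not found."))
    }
    groups <- x$metadata[[groups]]
  }
  groups <- check_groups(groups, ncol(x$counts))
  pooled <- t(rowsum(t(x$counts), group = groups))  # OTU x group
  if (any(colSums(pooled) == 0)) abort("A group has no reads.")
  k <- ncol(pooled)
  gtot <- colSums(pooled)
  g <- vapply(seq_len(nrow(pooled)), function(i) {
    row1 <- pooled[i, ]
    stat <- g_statistic(row1, gtot - row1)
    if (williams && sum(row1) > 0) {
      stat <- stat / williams_q(rbind(row1, gtot - row1))
    }
    stat
  }, 1)
  p <- pchisq(g, df = k - 1, lower.tail = FALSE)
  res <- tibble(otu_id = rownames(pooled), G = g, df = k - 1,
                p_value = p, q_value = bh_fdr(p))
  total_reads <- rowSums(pooled)
  attr(res, "alpha") <- alpha
  attr(res, "pct_reads_affected") <-
    100 * sum(total_reads[res$q_value < alpha]) / sum(total_reads)
  class(res) <- c("diff_abund", class(res))
  res
}

#' @exportS3Method generics::glance
glance.diff_abund <- function(x, ...) {
  alpha <- attr(x, "alpha")
  tibble(n_otus = nrow(x),
         n_significant = sum(x$q_value < alpha),
         pct_reads_affected = attr(x, "pct_reads_affected"),
         alpha = alpha)
}

#' @exportS3Method generics::tidy
tidy.diff_abund <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "diff_abund")
  out
}
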