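#' Pairwise association scores between OTUs
#'
#' Computes one of the four ensemble measures over all OTU pairs: Pearson or
#' Spearman correlation of across-sample relative-abundance profiles
#' (similarity orientation), Bray-Curtis dissimilarity between the two
#' profiles, or symmetrised Kullback-Leibler divergence
#' `D(p||q) + D(q||p)` between the profiles normalised to probability
#' vectors after adding `pseudocount` (dissimilarity orientation).
#'
#' Correlations are computed on relative abundances by default; the
#' compositional bias this introduces is precisely what the ReBoot
#' permutation null (see [reboot_null()]) is designed to retain under the
#' null. OTUs with a constant profile have undefined correlation: their
#' scores are `NA` and they are excluded from edge candidacy downstream.
#'
#' @param x An [otu_table()] or `rel_abundance_table`.
#' @param measure One of `"pearson"`, `"spearman"`, `"bray_curtis"`,
#'   `"kullback_leibler"`.
#' @param pseudocount Additive pseudocount for the KL measure.
#' @param on `"relative"` (default) or `"counts"` profiles for the
#'   correlation measures.
#' @return A `score_matrix`: list with `scores` (symmetric OTU x OTU
#'   matrix), `measure` and `orientation` (`"similarity"` or
#'   `"dissimilarity"`).
#' @export
pairwise_scores <- function(x, measure = c("pearson", "spearman",
                                           "bray_curtis", "kullback_leibler"),
                            pseudocount = 1e-6, on = c("relative", "counts")) {
  measure <- match.arg(measure)
  on <- match.arg(on)
  p <- if (on == "counts" && inherits(x, "otu_table")) x$counts else as_proportions(x)
  if (ncol(p) < 3) abort("Need at least 3 samples.")
  scores <- switch(measure,
    pearson = suppressWarnings(cor(t(p))),
    spearman = suppressWarnings(cor(t(p), method = "spearman")),
    bray_curtis = as.matrix(vegan::vegdist(p, method = "bray")),
    kullback_leibler = kl_matrix(p, pseudocount))
  diag(scores) <- if (measure_orientation(measure) == "similarity") 1 else 0
  structure(list(scores = scores, measure = measure,
                 orientation = measure_orientation(measure)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> ", x$measure, " (", x$orientation, "), ",
      nrow(x$scores), " OTUs\n", sep = "")
  invisible(x)
}

measure_orientation <- function(measure) {
  if (measure %in% c("pearson", "spearman")) "similarity" else "dissimilarity"
}

kl_matrix <- function(p, pseudocount) {
  q <- p + pseudocount
  q <- q / rowSums(q)
  lq <- log(q)
  m <- q %*% t(lq)
  d <- diag(m)
  out <- outer(d, d, "+") - m - t(m)
  out[out < 0] <- 0  # numerical floor; KL >= 0
  dimnames(out) <- list(rownames(p), rownames(p))
  out
}

#' Classify an edge as copresence or mutual exclusion
#'
#' For correlation measures the sign decides (positive score = copresence).
#' For dissimilarity measures the score is compared with a null center
#' (e.g. the permutation-null mean): below the center = copresence, above =
#' exclusion; a score exactly at the center is classed as exclusion (the
#' conservative tie rule, reported via [rlang::inform()]).
#'
#' @param measure Measure name as in [pairwise_scores()].
#' @param score Numeric score(s).
#' @param null_center Required for dissimilarity measures.
#' @return Character vector of `"copresence"` / `"exclusion"`.
#' @export
direction_of <- function(measure, score, null_center = NULL) {
  if (measure_orientation(measure) == "similarity") {
    return(ifelse(score > 0, "copresence", "exclusion"))
  }
  if (is.null(null_center)) abort("Dissimilarity measures need `null_center`.")
  if (any(score == null_center)) {
    inform("direction_of: score at null center classed as exclusion (tie rule).")
  }
  ifelse(score < null_center, "copresence", "exclusion")
}

#' Association score for a single OTU pair
#'
#' @inheritParams pairwise_scores
#' @param otu1,otu2 OTU ids.
#' @return A single score.
#' @export
score_pair <- function(x, otu1, otu2, measure, pseudocount = 1e-6) {
  p <- as_proportions(x)
  score_cols(matrix(p[otu1, ]), matrix(p[otu2, ]), measure, pseudocount)
}

# Vectorised per-column scorers: X, Y are samples x iterations matrices of
# paired profiles; returns one score per column. The engine behind the
# permutation and bootstrap loops.
score_cols <- function(X, Y, measure, pseudocount = 1e-6) {
  switch(measure,
    pearson = cols_pearson(X, Y),
    spearman = cols_pearson(col_ranks(X), col_ranks(Y)),
    bray_curtis = colSums(abs(X - Y)) / colSums(X + Y),
    kullback_leibler = cols_kl(X, Y, pseudocount),
    abort(paste0("Unknown measure: ", measure)))
}

cols_pearson <- function(X, Y) {
  cx <- sweep(X, 2, colMeans(X))
  cy <- sweep(Y, 2, colMeans(Y))
  den <- sqrt(colSums(cx^2) * colSums(cy^2))
  out <- colSums(cx * cy) / den
  out[den == 0] <- NA_real_
  out
}

col_ranks <- function(X) {
  matrix(apply(X, 2, rank), nrow(X), ncol(X))
}

cols_kl <- function(X, Y, pseudocount) {
  P <- X + pseudocount
  P <- sweep(P, 2, colSums(P), "/")
  Q <- Y + pseudocount
  Q <- sweep(Q, 2, colSums(Q), "/")
  colSums((P - Q) * (log(P) - log(Q)))
}
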