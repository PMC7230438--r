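#' Configuration for ensemble network inference
#'
#' Defaults mirror the standard CoNet-style protocol: initial thresholds
#' admitting the 1000 most copresence-like and 1000 most exclusion-like pairs
#' per measure, 100 ReBoot permutations and 100 bootstraps per edge and
#' measure, stability limits at the 2.5-97.5 bootstrap percentiles, Brown
#' merging of the per-measure p-values, Benjamini-Hochberg control at
#' `alpha = 0.05`, and retention of edges supported by at least three of the
#' four measures with a concordant direction.
#'
#' @param edges_top,edges_bottom Copresence-like / exclusion-like pairs to
#'   admit per measure.
#' @param n_permutations,n_bootstraps Iterations per edge and measure.
#' @param stability_percentiles Lower/upper bootstrap percentiles.
#' @param alpha FDR level on Brown-merged p-values.
#' @param min_support Minimum number of merging measures agreeing on the
#'   consensus direction (1..4).
#' @param measures Which of the four measures to use.
#' @param fdr_order `"fdr_first"` corrects merged p-values across all merged
#'   edges and then applies the support filter; `"support_first"` reverses
#'   the order.
#' @param positive_only Keep only copresence edges in the final graph.
#' @param p_method `"gaussian"` (parametric approximation to the permutation
#'   null, with a small-sample t correction) or `"empirical"` (add-one
#'   permutation p) for the similarity measures.
#' @param gaussian_dissimilarity Extend the parametric approximation to the
#'   dissimilarity measures. Off by default: the permutation null of
#'   Bray-Curtis (and, less severely, Kullback-Leibler) on spiky
#'   relative-abundance profiles is a collision-driven mixture, not
#'   approximately normal, so those measures use the add-one empirical
#'   p-value unless this flag is set.
#' @param n_calibration_pairs Random pairs per measure used to calibrate
#'   the null (see [measure_null_calibration()]); 0 disables calibration.
#' @param pseudocount Pseudocount for the Kullback-Leibler measure.
#' @param seed Integer seed driving all permutations and bootstraps.
#' @return An `inference_config` list.
#' @export
inference_config <- function(edges_top = 1000, edges_bottom = 1000,
                             n_permutations = 100, n_bootstraps = 100,
                             stability_percentiles = c(2.5, 97.5),
                             alpha = 0.05, min_support = 3,
                             measures = c("bray_curtis", "kullback_leibler",
                                          "pearson", "spearman"),
                             fdr_order = c("fdr_first", "support_first"),
                             positive_only = FALSE,
                             p_method = c("gaussian", "empirical"),
                             gaussian_dissimilarity = FALSE,
                             n_calibration_pairs = 200,
                             pseudocount = 1e-6, seed = 1) {
  if (stability_percentiles[1] >= stability_percentiles[2]) {
    abort("stability percentiles must satisfy low < high.")
  }
  if (!min_support %in% 1:4) abort("`min_support` must be in 1..4.")
  if (n_permutations < 20) warn("Fewer than 20 permutations: p-values unstable.")
  structure(list(edges_top = edges_top, edges_bottom = edges_bottom,
                 n_permutations = n_permutations, n_bootstraps = n_bootstraps,
                 stability_percentiles = stability_percentiles, alpha = alpha,
                 min_support = min_support, measures = measures,
                 fdr_order = match.arg(fdr_order),
                 positive_only = positive_only,
                 p_method = match.arg(p_method),
                 gaussian_dissimilarity = gaussian_dissimilarity,
                 n_calibration_pairs = n_calibration_pairs,
                 pseudocount = pseudocount, seed = seed),
            class = "inference_config")
}

#' Select initial edge candidates per measure
#'
#' For each score matrix, admits the `top_n` most copresence-like and
#' `bottom_n` most exclusion-like OTU pairs (for similarity measures the
#' largest/smallest scores; for dissimilarity measures the smallest/largest).
#' The threshold is the n-th order statistic and boundary ties are all
#' included (reported). The union over measures forms the candidate set.
#'
#' @param score_list Named list of `score_matrix` objects
#'   (from [pairwise_scores()]).
#' @param top_n,bottom_n Pairs per list; if together they meet or exceed the
#'   number of scorable pairs, all pairs are selected with a warning and
#'   directions fall back to [direction_of()] around the median score.
#' @return A tibble with one row per selected (pair, measure): `otu1`,
#'   `otu2`, `measure`, `score`, `direction`.
#' @export
select_initial_edges <- function(score_list, top_n = 1000, bottom_n = 1000) {
  rows <- lapply(score_list, function(sm) {
    s <- sm$scores
    ut <- which(upper.tri(s), arr.ind = TRUE)
    sc <- s[ut]
    ok <- is.finite(sc)
    ut <- ut[ok, , drop = FALSE]
    sc <- sc[ok]
    n <- length(sc)
    base <- tibble(otu1 = rownames(s)[ut[, 1]], otu2 = colnames(s)[ut[, 2]],
                   measure = sm$measure, score = sc)
    if (top_n + bottom_n >= n) {
      warn(paste0(sm$measure, ": top_n + bottom_n >= ", n,
                  " scorable pairs; selecting all."))
      ctr <- if (sm$orientation == "similarity") 0 else median(sc)
      base$direction <- direction_of(sm$measure, sc, null_center = ctr)
      return(base)
    }
    sim <- sm$orientation == "similarity"
    co_thr <- if (sim) sort(sc, decreasing = TRUE)[top_n] else sort(sc)[top_n]
    ex_thr <- if (sim) sort(sc)[bottom_n] else sort(sc, decreasing = TRUE)[bottom_n]
    co <- if (sim) sc >= co_thr else sc <= co_thr
    ex <- if (sim) sc <= ex_thr else sc >= ex_thr
    if (sum(co) > top_n || sum(ex) > bottom_n) {
      inform(paste0(sm$measure, ": boundary ties admitted ",
                    (sum(co) - top_n) + (sum(ex) - bottom_n),
                    " extra pair(s)."))
    }
    bind_rows(
      mutate(base[co, ], direction = "copresence"),
      mutate(base[ex & !co, ], direction = "exclusion"))
  })
  bind_rows(rows)
}

# Orders the two ids so the pair key is unordered.
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "||"), paste(b, a, sep = "||"))
}

#' ReBoot permutation null for one edge
#'
#' Each iteration independently permutes the two OTUs' count vectors across
#' samples. For correlation measures the permuted rows are substituted into
#' the count matrix and every sample is re-closed to relative abundances
#' before scoring, so the null distribution retains the compositional bias
#' of proportion data (the renormalisation step). For dissimilarity measures
#' the permuted relative-abundance profiles are scored directly.
#'
#' @param x An [otu_table()].
#' @param otu1,otu2 OTU ids.
#' @param measure Measure name.
#' @param n_perm Number of permutations (a warning is issued below 20).
#' @param seed Optional seed.
#' @param pseudocount Pseudocount for KL.
#' @return Numeric vector of `n_perm` null scores.
#' @export
reboot_null <- function(x, otu1, otu2, measure, n_perm = 100, seed = NULL,
                        pseudocount = 1e-6) {
  stopifnot(inherits(x, "otu_table"))
  if (n_perm < 20) warn("n_perm < 20: permutation p-values will be unstable.")
  if (!is.null(seed)) set.seed(seed)
  s <- ncol(x$counts)
  perm_i <- vapply(seq_len(n_perm), function(b) sample.int(s), integer(s))
  perm_j <- vapply(seq_len(n_perm), function(b) sample.int(s), integer(s))
  reboot_engine(x$counts, to_relative(x)$proportions, colSums(x$counts),
                match(otu1, otu_ids(x)), match(otu2, otu_ids(x)),
                measure, perm_i, perm_j, pseudocount)
}

reboot_engine <- function(counts, props, totals, i, j, measure,
                          perm_i, perm_j, pseudocount) {
  s <- nrow(perm_i)
  b <- ncol(perm_i)
  if (measure_orientation(measure) == "similarity") {
    # renormalise on the proportion scale: the rest of each sample's
    # composition is held fixed and the column re-closed around the two
    # permuted profiles, so the null keeps the pair's closure coupling
    # without inheriting library-size variation the observed (closed)
    # statistic never sees
    xi <- props[i, ]
    xj <- props[j, ]
    xp <- matrix(xi[perm_i], s, b)
    yp <- matrix(xj[perm_j], s, b)
    rest <- 1 - xi - xj
    tp <- rest + xp + yp
    tp[tp <= 0] <- .Machine$double.eps
    score_cols(xp / tp, yp / tp, measure, pseudocount)
  } else {
    xp <- matrix(props[i, ][perm_i], s, b)
    yp <- matrix(props[j, ][perm_j], s, b)
    score_cols(xp, yp, measure, pseudocount)
  }
}

#' Empirical-null calibration of a measure
#'
#' The ReBoot permutation null is conditional on the two profiles and
#' cannot see two table-wide features of proportion data: the common mode
#' of closed compositions (many small OTUs jointly anti-correlating with
#' the large ones shifts random-pair correlations slightly positive) and
#' the depth-heterogeneous counting noise (which shifts the dissimilarity
#' measures relative to their pairing null). Following the empirical-null
#' idea of large-scale inference, this function scores `n_pairs` randomly
#' drawn OTU pairs against their own ReBoot nulls and summarises the
#' ensemble: the mean and sd of the standardised scores (used to recentre
#' and rescale parametric z-values) and the sorted add-one empirical
#' p-values for both tails (used as the reference distribution for
#' empirical p-values). [build_ensemble_network()] computes one calibration
#' per measure and passes it to [calibrated_edge_pvalue()].
#'
#' @param x An [otu_table()].
#' @param measure Measure name.
#' @param n_pairs Number of random calibration pairs.
#' @param n_perm Permutations per pair.
#' @param seed Optional seed.
#' @param pseudocount Pseudocount for KL.
#' @return A `measure_null_calibration` list with `z_center`, `z_scale`,
#'   `p_low`, `p_high`, `measure`, `n_perm`.
#' @export
measure_null_calibration <- function(x, measure, n_pairs = 200, n_perm = 100,
                                     seed = NULL, pseudocount = 1e-6) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.null(seed)) set.seed(seed)
  calibration_engine(x$counts, to_relative(x)$proportions, colSums(x$counts),
                     measure, n_perm, pseudocount, n_pairs)
}

calibration_engine <- function(counts, props, totals, measure, n_perm,
                               pseudocount, n_pairs = 200) {
  s <- ncol(counts)
  n <- nrow(counts)
  zs <- rep(NA_real_, n_pairs)
  pl <- rep(NA_real_, n_pairs)
  ph <- rep(NA_real_, n_pairs)
  for (k in seq_len(n_pairs)) {
    ij <- if (n >= 2) sample.int(n, 2) else c(1, 1)
    perm_i <- vapply(seq_len(n_perm), function(b) sample.int(s), integer(s))
    perm_j <- vapply(seq_len(n_perm), function(b) sample.int(s), integer(s))
    ns <- reboot_engine(counts, props, totals, ij[1], ij[2], measure,
                        perm_i, perm_j, pseudocount)
    obs <- score_cols(matrix(props[ij[1], ]), matrix(props[ij[2], ]),
                      measure, pseudocount)
    ns <- ns[is.finite(ns)]
    if (!is.finite(obs) || length(ns) < 2) next
    if (sd(ns) > 0) zs[k] <- (obs - mean(ns)) / sd(ns)
    pl[k] <- (1 + sum(ns <= obs)) / (1 + length(ns))
    ph[k] <- (1 + sum(ns >= obs)) / (1 + length(ns))
  }
  zz <- zs[is.finite(zs)]
  # median: the pair-to-pair z offsets are right-skewed (abundant pairs carry
  # a larger compositional common mode), so a moment estimate would
  # over-correct the typical pair. The scale is left at 1: the standardised
  # scores are already t-scaled per pair, and an estimated scale would
  # multiply extreme-tail p-values by its own sampling noise.
  structure(list(measure = measure, n_perm = n_perm,
                 z_center = if (length(zz) > 10) median(zz) else 0,
                 z_scale = 1,
                 p_low = sort(pl[is.finite(pl)]),
                 p_high = sort(ph[is.finite(ph)])),
            class = "measure_null_calibration")
}

#' Calibrated one-tailed edge p-value
#'
#' Like [edge_pvalue()], but referred to a measure's empirical-null
#' calibration: in `"gaussian"` mode the standardised score is recentred
#' and rescaled by the calibration ensemble before the t tail is taken; in
#' `"empirical"` mode the add-one permutation p is ranked against the
#' calibration pairs' p-values of the same tail, giving the probability
#' that a random pair of the same table scores at least as extremely.
#'
#' @inheritParams edge_pvalue
#' @param calibration A [measure_null_calibration()] for the same measure,
#'   or `NULL` for the uncalibrated behaviour of [edge_pvalue()].
#' @return p-value in (0, 1].
#' @export
calibrated_edge_pvalue <- function(observed, null_sample, direction, measure,
                                   calibration = NULL,
                                   method = c("gaussian", "empirical")) {
  method <- match.arg(method)
  if (is.null(calibration)) {
    return(edge_pvalue(observed, null_sample, direction, measure, method))
  }
  sim <- measure_orientation(measure) == "similarity"
  upper <- (direction == "copresence") == sim
  ns <- null_sample[is.finite(null_sample)]
  mu <- mean(ns)
  sigma <- sd(ns)
  if (method == "gaussian" && is.finite(sigma) && sigma > 0) {
    z <- ((observed - mu) / sigma - calibration$z_center) /
      calibration$z_scale
    return(stats::pt(z, df = length(ns) - 1, lower.tail = !upper))
  }
  n <- length(ns)
  if (upper) {
    p_raw <- (1 + sum(ns >= observed)) / (1 + n)
    ref <- calibration$p_high
  } else {
    p_raw <- (1 + sum(ns <= observed)) / (1 + n)
    ref <- calibration$p_low
  }
  if (length(ref) == 0) return(p_raw)
  tol <- 1e-12
  less <- sum(ref < p_raw - tol)
  ties <- sum(abs(ref - p_raw) <= tol)
  (1 + less + 0.5 * ties) / (1 + length(ref))
}

#' Bootstrap score distribution for one edge
#'
#' Resamples the samples (columns) with replacement to the original size and
#' recomputes the score on the resampled relative-abundance profiles.
#' Degenerate resamples with a constant profile (undefined correlation) are
#' skipped; the number skipped is attached as attribute `n_skipped`.
#'
#' @inheritParams reboot_null
#' @param n_boot Number of bootstrap iterations (needs >= 5 samples).
#' @return Numeric vector of bootstrap scores (length <= `n_boot`).
#' @export
bootstrap_scores <- function(x, otu1, otu2, measure, n_boot = 100, seed = NULL,
                             pseudocount = 1e-6) {
  stopifnot(inherits(x, "otu_table"))
  s <- ncol(x$counts)
  if (s < 5) abort("Bootstrap needs at least 5 samples.")
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(s, s * n_boot, replace = TRUE), s, n_boot)
  props <- to_relative(x)$proportions
  out <- bootstrap_engine(props, match(otu1, otu_ids(x)),
                          match(otu2, otu_ids(x)), measure, idx, pseudocount)
  res <- out[!is.na(out)]
  attr(res, "n_skipped") <- sum(is.na(out))
  res
}

bootstrap_engine <- function(props, i, j, measure, idx, pseudocount) {
  s <- nrow(idx)
  b <- ncol(idx)
  xb <- matrix(props[i, ][idx], s, b)
  yb <- matrix(props[j, ][idx], s, b)
  score_cols(xb, yb, measure, pseudocount)
}

#' Bootstrap stability of an observed score
#'
#' An edge is stable for a measure iff its observed score lies inside the
#' closed interval between the lower and upper empirical percentiles
#' (linear interpolation) of its bootstrap distribution.
#'
#' @param observed Observed score.
#' @param bootstrap_sample Numeric vector of bootstrap scores.
#' @param percentiles Length-2 percentages, default `c(2.5, 97.5)`.
#' @return Logical.
#' @export
filter_unstable <- function(observed, bootstrap_sample,
                            percentiles = c(2.5, 97.5)) {
  if (length(bootstrap_sample) == 0) abort("Empty bootstrap sample.")
  q <- quantile(bootstrap_sample, percentiles / 100, names = FALSE, type = 7)
  observed >= q[1] && observed <= q[2]
}

#' One-tailed permutation p-value for an edge
#'
#' The tail is taken in the edge's direction: for similarity measures a
#' copresence edge is tested against high null scores and an exclusion edge
#' against low ones; for dissimilarity measures the tails swap. By default a
#' Gaussian approximation to the null is used,
#' `p = Phibar((obs - mu) / sigma)` (or the lower tail), falling back to the
#' add-one empirical p-value when the null is degenerate (`sigma = 0`) or
#' when `method = "empirical"`.
#'
#' Because the null moments are estimated from a finite permutation sample,
#' the standardised score is referred to a t distribution with
#' `length(null_sample) - 1` degrees of freedom rather than the standard
#' normal; this keeps the extrapolated tail honest when the permutation
#' count is modest.
#'
#' @param observed Observed score.
#' @param null_sample Permutation null scores.
#' @param direction `"copresence"` or `"exclusion"`.
#' @param measure Measure name (fixes the orientation).
#' @param method `"gaussian"` or `"empirical"`.
#' @return p-value in (0, 1].
#' @export
edge_pvalue <- function(observed, null_sample, direction, measure,
                        method = c("gaussian", "empirical")) {
  method <- match.arg(method)
  if (length(null_sample) == 0) abort("Empty null sample.")
  sim <- measure_orientation(measure) == "similarity"
  upper <- (direction == "copresence") == sim
  mu <- mean(null_sample)
  sigma <- sd(null_sample)
  if (method == "gaussian" && is.finite(sigma) && sigma > 0) {
    z <- (observed - mu) / sigma
    return(stats::pt(z, df = length(null_sample) - 1, lower.tail = !upper))
  }
  if ((!is.finite(sigma) || sigma == 0) && observed == mu) return(1)
  n <- length(null_sample)
  if (upper) (1 + sum(null_sample >= observed)) / (1 + n)
  else (1 + sum(null_sample <= observed)) / (1 + n)
}

#' Combine dependent p-values with Brown's method
#'
#' Brown's extension of Fisher's method: `X = -2 sum(log p)` is referred to
#' a scaled chi-square whose first two moments match the dependent sum,
#' `E = 2k`, `Var = 4k + 2 sum_{i<j} cov_ij`, with the covariance of each
#' pair of `-2 log p` terms obtained from the Kost-McDermott polynomial
#' `3.263 r + 0.710 r^2 + 0.027 r^3` in the correlation `r` of the
#' underlying statistics. With all correlations zero this reduces exactly to
#' Fisher's method; with perfectly correlated statistics and equal p-values
#' it returns that p-value.
#'
#' @param p_values Vector of k p-values in (0, 1].
#' @param correlations k x k correlation matrix of the score statistics
#'   (e.g. estimated across shared permutation iterations), a single scalar
#'   applied to every pair, or `NULL` for independence.
#' @return The merged p-value.
#' @export
brown_merge <- function(p_values, correlations = NULL) {
  k <- length(p_values)
  if (k == 0) abort("Need at least one p-value.")
  if (any(!is.finite(p_values)) || any(p_values > 1) || any(p_values < 0)) {
    abort("p-values must lie in [0, 1].")
  }
  if (any(p_values == 0)) {
    inform("brown_merge: p = 0 clamped to the machine floor.")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  if (k == 1) return(p_values)
  if (is.null(correlations)) correlations <- diag(k)
  if (length(correlations) == 1) {
    correlations <- matrix(correlations, k, k) + diag(k) * (1 - correlations)
  }
  r <- pmin(pmax(correlations, -1), 1)
  x <- -2 * sum(log(p_values))
  e <- 2 * k
  covs <- 3.263 * r + 0.710 * r^2 + 0.027 * r^3
  v <- 4 * k + 2 * sum(covs[upper.tri(covs)])
  if (v <= 0) v <- 4 * k
  cc <- v / (2 * e)
  f <- 2 * e^2 / v
  pchisq(x / cc, df = f, lower.tail = FALSE)
}

#' Infer the ensemble co-occurrence network
#'
#' Runs the full edge-significance pipeline on an OTU table (normally
#' filtered with the `"network"` preset of [filter_min_total()] first):
#' pairwise scores for the configured measures; initial top/bottom edge
#' selection per measure; per edge and measure, a ReBoot permutation null
#' (shared permutations across measures) giving a one-tailed p-value, and a
#' bootstrap distribution giving a stability flag; unstable measures are
#' dropped; the surviving measures' p-values are merged with Brown's method
#' using their correlation across the shared permutation iterations;
#' Benjamini-Hochberg correction over merged p-values; and retention of
#' edges with `q < alpha` and at least `min_support` merging measures
#' agreeing on the consensus direction.
#'
#' @param x An [otu_table()].
#' @param config An [inference_config()].
#' @return An `ensemble_network`: list with `edges` (tibble over all
#'   candidate pairs, per-measure scores/p-values/stability, `merged_p`,
#'   `q_value`, `support`, `direction`, `retained`), `graph` (igraph of
#'   retained edges), `nodes`, `config`. [tidy()] returns the edge table,
#'   [glance()] a one-row summary.
#' @export
build_ensemble_network <- function(x, config = inference_config()) {
  stopifnot(inherits(x, "otu_table"), inherits(config, "inference_config"))
  counts <- x$counts
  s <- ncol(counts)
  props <- to_relative(x)$proportions
  totals <- colSums(counts)
  score_list <- lapply(config$measures, function(m)
    pairwise_scores(x, m, pseudocount = config$pseudocount))
  names(score_list) <- config$measures
  sel <- select_initial_edges(score_list, config$edges_top, config$edges_bottom)
  if (nrow(sel) == 0) {
    warn("Empty candidate set; returning an empty network.")
    return(empty_network(x, config))
  }
  sel$key <- pair_key(sel$otu1, sel$otu2)
  keys <- sort(unique(sel$key))
  set.seed(config$seed)
  calibrations <- NULL
  if ((config$n_calibration_pairs %||% 0) > 0) {
    calibrations <- lapply(config$measures, function(m)
      calibration_engine(counts, props, totals, m, config$n_permutations,
                         config$pseudocount, config$n_calibration_pairs))
    names(calibrations) <- config$measures
  }
  edges <- infer_edges(keys, sel, counts, props, totals, config,
                       calibrations)
  n_pairs <- choose(nrow(counts), 2)
  edges <- apply_edge_filters(edges, config, n_pairs)
  build_network_object(x, edges, config, n_pairs)
}

calibrate_null_center_engine <- function(counts, props, totals, measure,
                                         n_perm, pseudocount, n_pairs = 40) {
  s <- ncol(counts)
  n <- nrow(counts)
  if (n < 2) return(0)
  offs <- vapply(seq_len(n_pairs), function(k) {
    ij <- sample.int(n, 2)
    perm_i <- vapply(seq_len(n_perm), function(b) sample.int(s), integer(s))
    perm_j <- vapply(seq_len(n_perm), function(b) sample.int(s), integer(s))
    ns <- reboot_engine(counts, props, totals, ij[1], ij[2], measure,
                        perm_i, perm_j, pseudocount)
    obs <- score_cols(matrix(props[ij[1], ]), matrix(props[ij[2], ]),
                      measure, pseudocount)
    ns <- ns[is.finite(ns)]
    if (!is.finite(obs) || length(ns) < 2 || sd(ns) == 0) return(NA_real_)
    (obs - mean(ns)) / sd(ns)
  }, 1)
  med <- median(offs[is.finite(offs)])
  if (is.finite(med)) med else 0
}

# Per-edge permutation/bootstrap computation. Kept separate from the driver
# for clarity; consumes the RNG stream sequentially over sorted pair keys.
infer_edges <- function(keys, sel, counts, props, totals, config,
                        calibrations = NULL) {
  s <- ncol(counts)
  n_perm <- config$n_permutations
  n_boot <- config$n_bootstraps
  measures <- config$measures
  out <- vector("list", length(keys))
  for (ei in seq_along(keys)) {
    rows <- sel[sel$key == keys[ei], ]
    o1 <- rows$otu1[1]
    o2 <- rows$otu2[1]
    i <- match(o1, rownames(counts))
    j <- match(o2, rownames(counts))
    perm_i <- vapply(seq_len(n_perm), function(b) sample.int(s), integer(s))
    perm_j <- vapply(seq_len(n_perm), function(b) sample.int(s), integer(s))
    boot_idx <- matrix(sample.int(s, s * n_boot, replace = TRUE), s, n_boot)
    nulls <- matrix(NA_real_, n_perm, length(measures),
                    dimnames = list(NULL, measures))
    rec <- list(otu1 = o1, otu2 = o2)
    for (m in measures) {
      mrow <- rows[rows$measure == m, ]
      selected <- nrow(mrow) == 1
      rec[[paste0("score_", m)]] <- if (selected) mrow$score else NA_real_
      rec[[paste0("dir_", m)]] <- if (selected) mrow$direction else NA_character_
      p_m <- NA_real_
      stable_m <- NA
      if (selected) {
        nulls[, m] <- reboot_engine(counts, props, totals, i, j, m,
                                    perm_i, perm_j, config$pseudocount)
        ns <- nulls[, m][is.finite(nulls[, m])]
        if (length(ns) >= 2) {
          meth <- config$p_method
          if (meth == "gaussian" &&
              measure_orientation(m) == "dissimilarity" &&
              !isTRUE(config$gaussian_dissimilarity)) {
            meth <- "empirical"
          }
          cal_m <- if (is.null(calibrations)) NULL else calibrations[[m]]
          p_m <- calibrated_edge_pvalue(mrow$score, ns, mrow$direction, m,
                                        calibration = cal_m,
                                        method = meth)
        }
        bs <- bootstrap_engine(props, i, j, m, boot_idx, config$pseudocount)
        bs <- bs[is.finite(bs)]
        if (length(bs) > 0) {
          stable_m <- filter_unstable(mrow$score, bs,
                                      config$stability_percentiles)
        } else stable_m <- FALSE
      }
      rec[[paste0("p_", m)]] <- p_m
      rec[[paste0("stable_", m)]] <- stable_m
    }
    merging <- vapply(measures, function(m)
      isTRUE(rec[[paste0("stable_", m)]]) &&
        is.finite(rec[[paste0("p_", m)]]), TRUE)
    rec$n_merging <- sum(merging)
    if (any(merging)) {
      mm <- measures[merging]
      dirs <- vapply(mm, function(m) rec[[paste0("dir_", m)]], "")
      ps <- vapply(mm, function(m) rec[[paste0("p_", m)]], 1)
      tab <- table(dirs)
      consensus <- names(tab)[tab == max(tab)]
      if (length(consensus) > 1) consensus <- dirs[which.min(ps)]
      rec$direction <- consensus
      rec$support <- sum(dirs == consensus)
      # orient each measure's null scores towards its rejection tail, so the
      # estimated dependence matches the dependence of the one-tailed
      # p-values (e.g. high Pearson and low KL are the same evidence)
      signs <- vapply(mm, function(m) {
        upper <- (rec[[paste0("dir_", m)]] == "copresence") ==
          (measure_orientation(m) == "similarity")
        if (upper) 1 else -1
      }, 1)
      corr <- if (length(mm) > 1) {
        oriented <- sweep(nulls[, mm, drop = FALSE], 2, signs, "*")
        suppressWarnings(cor(oriented, use = "pairwise.complete.obs"))
      } else NULL
      if (!is.null(corr)) {
        corr[!is.finite(corr)] <- 0
        # estimated dependence is clamped away from +-1 for stability
        corr <- pmin(pmax(corr, -0.99), 0.99)
      }
      rec$merged_p <- brown_merge(ps, corr)
    } else {
      rec$direction <- NA_character_
      rec$support <- 0L
      rec$merged_p <- NA_real_
    }
    out[[ei]] <- rec
  }
  dplyr::bind_rows(lapply(out, tibble::as_tibble_row))
}

# BH + support filtering under the configured order. The FDR family is the
# full set of scorable OTU pairs (`n_pairs`), not just the screened
# candidates: the initial top/bottom selection examines every pair, so
# correcting only over the survivors would re-discover the selection's own
# order statistics under the null.
apply_edge_filters <- function(edges, config, n_pairs) {
  edges$q_value <- NA_real_
  merged <- is.finite(edges$merged_p)
  if (config$fdr_order == "fdr_first") {
    edges$q_value[merged] <- bh_fdr(edges$merged_p[merged], n = n_pairs)
    keep <- merged & edges$q_value < config$alpha &
      edges$support >= config$min_support
  } else {
    fam <- merged & edges$support >= config$min_support
    edges$q_value[fam] <- bh_fdr(edges$merged_p[fam], n = n_pairs)
    keep <- fam & !is.na(edges$q_value) & edges$q_value < config$alpha
  }
  if (config$positive_only) keep <- keep & edges$direction %in% "copresence"
  edges$retained <- keep
  edges
}

build_network_object <- function(x, edges, config, n_pairs = NA_real_) {
  kept <- edges[edges$retained, , drop = FALSE]
  node_ids <- sort(unique(c(kept$otu1, kept$otu2)))
  nodes <- tibble(otu_id = node_ids,
                  taxonomy = if (!is.null(x$taxonomy)) {
                    unname(x$taxonomy[node_ids])
                  } else NA_character_)
  g <- igraph::graph_from_data_frame(
    d = if (nrow(kept) > 0) {
      data.frame(from = kept$otu1, to = kept$otu2,
                 direction = kept$direction, merged_p = kept$merged_p,
                 q_value = kept$q_value, support = kept$support)
    } else data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = if (nrow(nodes) > 0) as.data.frame(nodes) else NULL)
  structure(list(edges = edges, graph = g, nodes = nodes, config = config,
                 n_candidates = nrow(edges), n_pairs = n_pairs),
            class = "ensemble_network")
}

empty_network <- function(x, config) {
  edges <- tibble(otu1 = character(), otu2 = character(),
                  merged_p = numeric(), q_value = numeric(),
                  support = integer(), direction = character(),
                  retained = logical())
  build_network_object(x, edges, config)
}

#' Re-apply retention filters to an inferred network
#'
#' Recomputes the q-values and the retained edge set from the stored
#' per-edge results without redoing permutations, e.g. to tighten `alpha`,
#' raise `min_support`, or restrict to positive (copresence) edges.
#'
#' @param net An `ensemble_network`.
#' @param alpha,min_support,positive_only,fdr_order Overrides; `NULL` keeps
#'   the stored configuration.
#' @param x Optional source [otu_table()] to refresh node taxonomy from.
#' @return A new `ensemble_network`.
#' @export
refilter_network <- function(net, alpha = NULL, min_support = NULL,
                             positive_only = NULL, fdr_order = NULL,
                             x = NULL) {
  cfg <- net$config
  cfg$alpha <- alpha %||% cfg$alpha
  cfg$min_support <- min_support %||% cfg$min_support
  cfg$positive_only <- positive_only %||% cfg$positive_only
  cfg$fdr_order <- fdr_order %||% cfg$fdr_order
  edges <- apply_edge_filters(net$edges, cfg, net$n_pairs)
  src <- x %||% structure(list(taxonomy = setNames(net$nodes$taxonomy,
                                                   net$nodes$otu_id)),
                          class = "otu_table")
  build_network_object(src, edges, cfg, net$n_pairs)
}

#' @export
print.ensemble_network <- function(x, ...) {
  cat("<ensemble_network> ", sum(x$edges$retained), " retained edges / ",
      x$n_candidates, " candidates; ", nrow(x$nodes), " nodes\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ensemble_network <- function(x, ...) as_tibble(x$edges)

#' @exportS3Method generics::glance
glance.ensemble_network <- function(x, ...) {
  kept <- x$edges[x$edges$retained, , drop = FALSE]
  tibble(n_candidates = x$n_candidates,
         n_retained = nrow(kept),
         n_copresence = sum(kept$direction %in% "copresence"),
         n_exclusion = sum(kept$direction %in% "exclusion"),
         n_nodes = nrow(x$nodes),
         alpha = x$config$alpha,
         min_support = x$config$min_support)
}

#' Write network edge list / GraphML
#'
#' @param net An `ensemble_network` (optionally cluster-labelled).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  kept <- net$edges[net$edges$retained, , drop = FALSE]
  utils::write.table(kept, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
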