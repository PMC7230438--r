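test_that("initial edge selection takes order statistics with boundary ties", {
  s <- matrix(0, 5, 5, dimnames = list(paste0("O", 1:5), paste0("O", 1:5)))
  vals <- c(0.9, 0.8, 0.7, 0.7, 0.2, -0.1, -0.6, -0.6, -0.6, -0.9)
  s[upper.tri(s)] <- vals
  s <- s + t(s); diag(s) <- 1
  sm <- structure(list(scores = s, measure = "pearson",
                       orientation = "similarity"), class = "score_matrix")
  sel <- suppressMessages(select_initial_edges(list(pearson = sm),
                                               top_n = 3, bottom_n = 3))
  co <- sel[sel$direction == "copresence", ]
  ex <- sel[sel$direction == "exclusion", ]
  expect_equal(sort(co$score, decreasing = TRUE), c(0.9, 0.8, 0.7, 0.7))
  expect_equal(sort(ex$score), c(-0.9, -0.6, -0.6, -0.6))
  # requesting more than available selects all with a warning
  expect_warning(all_sel <- select_initial_edges(list(pearson = sm),
                                                 top_n = 6, bottom_n = 6),
                 "selecting all")
  expect_equal(nrow(all_sel), 10)
})

test_that("planted block pairs dominate the Spearman top set", {
  cfg <- synth_config(n_otus = 60, seed = 21, noise_sd = 0.7, blocks = list(
    list(habitat = "rhizosphere", members = 1:10, rho = 0.9)))
  tab <- suppressMessages(filter_min_total(generate_otu_table(cfg)$table,
                                           preset = "network"))
  sm <- pairwise_scores(tab, "spearman")
  sel <- suppressMessages(select_initial_edges(list(spearman = sm),
                                               top_n = 90, bottom_n = 1))
  co <- sel[sel$direction == "copresence", ]
  within <- block_of(co$otu1) == "A" & block_of(co$otu2) == "A"
  expect_gte(sum(within) / 45, 0.9)
})

test_that("ReBoot null has the requested size and neutralises a joint-dominance artifact", {
  tab <- generate_otu_table(synth_config(n_otus = 30, seed = 2))$table
  ns <- reboot_null(tab, "OTU_1", "OTU_2", "pearson", n_perm = 60, seed = 1)
  expect_length(ns, 60)
  expect_warning(reboot_null(tab, "OTU_1", "OTU_2", "pearson", n_perm = 10,
                             seed = 1), "unstable")
  # two OTUs dominating the composition: closure makes their proportions
  # strongly anti-correlated although their latent abundances are independent
  set.seed(40)
  hits <- 0
  naive_sig <- 0
  for (r in 1:10) {
    base <- c(3, 3, rep(0, 18))  # two dominant, independent OTUs
    loglam <- matrix(base, 20, 32) + matrix(rnorm(20 * 32, 0, 0.9), 20, 32)
    counts <- apply(exp(loglam), 2, function(w) rmultinom(1, 10000, w / sum(w)))
    dimnames(counts) <- list(paste0("OTU_", 1:20), paste0("S", 1:32))
    dom <- otu_table(counts)
    pr <- to_relative(dom)$proportions
    naive_p <- cor.test(pr["OTU_1", ], pr["OTU_2", ])$p.value
    ns <- reboot_null(dom, "OTU_1", "OTU_2", "pearson", n_perm = 100)
    rb_p <- edge_pvalue(cor(pr["OTU_1", ], pr["OTU_2", ]), ns,
                        "exclusion", "pearson")
    if (naive_p < 0.05) naive_sig <- naive_sig + 1
    if (naive_p < 0.05 && rb_p > 0.05) hits <- hits + 1
  }
  expect_gte(naive_sig, 8)           # the artifact is real for a naive test
  expect_gte(hits / max(naive_sig, 1), 0.8)
})

test_that("bootstrap resamples preserve size and track strong correlations", {
  cfg <- synth_config(n_otus = 40, seed = 5, noise_sd = 0.7, blocks = list(
    list(habitat = "rhizosphere", members = 1:5, rho = 0.9)))
  tab <- generate_otu_table(cfg)$table
  bs <- bootstrap_scores(tab, "OTU_1", "OTU_2", "pearson", n_boot = 200,
                         seed = 3)
  expect_lte(length(bs), 200)
  obs <- score_pair(tab, "OTU_1", "OTU_2", "pearson")
  expect_lt(abs(mean(bs) - obs), 2 * sd(bs))
  # constant table -> all bootstrap BC scores identical
  cm <- matrix(rep(c(4, 6), 8), 2, 8,
               dimnames = list(c("O1", "O2"), paste0("S", 1:8)))
  cbs <- bootstrap_scores(otu_table(cm), "O1", "O2", "bray_curtis",
                          n_boot = 50, seed = 1)
  expect_equal(length(unique(round(cbs, 12))), 1)
})

test_that("stability uses a closed percentile interval", {
  boot <- 1:100
  expect_true(filter_unstable(median(boot), boot))
  expect_false(filter_unstable(1000, boot))
  q <- quantile(boot, 0.025, names = FALSE)
  expect_true(filter_unstable(q, boot))  # exactly at P2.5 -> stable
  expect_error(filter_unstable(1, numeric(0)), "Empty")
})

test_that("edge p-values follow the t tail and the empirical convention", {
  ns <- rnorm(100)
  mu <- mean(ns); s <- sd(ns)
  expect_equal(edge_pvalue(mu, ns, "copresence", "pearson"), 0.5)
  expect_equal(edge_pvalue(mu + 1.96 * s, ns, "copresence", "pearson"),
               pt(1.96, 99, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(abs(edge_pvalue(mu + 1.96 * s, ns, "copresence", "pearson") -
                   0.025), 0.005)
  # empirical add-one
  nv <- c(1, 2, 3, 4, 5)
  expect_equal(edge_pvalue(4.5, nv, "copresence", "pearson",
                           method = "empirical"), (1 + 1) / 6)
  # degenerate null at the observed value
  expect_equal(edge_pvalue(2, rep(2, 50), "copresence", "pearson"), 1)
})

test_that("Brown's method reduces to Fisher at independence and to the single p at rho 1", {
  set.seed(6)
  for (i in 1:200) {
    p <- runif(4, 1e-6, 1)
    fisher <- pchisq(-2 * sum(log(p)), df = 8, lower.tail = FALSE)
    expect_equal(brown_merge(p, 0), fisher, tolerance = 1e-9)
  }
  expect_equal(brown_merge(rep(0.05, 4), 0), 0.0023222, tolerance = 1e-4)
  for (p in c(0.9, 0.2, 0.01, 1e-4)) {
    expect_equal(brown_merge(rep(p, 4), 1), p, tolerance = 1e-9)
  }
  expect_equal(brown_merge(rep(1, 4), 0.3), 1)
  expect_equal(brown_merge(0.123), 0.123)
  expect_message(z <- brown_merge(c(0, 0.5), 0), "clamped")
  expect_gt(z, 0)
})

test_that("the ensemble recovers planted blocks and stays quiet on null tables", {
  fix <- planted_network()
  kept <- tidy(fix$net)[tidy(fix$net)$retained, ]
  b1 <- block_of(kept$otu1)
  b2 <- block_of(kept$otu2)
  within <- (b1 == b2) & b1 %in% c("A", "B")
  expect_gte(sum(within) / 90, 0.7)                  # recall
  expect_gte(mean(within), 0.9)                      # precision
  expect_equal(sum(b1 != b2 & b1 != "-" & b2 != "-"), 0)  # no A-B edges
  # support is never above the measure count; min_support = 5 empties it
  expect_true(all(kept$support <= 4))
  # null tables: no retained edges across seeds
  nulls <- vapply(1:3, function(s) sum(null_network(s)$edges$retained), 1)
  expect_equal(unname(nulls), c(0, 0, 0))
})

test_that("inference is seed-deterministic and filters are monotone", {
  cfg <- synth_config(n_otus = 40, seed = 33, noise_sd = 0.7, blocks = list(
    list(habitat = "bulk", members = 1:8, rho = 0.9)))
  tab <- suppressMessages(filter_min_total(generate_otu_table(cfg)$table,
                                           preset = "network"))
  icfg <- inference_config(edges_top = 30, edges_bottom = 30,
                           n_permutations = 40, n_bootstraps = 40,
                           n_calibration_pairs = 50, seed = 9)
  n1 <- suppressMessages(suppressWarnings(build_ensemble_network(tab, icfg)))
  n2 <- suppressMessages(suppressWarnings(build_ensemble_network(tab, icfg)))
  expect_equal(tidy(n1), tidy(n2))
  kept <- tidy(n1)$retained
  stricter <- refilter_network(n1, alpha = 0.01)
  expect_true(all(tidy(stricter)$retained <= kept))
  higher <- refilter_network(n1, min_support = 4)
  expect_true(all(tidy(higher)$retained <= kept))
  pos <- refilter_network(n1, positive_only = TRUE)
  expect_true(all(tidy(pos)$retained <= kept))
  # min_support = 5 cannot be satisfied by four measures
  expect_error(inference_config(min_support = 5), "1..4")
})

test_that("network export formats round-trip the retained edges", {
  fix <- planted_network()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(fix$net, f1)
  el <- utils::read.delim(f1)
  expect_equal(nrow(el), sum(tidy(fix$net)$retained))
  f2 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(fix$net, f2)
  g <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::ecount(g), igraph::ecount(fix$net$graph))
})
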