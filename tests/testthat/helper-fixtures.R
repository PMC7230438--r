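# Shared fixtures. Everything is generated in code; the expensive planted
# network build is memoised so several test files can reuse it.

tiny_table <- function() {
  m <- matrix(c(5, 0, 2,
                7, 3, 1,
                0, 1, 4), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("OTU_", 1:3), paste0("S", 1:3)))
  otu_table(m,
            taxonomy = c("Bacteria;Acidobacteria;Subgroup6",
                         "Bacteria;Proteobacteria;Gamma",
                         "Bacteria;Nitrospirae;Nitrospira"),
            metadata = tibble::tibble(sample_id = paste0("S", 1:3),
                                      habitat = c("rhizosphere", "bulk", "bulk"),
                                      treatment = c("0", "N", "M"),
                                      block = c("B1", "B1", "B2")))
}

# adjusted Rand index between two label vectors (closed form from the
# pair-counting contingency table) -- oracle helper, independent of any
# clustering code under test
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

block_of <- function(ids) {
  ifelse(ids %in% paste0("OTU_", 1:10), "A",
         ifelse(ids %in% paste0("OTU_", 11:20), "B", "-"))
}

planted_config <- function(seed = 7) {
  synth_config(
    n_otus = 100, seed = seed, noise_sd = 0.7,
    blocks = list(
      list(habitat = "rhizosphere", members = 1:10, rho = 0.85, hub = "OTU_1"),
      list(habitat = "bulk", members = 11:20, rho = 0.85)))
}

.fixture_cache <- new.env(parent = emptyenv())

planted_network <- function() {
  if (is.null(.fixture_cache$planted)) {
    tab <- suppressMessages(
      filter_min_total(generate_otu_table(planted_config())$table,
                       preset = "network"))
    cfg <- inference_config(edges_top = 100, edges_bottom = 100,
                            n_permutations = 200, n_bootstraps = 100,
                            n_calibration_pairs = 400, seed = 11,
                            positive_only = TRUE)
    net <- suppressMessages(suppressWarnings(build_ensemble_network(tab, cfg)))
    .fixture_cache$planted <- list(table = tab, net = net)
  }
  .fixture_cache$planted
}

null_network <- function(seed, edges = 50, n_perm = 50) {
  cfg <- synth_config(n_otus = 100, seed = seed)
  tab <- suppressMessages(
    filter_min_total(generate_otu_table(cfg)$table, preset = "network"))
  icfg <- inference_config(edges_top = edges, edges_bottom = edges,
                           n_permutations = n_perm, n_bootstraps = n_perm,
                           seed = seed + 1000)
  suppressMessages(suppressWarnings(build_ensemble_network(tab, icfg)))
}
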