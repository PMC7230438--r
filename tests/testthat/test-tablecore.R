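test_that("classic TSV and BIOM round-trips preserve counts, ids and taxonomy", {
  tab <- tiny_table()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, tsv, "classic_tsv")
  back <- read_otu_table(tsv, "classic_tsv")
  expect_identical(back$counts, tab$counts)
  expect_identical(unname(back$taxonomy), unname(tab$taxonomy))

  skip_if_not_installed("biomformat")
  bj <- withr::local_tempfile(fileext = ".biom")
  write_otu_table(tab, bj, "biom_json")
  back2 <- read_otu_table(bj, "biom_json")
  expect_equal(back2$counts[rownames(tab$counts), colnames(tab$counts)],
               tab$counts)
  expect_match(back2$taxonomy[["OTU_3"]], "Nitrospira")
})

test_that("malformed rows and invalid counts are rejected with the line named", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tS1\tS2\ttaxonomy",
               "OTU_1\t3\t4\tBacteria",
               "OTU_2\t9\tBacteria"), f)
  expect_error(read_otu_table(f, "classic_tsv"), "line 3")
  writeLines(c("#OTU ID\tS1", "OTU_1\t-3"), f)
  expect_error(read_otu_table(f, "classic_tsv"), "Negative")
  writeLines(c("#OTU ID\tS1", "OTU_1\t2", "OTU_1\t5"), f)
  expect_error(read_otu_table(f, "classic_tsv"), "Duplicate")
})

test_that("mapping file round-trips and attaches to the table", {
  tab <- tiny_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mapping_file(tab$metadata, f)
  md <- read_mapping_file(f)
  expect_equal(md$sample_id, tab$metadata$sample_id)
  expect_equal(md$habitat, tab$metadata$habitat)
  expect_error(otu_table(tab$counts, metadata = md[1:2, ]), "missing")
})

test_that("contaminant and singleton removal follows the keyword and count rules", {
  m <- matrix(c(10, 10,  # kept
                1, 0,    # singleton -> dropped
                2, 0,    # total 2 -> kept
                5, 5,    # chloroplast -> dropped
                4, 4,    # mitochondria -> dropped
                3, 3),   # unassigned -> dropped
              ncol = 2, byrow = TRUE,
              dimnames = list(paste0("O", 1:6), c("S1", "S2")))
  tab <- otu_table(m, taxonomy = c(
    "Bacteria;Acidobacteria", "Bacteria;Planctomycetes", "Bacteria;Chloroflexi",
    "Bacteria;Cyanobacteria;Chloroplast;x", "Eukaryota;Mitochondria",
    "Unassigned;"))
  out <- suppressMessages(remove_contaminants_and_singletons(tab))
  expect_setequal(otu_ids(out), c("O1", "O3"))
  # no matches -> unchanged
  clean <- otu_table(m[c(1, 3), ], taxonomy = c("Bacteria;A", "Bacteria;B"))
  expect_identical(suppressMessages(
    remove_contaminants_and_singletons(clean))$counts, clean$counts)
})

test_that("read-count presets honour the more-than-10 and 1000-read boundaries", {
  m <- matrix(c(10, 11, 999, 1000), ncol = 1,
              dimnames = list(paste0("O", 1:4), "S1"))
  tab <- otu_table(m)
  expect_identical(otu_ids(suppressMessages(
    filter_min_total(tab, preset = "more_than_10"))), c("O2", "O3", "O4"))
  expect_identical(otu_ids(suppressMessages(
    filter_min_total(tab, preset = "network"))), "O4")
  expect_identical(filter_min_total(tab, min_reads = 0)$counts, tab$counts)
})

test_that("filters are idempotent", {
  tab <- generate_otu_table(synth_config(n_otus = 80, seed = 3))$table
  f1 <- suppressMessages(filter_min_total(tab, preset = "more_than_10"))
  expect_identical(suppressMessages(
    filter_min_total(f1, preset = "more_than_10"))$counts, f1$counts)
  r1 <- suppressMessages(filter_min_relative(tab, 0.001))
  expect_identical(suppressMessages(filter_min_relative(r1, 0.001))$counts,
                   r1$counts)
  c1 <- suppressMessages(remove_contaminants_and_singletons(tab))
  expect_identical(suppressMessages(
    remove_contaminants_and_singletons(c1))$counts, c1$counts)
})

test_that("rarefaction subsamples to exact depth, drops shallow samples, and is seeded", {
  tab <- generate_otu_table(
    synth_config(n_otus = 60, seed = 5, depth_range = c(4500, 9000)))$table
  rar <- rarefy_table(tab, 4310, seed = 1)
  expect_true(all(colSums(rar$counts) == 4310))
  expect_true(all(rar$counts <= tab$counts[, colnames(rar$counts)]))
  # shallow sample dropped and reported
  small <- tab
  small$counts[, 1] <- round(small$counts[, 1] * 0.4)
  expect_message(out <- rarefy_table(otu_table(small$counts,
                                               metadata = tab$metadata),
                                     4310, seed = 1), "dropped 1 sample")
  expect_false(colnames(tab$counts)[1] %in% sample_ids(out))
  # determinism
  expect_identical(rarefy_table(tab, 4310, seed = 1)$counts, rar$counts)
  expect_false(identical(rarefy_table(tab, 4310, seed = 2)$counts, rar$counts))
})

test_that("rarefaction is unbiased for composition", {
  m <- matrix(c(5000, 3000, 1500, 400, 100), ncol = 1,
              dimnames = list(paste0("O", 1:5), "S1"))
  tab <- otu_table(m)
  src <- m[, 1] / sum(m)
  set.seed(42)
  reps <- replicate(200, rarefy_table(tab, 1000)$counts[, 1] / 1000)
  se <- sqrt(src * (1 - src) / 1000) / sqrt(200)
  expect_true(all(abs(rowMeans(reps) - src) < 3 * se + 1e-12))
})

test_that("relative abundances close to one and rank aggregation conserves reads", {
  tab <- tiny_table()
  rel <- to_relative(tab)
  expect_equal(colSums(rel$proportions), c(S1 = 1, S2 = 1, S3 = 1))
  single <- otu_table(matrix(c(4, 9), 1, 2,
                             dimnames = list("O1", c("S1", "S2"))))
  expect_true(all(to_relative(single)$proportions == 1))
  zero <- otu_table(matrix(c(0, 3), 1, 2, dimnames = list("O1", c("S1", "S2"))))
  expect_error(to_relative(zero), "All-zero")

  agg <- aggregate_by_rank(tab, 2)
  expect_equal(colSums(agg$counts), colSums(tab$counts))
  twophy <- otu_table(tab$counts,
                      taxonomy = c("Bacteria;Acidobacteria;a",
                                   "Bacteria;Acidobacteria;b",
                                   "Bacteria"))
  agg2 <- aggregate_by_rank(twophy, 2)
  expect_setequal(otu_ids(agg2), c("Acidobacteria", "unclassified at rank 2"))
  expect_equal(unname(agg2$counts["Acidobacteria", ]),
               unname(colSums(tab$counts[1:2, ])))
})

test_that("relative-abundance threshold is strict and uses the pre-filter grand total", {
  m <- matrix(c(75, 99925, 25, 0), ncol = 1,
              dimnames = list(paste0("O", 1:4), "S1"))
  tab <- otu_table(m)  # grand total 100025; O1 at 74.98 ppm < 0.075%
  keep <- suppressMessages(filter_min_relative(tab, 0.00075))
  expect_identical(otu_ids(keep), "O2")
  # exactly at the threshold -> excluded (strict >)
  m2 <- matrix(c(75, 99925), ncol = 1, dimnames = list(c("A", "B"), "S1"))
  expect_identical(otu_ids(suppressMessages(
    filter_min_relative(otu_table(m2), 75 / 100000))), "B")
  # threshold 0 drops only all-zero OTUs
  expect_setequal(otu_ids(suppressMessages(filter_min_relative(tab, 0))),
                  c("O1", "O2", "O3"))
})
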