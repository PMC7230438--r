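#' Remove contaminant and singleton OTUs
#'
#' Drops OTUs whose taxonomy string contains any of the contaminant keywords
#' (case-insensitive substring match; defaults cover plastidic, mitochondrial
#' and unidentified reads) and OTUs whose total count across samples is at
#' most one (singletons, and empty rows which carry no information).
#'
#' @param x An [otu_table()] with taxonomy.
#' @param keywords Character vector of contaminant keywords.
#' @return A filtered `otu_table`. Each category of drop is reported via
#'   [rlang::inform()].
#' @export
remove_contaminants_and_singletons <- function(
    x, keywords = c("chloroplast", "mitochondria", "unassigned", "unidentified")) {
  stopifnot(inherits(x, "otu_table"))
  if (is.null(x$taxonomy)) abort("Taxonomy is required for contaminant removal.")
  tax <- tolower(x$taxonomy)
  contaminant <- rep(FALSE, nrow(x$counts))
  for (k in tolower(keywords)) contaminant <- contaminant | grepl(k, tax, fixed = TRUE)
  singleton <- rowSums(x$counts) <= 1
  keep <- !contaminant & !singleton
  inform(paste0("Dropped ", sum(contaminant), " contaminant and ",
                sum(singleton & !contaminant), " singleton/empty OTUs; ",
                sum(keep), " retained."))
  if (!any(keep)) warn("All OTUs removed by contaminant/singleton filter.")
  subset_otus(x, keep)
}

#' Filter OTUs by total read count
#'
#' Keeps OTUs whose total count across all samples is at least `min_reads`.
#' Two named presets mirror the two read-count rules used when analysing
#' amplicon surveys: `"more_than_10"` keeps OTUs with more than 10 reads
#' (i.e. totals >= 11, the diversity-analysis rule) and `"network"` keeps
#' OTUs with totals >= 1000 (the co-occurrence rule, under which OTUs with
#' fewer than 1000 reads are deleted).
#'
#' @param x An [otu_table()].
#' @param min_reads Minimum total count to keep (ignored when `preset` given).
#' @param preset `"more_than_10"` or `"network"`, or `NULL` to use `min_reads`.
#' @return A filtered `otu_table`.
#' @export
filter_min_total <- function(x, min_reads = 0, preset = NULL) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("more_than_10", "network"))
    min_reads <- switch(preset, more_than_10 = 11, network = 1000)
  }
  if (min_reads < 0) abort("`min_reads` must be >= 0.")
  keep <- rowSums(x$counts) >= min_reads
  if (!all(keep)) {
    inform(paste0("filter_min_total: dropped ", sum(!keep),
                  " OTUs with total < ", min_reads, "."))
  }
  subset_otus(x, keep)
}

#' Rarefy samples to a common depth
#'
#' Each sample is subsampled uniformly *without replacement* to exactly
#' `depth` reads. Samples with fewer than `depth` total reads are dropped
#' and reported.
#'
#' @param x An [otu_table()].
#' @param depth Target reads per sample (>= 1).
#' @param seed Optional integer seed for reproducible subsampling.
#' @return An `otu_table` whose columns all sum to `depth`.
#' @export
rarefy_table <- function(x, depth, seed = NULL) {
  stopifnot(inherits(x, "otu_table"))
  if (depth < 1) abort("`depth` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  tot <- colSums(x$counts)
  shallow <- tot < depth
  if (any(shallow)) {
    inform(paste0("rarefy_table: dropped ", sum(shallow), " sample(s) below depth ",
                  depth, ": ",
                  paste(colnames(x$counts)[shallow], collapse = ", ")))
  }
  x <- subset_samples_tab(x, !shallow)
  n <- nrow(x$counts)
  out <- apply(x$counts, 2, function(col) {
    reads <- rep.int(seq_len(n), col)
    tabulate(sample(reads, depth), nbins = n)
  })
  rownames(out) <- rownames(x$counts)
  otu_table(out, taxonomy = x$taxonomy, metadata = x$metadata)
}

#' Aggregate counts at a taxonomic rank
#'
#' Sums counts within taxa sharing the same label at `rank` (1 = domain
#' through 7 = species in the usual SILVA 7-rank scheme). OTUs whose
#' taxonomy is missing or truncated above `rank` are pooled into an
#' `"unclassified at rank <r>"` row. Column sums are preserved exactly.
#'
#' @param x An [otu_table()] with taxonomy.
#' @param rank Integer in 1..7.
#' @return An `otu_table` with one row per taxon at `rank`.
#' @export
aggregate_by_rank <- function(x, rank) {
  stopifnot(inherits(x, "otu_table"))
  if (nrow(x$counts) == 0) abort("Empty table.")
  if (is.null(x$taxonomy)) abort("Taxonomy is required for aggregation.")
  if (!(rank %in% 1:7)) abort("`rank` must be in 1..7.")
  labs <- vapply(strsplit(x$taxonomy, ";", fixed = TRUE), function(p) {
    p <- trimws(p)
    if (length(p) >= rank && nzchar(p[rank])) p[rank] else NA_character_
  }, "")
  labs[is.na(labs)] <- paste0("unclassified at rank ", rank)
  agg <- rowsum(x$counts, group = labs)
  otu_table(agg, taxonomy = rownames(agg), metadata = x$metadata)
}

#' Filter OTUs by share of total reads
#'
#' Keeps OTUs whose total count exceeds `threshold_fraction` of the grand
#' total (strictly greater). The grand total is that of the table passed in,
#' i.e. the share is evaluated before, not after, removal.
#'
#' @param x An [otu_table()].
#' @param threshold_fraction Fraction in `[0, 1)`; e.g. `0.00075` keeps OTUs
#'   above 0.075% of total reads.
#' @return A filtered `otu_table`.
#' @export
filter_min_relative <- function(x, threshold_fraction) {
  stopifnot(inherits(x, "otu_table"))
  if (threshold_fraction < 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must be in [0, 1).")
  }
  grand <- sum(x$counts)
  keep <- rowSums(x$counts) / grand > threshold_fraction
  if (!all(keep)) {
    inform(paste0("filter_min_relative: dropped ", sum(!keep),
                  " OTUs at <= ", threshold_fraction * 100, "% of total reads."))
  }
  subset_otus(x, keep)
}
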