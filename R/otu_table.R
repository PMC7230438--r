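#' Construct an OTU count table
#'
#' The central container of the package: a non-negative integer count matrix
#' (OTUs in rows, samples in columns), an optional taxonomy string per OTU
#' (rank-delimited, SILVA style, possibly truncated), and an optional
#' per-sample metadata tibble describing the experimental design.
#'
#' @param counts Numeric matrix of non-negative counts with unique rownames
#'   (OTU ids) and unique colnames (sample ids).
#' @param taxonomy Optional character vector of semicolon-delimited taxonomy
#'   strings, one per OTU (recycled names are taken from `counts`).
#' @param metadata Optional data frame with one row per sample and at least a
#'   `sample_id` column; typical columns are `habitat` (e.g. rhizosphere vs
#'   bulk), `treatment` and `block`. Every sample id in `counts` must appear.
#'
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `taxonomy` and `metadata`.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("OTU_1", "OTU_2"), c("S1", "S2")))
#' otu_table(m, taxonomy = c("Bacteria;Acidobacteria", "Bacteria;Proteobacteria"))
otu_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have OTU rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(counts))) abort("Duplicate OTU ids in `counts`.")
  if (anyDuplicated(colnames(counts))) abort("Duplicate sample ids in `counts`.")
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    abort("`counts` must be finite, non-negative and numeric.")
  }
  storage.mode(counts) <- "double"
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (length(taxonomy) != nrow(counts)) {
      abort("`taxonomy` must have one entry per OTU.")
    }
    names(taxonomy) <- rownames(counts)
  }
  if (!is.null(metadata)) {
    metadata <- as_tibble(metadata)
    if (!"sample_id" %in% names(metadata)) {
      abort("`metadata` must contain a `sample_id` column.")
    }
    metadata$sample_id <- as.character(metadata$sample_id)
    missing <- setdiff(colnames(counts), metadata$sample_id)
    if (length(missing) > 0) {
      abort(paste0("Metadata missing for sample(s): ",
                   paste(missing, collapse = ", ")))
    }
    metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("<otu_table> ", nrow(x$counts), " OTUs x ", ncol(x$counts),
      " samples; total reads ", format(sum(x$counts), big.mark = ","), "\n",
      sep = "")
  if (!is.null(x$taxonomy)) cat("  taxonomy: present\n")
  if (!is.null(x$metadata)) {
    cat("  metadata: ", paste(setdiff(names(x$metadata), "sample_id"),
                              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' OTU and sample identifiers
#' @param x An `otu_table`.
#' @return Character vector of ids.
#' @export
otu_ids <- function(x) rownames(x$counts)

#' @rdname otu_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

# Internal: subset keeping taxonomy/metadata aligned.
subset_otus <- function(x, keep) {
  counts <- x$counts[keep, , drop = FALSE]
  otu_table(counts,
            taxonomy = if (!is.null(x$taxonomy)) x$taxonomy[keep] else NULL,
            metadata = x$metadata)
}

subset_samples_tab <- function(x, keep) {
  counts <- x$counts[, keep, drop = FALSE]
  md <- x$metadata
  if (!is.null(md)) md <- md[match(colnames(counts), md$sample_id), ]
  otu_table(counts, taxonomy = x$taxonomy, metadata = md)
}

#' Convert counts to relative abundances
#'
#' Closes each sample (column) to proportions summing to one. All-zero
#' samples are an error because their composition is undefined.
#'
#' @param x An `otu_table`.
#' @return An object of class `rel_abundance_table` with elements
#'   `proportions` (matrix), `taxonomy`, `metadata` and `source_totals`
#'   (the per-sample read counts the proportions were derived from).
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  tot <- colSums(x$counts)
  if (any(tot == 0)) {
    abort(paste0("All-zero sample(s): ",
                 paste(colnames(x$counts)[tot == 0], collapse = ", ")))
  }
  props <- sweep(x$counts, 2, tot, "/")
  structure(list(proportions = props, taxonomy = x$taxonomy,
                 metadata = x$metadata, source_totals = tot),
            class = "rel_abundance_table")
}

#' @export
print.rel_abundance_table <- function(x, ...) {
  cat("<rel_abundance_table> ", nrow(x$proportions), " OTUs x ",
      ncol(x$proportions), " samples\n", sep = "")
  invisible(x)
}

# Internal: accept otu_table or rel_abundance_table, return proportion matrix.
as_proportions <- function(x) {
  if (inherits(x, "rel_abundance_table")) return(x$proportions)
  if (inherits(x, "otu_table")) return(to_relative(x)$proportions)
  if (is.matrix(x)) return(x)
  abort("Expected an otu_table, rel_abundance_table or matrix.")
}
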