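#' Read an OTU table from disk
#'
#' Supports the QIIME-classic tab-separated layout (a `#OTU ID` header row,
#' one OTU per row, optional trailing `taxonomy` column, optional leading
#' comment line) and BIOM-JSON (format 1.0, via the biomformat package).
#'
#' @param path File path.
#' @param format `"classic_tsv"` or `"biom_json"`.
#' @param metadata Optional per-sample metadata tibble (or a mapping-file
#'   path) to attach; see [read_mapping_file()].
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, format = c("classic_tsv", "biom_json"),
                           metadata = NULL) {
  format <- match.arg(format)
  if (is.character(metadata) && length(metadata) == 1) {
    metadata <- read_mapping_file(metadata)
  }
  tab <- switch(format,
    classic_tsv = read_classic_tsv(path),
    biom_json = read_biom_json(path)
  )
  if (!is.null(metadata)) {
    tab <- otu_table(tab$counts, taxonomy = tab$taxonomy, metadata = metadata)
  }
  tab
}

read_classic_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr_idx <- grep("^#OTU ID\t", lines)[1]
  if (is.na(hdr_idx)) abort("No '#OTU ID' header row found.")
  header <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  has_tax <- tolower(header[length(header)]) == "taxonomy"
  sample_ids <- header[-1]
  if (has_tax) sample_ids <- sample_ids[-length(sample_ids)]
  body <- lines[seq(hdr_idx + 1, length(lines))]
  body <- body[!startsWith(body, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  want <- length(header)
  bad <- which(vapply(parts, length, 1L) != want)
  if (length(bad) > 0) {
    abort(paste0("Malformed row at line ", hdr_idx + bad[1], " of ", path,
                 ": expected ", want, " fields."))
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) abort("Duplicate OTU ids in classic TSV.")
  ncount <- length(sample_ids)
  num <- vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[2:(1 + ncount)]))
    v
  }, numeric(ncount))
  num <- matrix(num, ncol = ncount, byrow = TRUE,
                dimnames = list(ids, sample_ids))
  if (any(is.na(num))) abort("Non-numeric count encountered in classic TSV.")
  if (any(num < 0)) abort("Negative count encountered in classic TSV.")
  taxonomy <- if (has_tax) vapply(parts, function(p) p[[length(p)]], "") else NULL
  otu_table(num, taxonomy = taxonomy)
}

read_biom_json <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("BIOM-JSON support needs the 'biomformat' package.")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  taxonomy <- NULL
  if (!is.null(om)) {
    if (is.data.frame(om)) {
      taxonomy <- apply(om, 1, paste, collapse = ";")
    } else if (is.list(om)) {
      taxonomy <- vapply(om, function(r) paste(unlist(r), collapse = ";"), "")
    }
    taxonomy <- taxonomy[rownames(m)]
  }
  otu_table(m, taxonomy = taxonomy)
}

#' Write an OTU table to disk
#'
#' @param x An [otu_table()].
#' @inheritParams read_otu_table
#' @return Invisibly, `path`.
#' @export
write_otu_table <- function(x, path, format = c("classic_tsv", "biom_json")) {
  stopifnot(inherits(x, "otu_table"))
  format <- match.arg(format)
  if (format == "classic_tsv") {
    header <- c("#OTU ID", colnames(x$counts))
    if (!is.null(x$taxonomy)) header <- c(header, "taxonomy")
    rows <- apply(x$counts, 1, function(r)
      paste(format(r, scientific = FALSE, trim = TRUE), collapse = "\t"))
    body <- paste0(rownames(x$counts), "\t", rows)
    if (!is.null(x$taxonomy)) body <- paste0(body, "\t", x$taxonomy)
    writeLines(c(paste(header, collapse = "\t"), body), path)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("BIOM-JSON support needs the 'biomformat' package.")
    }
    om <- NULL
    if (!is.null(x$taxonomy)) {
      om <- data.frame(taxonomy = unname(x$taxonomy),
                       row.names = rownames(x$counts))
    }
    b <- biomformat::make_biom(x$counts, observation_metadata = om)
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read / write a QIIME-style mapping file
#'
#' The mapping file is a TSV whose header starts with `#SampleID`; columns
#' are renamed to lower case (`sample_id`, `habitat`, `treatment`, `block`).
#'
#' @param path File path.
#' @return A tibble of per-sample metadata.
#' @export
read_mapping_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#SampleID", lines)[1]
  if (is.na(hdr)) abort("No '#SampleID' header row found.")
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr)]
  body <- body[!startsWith(body, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != length(cols))
  if (length(bad) > 0) {
    abort(paste0("Malformed mapping row at line ", hdr + bad[1], "."))
  }
  df <- as_tibble(do.call(rbind, parts), .name_repair = "minimal")
  names(df) <- cols
  names(df)[names(df) == "SampleID"] <- "sample_id"
  names(df) <- tolower(names(df))
  df
}

#' @rdname read_mapping_file
#' @param metadata A tibble with `sample_id` first.
#' @export
write_mapping_file <- function(metadata, path) {
  md <- as_tibble(metadata)
  stopifnot("sample_id" %in% names(md))
  md <- md[, c("sample_id", setdiff(names(md), "sample_id"))]
  cols <- names(md)
  cols[1] <- "#SampleID"
  cols[-1] <- sub("^(.)", "\\U\\1", cols[-1], perl = TRUE)
  body <- apply(md, 1, paste, collapse = "\t")
  writeLines(c(paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read / write a gene-abundance table
#'
#' A TSV with samples in rows (`sample_id` first column) and one column per
#' gene (e.g. `amoA_bacterial`, `amoA_archaeal`, `nirK`, `nirS`, `nosZ_I`,
#' `nosZ_II`); values are qPCR abundances, either absolute copies per gram of
#' soil or percent of 16S rRNA gene copies.
#'
#' @param path File path.
#' @return A tibble with `sample_id` and one numeric column per gene.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  for (j in seq_along(df)[-1]) df[[j]] <- as.numeric(df[[j]])
  if (any(vapply(df[-1], function(v) any(!is.finite(v)) || any(v < 0), TRUE))) {
    abort("Gene abundances must be finite and non-negative.")
  }
  as_tibble(df)
}

#' @rdname read_gene_table
#' @param genes A tibble as returned by [read_gene_table()].
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
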