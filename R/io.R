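# Plain-text I/O. Matrices travel as TSV with gene IDs in the first column
# and sample IDs in the header; peaks and regions as BED (0-based,
# half-open); gene sets as one-ID-per-line text or a two-column (gene,
# class) TSV.

#' Read a genes-by-samples matrix from TSV
#'
#' Expects a header row of sample IDs and gene IDs in the first column.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene IDs in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate sample IDs in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a genes-by-samples matrix to TSV
#'
#' @param m Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param id_column Name for the first (gene ID) column.
#' @export
write_matrix_tsv <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' The table must contain a `sample_id` column; remaining columns are kept
#' as-is (cohort labels, donor IDs, covariates, mutation status).
#'
#' @param path Path to a TSV file.
#' @return data.frame keyed by `sample_id`.
#' @export
read_metadata_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) {
    stop("metadata must contain a 'sample_id' column")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs in ", path)
  df
}

#' Read a gene set from plain text
#'
#' Accepts either one gene ID per line or a two-column TSV of
#' (gene, class).
#'
#' @param path Path to the file.
#' @param name Name of the set; defaults to the file name.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  members <- vapply(parts, `[[`, "", 1L)
  classification <- NULL
  if (all(lengths(parts) >= 2L)) {
    classification <- setNames(vapply(parts, `[[`, "", 2L), members)
  }
  gene_set(name %||% basename(path), members, classification)
}

#' Read BED intervals
#'
#' Minimal BED reader: chrom, start, end and (optionally) name. BED is
#' 0-based, half-open; coordinates are kept in that convention.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns chrom, start, end and optionally name.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$name <- as.character(df[[4L]])
  if (any(out$start >= out$end)) stop("BED intervals must have start < end")
  out
}

#' Write BED intervals
#'
#' @param df data.frame with chrom, start, end and optional further columns.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    colnames(df))
  write.table(df[, keep, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
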