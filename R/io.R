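## Readers and writers for the plain-text formats used by the pipeline.

#' Read / write probe-level intensity tables
#'
#' CSV with columns `subject_id`, `batch_id`, `probe_id`, `chrom`, `lrr`
#' (batch optional on read).
#'
#' @param path file path.
#' @return data.frame of probes.
#' @export
read_intensity_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "chrom", "lrr")
  if (!all(need %in% names(df)))
    stop("intensity CSV needs columns subject_id, chrom, lrr")
  df$chrom <- as.character(df$chrom)
  df
}

#' @rdname read_intensity_csv
#' @param profiles probe-level data.frame.
#' @export
write_intensity_csv <- function(profiles, path) {
  write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' Read digital PCR plate tables
#'
#' CSV with columns `sample_id`, `n_partitions`, `positives_y`,
#' `positives_x` (optional `volume`).
#'
#' @param path file path.
#' @return data.frame of plates.
#' @export
read_plates_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "n_partitions", "positives_y", "positives_x")
  if (!all(need %in% names(df)))
    stop("plate CSV needs columns sample_id, n_partitions, positives_y, positives_x")
  df
}

#' Write a CellDataset as 10x-style MTX + TSV files
#'
#' Writes `matrix.mtx` (MatrixMarket), `features.tsv`, `barcodes.tsv` and
#' `cells.csv` (metadata) into `dir`.
#'
#' @param dataset a [cell_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dataset$counts, file.path(dir, "matrix.mtx"))
  write.table(dataset$genes, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(dataset$counts), file.path(dir, "barcodes.tsv"))
  write.csv(dataset$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style MTX directory into a CellDataset
#'
#' Expects `matrix.mtx`, `features.tsv` (first column = gene id),
#' `barcodes.tsv`, and optionally `cells.csv` metadata.
#'
#' @param dir directory path.
#' @param msy_genes MSY gene list (default shipped list).
#' @return a [cell_dataset()].
#' @export
read_cell_dataset <- function(dir, msy_genes = default_msy_genes()) {
  counts <- as_csparse(Matrix::readMM(file.path(dir, "matrix.mtx")))
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(feats[[1]], barcodes)
  meta_path <- file.path(dir, "cells.csv")
  cells <- if (file.exists(meta_path))
    read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  if (!is.null(cells))
    cells <- cells[setdiff(names(cells),
                           c("depth", "n_expressed_genes", "mito_fraction"))]
  cell_dataset(counts, cells, msy_genes = msy_genes)
}

#' Read a dense delimited expression matrix into a CellDataset
#'
#' First column gene identifiers, remaining columns cells.
#'
#' @param path file path.
#' @param sep field separator.
#' @inheritParams read_cell_dataset
#' @return a [cell_dataset()].
#' @export
read_dense_matrix <- function(path, sep = ",", msy_genes = default_msy_genes()) {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  cell_dataset(m, msy_genes = msy_genes)
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name`, `description`, genes.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions in attribute
#'   `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}
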