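#' Construct a single-cell dataset container
#'
#' Bundles a genes x cells count matrix with per-gene flags (MSY membership,
#' mitochondrial) and per-cell metadata.  Depth (total transcripts), number
#' of expressed genes and mitochondrial fraction are always recomputed from
#' the matrix so that metadata and counts cannot drift apart.
#'
#' @param counts genes x cells matrix of non-negative integer counts, with
#'   rownames (gene identifiers) and colnames (cell identifiers); dense or
#'   `Matrix` sparse.
#' @param cells data.frame of per-cell metadata, one row per column of
#'   `counts` (matched by `cell_id` column if present, else by order).
#'   Typical columns: `donor_id`, `sex`, `condition`, `cell_type`.
#' @param msy_genes character vector of gene identifiers belonging to the
#'   male-specific region of chromosome Y (MSY).  Defaults to the list
#'   shipped with the package (see [default_msy_genes()]).
#' @param mito_pattern regular expression identifying mitochondrial genes.
#' @return object of class `CellDataset`: list with `counts` (dgCMatrix),
#'   `genes` (data.frame: `gene`, `is_msy`, `is_mito`) and `cells`
#'   (metadata plus computed `depth`, `n_expressed_genes`, `mito_fraction`).
#' @export
cell_dataset <- function(counts, cells = NULL, msy_genes = default_msy_genes(),
                         mito_pattern = "^MT-") {
  counts <- as_csparse(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and cell colnames")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  genes <- data.frame(gene = rownames(counts),
                      is_msy = rownames(counts) %in% msy_genes,
                      is_mito = grepl(mito_pattern, rownames(counts)),
                      stringsAsFactors = FALSE)
  depth <- Matrix::colSums(counts)
  nexpr <- Matrix::colSums(counts > 0)
  mito <- if (any(genes$is_mito))
    Matrix::colSums(counts[genes$is_mito, , drop = FALSE]) / pmax(depth, 1)
  else rep(0, ncol(counts))
  meta <- data.frame(cell_id = colnames(counts), stringsAsFactors = FALSE)
  if (!is.null(cells)) {
    cells <- as.data.frame(cells)
    if ("cell_id" %in% names(cells)) {
      idx <- match(colnames(counts), cells$cell_id)
      if (anyNA(idx)) stop("cells metadata missing entries for some cells")
      cells <- cells[idx, setdiff(names(cells), "cell_id"), drop = FALSE]
    } else if (nrow(cells) != ncol(counts)) {
      stop("cells metadata must have one row per cell")
    }
    meta <- cbind(meta, cells, stringsAsFactors = FALSE)
  }
  meta$depth <- as.numeric(depth)
  meta$n_expressed_genes <- as.integer(nexpr)
  meta$mito_fraction <- as.numeric(mito)
  rownames(meta) <- NULL
  structure(list(counts = counts, genes = genes, cells = meta),
            class = "CellDataset")
}

#' @export
print.CellDataset <- function(x, ...) {
  cat(sprintf("CellDataset: %d genes x %d cells (%d MSY, %d mito genes)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$genes$is_msy), sum(x$genes$is_mito)))
  if ("condition" %in% names(x$cells))
    print(table(condition = x$cells$condition))
  invisible(x)
}

#' @export
dim.CellDataset <- function(x) dim(x$counts)

#' Library-size normalized, log1p-transformed expression
#'
#' The single normalization used by all expression-based operations: each
#' cell's counts are scaled to a common library size `scale` and
#' log1p-transformed.  Sparsity is preserved.
#'
#' @param dataset a `CellDataset` (or a bare counts matrix).
#' @param scale common library size (default 1e4).
#' @return dgCMatrix of normalized values, same dimensions as the counts.
#' @export
lognorm_matrix <- function(dataset, scale = 1e4) {
  counts <- if (inherits(dataset, "CellDataset")) dataset$counts
            else as_csparse(dataset)
  depth <- pmax(Matrix::colSums(counts), 1)
  norm <- counts %*% Matrix::Diagonal(x = scale / depth)
  norm <- as_csparse(norm)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}

## coerce dense/sparse input to a numeric dgC sparse matrix without relying
## on implicit S4 coercion method lookup (robust when Matrix is only loaded,
## not attached)
as_csparse <- function(x) {
  if (is(x, "Matrix")) {
    if (is(x, "CsparseMatrix") && is(x, "dMatrix")) return(x)
    return(methods::as(x * 1, "CsparseMatrix"))
  }
  Matrix::Matrix(as.matrix(x) * 1, sparse = TRUE)
}

#' Default MSY gene list
#'
#' Symbols of genes in the male-specific region of chromosome Y, as shipped
#' in `inst/extdata/msy_genes.txt` (human symbols matching the Ensembl
#' release-91 annotation commonly used for single-cell LOY calling).
#' Override by passing your own vector to [cell_dataset()].
#'
#' @return character vector of gene symbols.
#' @export
default_msy_genes <- function() {
  path <- system.file("extdata", "msy_genes.txt", package = "mloykit")
  if (!nzchar(path)) stop("shipped MSY gene list not found")
  readLines(path, warn = FALSE)
}

#' Default hierarchical marker table
#'
#' Three-level marker map used by [annotate_cell_types()]: major pulmonary
#' cell types (leukocyte PTPRC, endothelial CDH5, epithelial EPCAM,
#' fibroblast PDGFRA, smooth muscle ACTA2), leukocyte lineages (macrophage
#' CD68, monocyte CSF1R, neutrophil CSF3R, T cell CD3G, B cell CD79A, NK
#' NCAM1, dendritic CD80), and macrophage subtypes (M1 IL1B, M2 MRC1, M2a
#' FN1+TGM2, M2b IL1B, M2c MERTK, M2d VEGFA).
#'
#' @return data.frame with columns `level` (major/lineage/subtype), `label`,
#'   `gene`, and `parent` (label at the level above, or NA).
#' @export
default_marker_table <- function() {
  path <- system.file("extdata", "marker_table.csv", package = "mloykit")
  read.csv(path, stringsAsFactors = FALSE)
}
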