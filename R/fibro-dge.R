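#' Differential expression between LOY and WT cells
#'
#' Per-gene two-sided Wilcoxon rank-sum test on library-size-normalized
#' log1p expression, comparing LOY cells with WT cells within a chosen cell
#' subset.  For small arms (both <= 10 cells) the permutation null is
#' enumerated exactly; otherwise the tie-corrected normal approximation is
#' used.  The log2 fold change is computed from mean normalized (linear
#' scale) expression with a pseudocount of 1 on the common-library-size
#' scale.  MSY genes are flagged: they define the LOY groups and must come
#' out down-regulated, so they are not biological findings.
#'
#' Cells enter only if they pass QC, the functional depth gate
#' (`depth_pass`, see [qc_filter_depth()]; computed here with the default
#' 4000-read threshold when absent) and `subset`.
#'
#' @param dataset a [cell_dataset()].
#' @param calls output of [call_loy()].
#' @param subset logical vector aligned with `calls` restricting the cells
#'   (e.g. one cell type within IPF donors); default all.
#' @param min_cells minimum cells per arm (skip with a message otherwise).
#' @param scale common library size for normalization.
#' @param min_detect test only genes detected in at least this fraction of
#'   included cells (default 0, i.e. any expressed gene).
#' @return data.frame: `gene`, `log2fc`, `p_value`, `q_value`, `pct_loy`,
#'   `pct_wt`, `is_msy`; `NULL` (with a message) if either arm is too small.
#' @export
dge_loy_vs_wt <- function(dataset, calls, subset = NULL, min_cells = 20,
                          scale = 1e4, min_detect = 0) {
  if (is.null(subset)) subset <- rep(TRUE, nrow(calls))
  stopifnot(length(subset) == nrow(calls))
  if (is.null(calls$depth_pass))
    calls <- qc_filter_depth(dataset, calls)
  use <- subset & !is.na(calls$is_loy) & calls$depth_pass
  grp_loy <- use & calls$is_loy
  grp_wt <- use & !calls$is_loy
  if (sum(grp_loy) < min_cells || sum(grp_wt) < min_cells) {
    message(sprintf("skipping DGE: %d LOY / %d WT cells (< %d per arm)",
                    sum(grp_loy), sum(grp_wt), min_cells))
    return(NULL)
  }
  norm <- lognorm_matrix(dataset, scale = scale)
  ix_l <- match(calls$cell_id[grp_loy], colnames(norm))
  ix_w <- match(calls$cell_id[grp_wt], colnames(norm))
  lin_l <- expm1(norm[, ix_l, drop = FALSE])
  lin_w <- expm1(norm[, ix_w, drop = FALSE])
  det_l <- Matrix::rowMeans(lin_l > 0)
  det_w <- Matrix::rowMeans(lin_w > 0)
  test_genes <- which((det_l > 0 | det_w > 0) &
                      pmax(det_l, det_w) >= min_detect)
  log2fc <- log2((Matrix::rowMeans(lin_l)[test_genes] + 1) /
                 (Matrix::rowMeans(lin_w)[test_genes] + 1))
  nl <- as.matrix(norm[test_genes, ix_l, drop = FALSE])
  nw <- as.matrix(norm[test_genes, ix_w, drop = FALSE])
  p <- vapply(seq_along(test_genes), function(i)
    ranksum_test(nl[i, ], nw[i, ])$p_value, numeric(1))
  out <- data.frame(gene = rownames(norm)[test_genes],
                    log2fc = as.numeric(log2fc), p_value = p,
                    q_value = bh_adjust(p),
                    pct_loy = as.numeric(det_l[test_genes]),
                    pct_wt = as.numeric(det_w[test_genes]),
                    is_msy = dataset$genes$is_msy[test_genes],
                    stringsAsFactors = FALSE)
  out[order(out$p_value), ]
}
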