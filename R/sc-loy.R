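#' Quality-control filter for single cells
#'
#' Standard low-quality-cell removal before LOY calling: a cell passes when
#' its mitochondrial fraction is at most `mito_max` (default 10%) and its
#' number of expressed genes lies in `[genes_min, genes_max]` (defaults
#' 800-3500; cells below are likely empty droplets or debris, cells above
#' likely doublets).  Failure reasons are recorded per cell.
#'
#' @param dataset a [cell_dataset()].
#' @param mito_max maximum mitochondrial fraction.
#' @param genes_min,genes_max expressed-gene bounds (inclusive).
#' @return data.frame (one row per cell): `cell_id`, `qc_pass`,
#'   `qc_reasons` (comma-separated, "" when passing).
#' @export
qc_filter_cells <- function(dataset, mito_max = 0.10, genes_min = 800,
                            genes_max = 3500) {
  m <- dataset$cells
  mito_fail <- m$mito_fraction > mito_max
  low <- m$n_expressed_genes < genes_min
  high <- m$n_expressed_genes > genes_max
  reasons <- mapply(function(a, b, c)
    paste(c(if (a) "mito", if (b) "low_genes", if (c) "high_genes"),
          collapse = ","),
    mito_fail, low, high)
  data.frame(cell_id = m$cell_id, qc_pass = !(mito_fail | low | high),
             qc_reasons = reasons, stringsAsFactors = FALSE)
}

#' Depth filter for functional (expression) analyses
#'
#' Cells must have strictly more than `min_reads` total transcripts to enter
#' differential expression and module scoring; this is a separate, stricter
#' gate than the clustering QC of [qc_filter_cells()] and is recorded in its
#' own column.
#'
#' @param dataset a [cell_dataset()].
#' @param calls data.frame from [qc_filter_cells()] (or [call_loy()]); the
#'   `depth_pass` column is added to it.
#' @param min_reads threshold; inclusion requires `depth > min_reads`
#'   (strict, so a cell at exactly `min_reads` is excluded).
#' @return `calls` with a logical `depth_pass` column.
#' @export
qc_filter_depth <- function(dataset, calls, min_reads = 4000) {
  depth <- dataset$cells$depth[match(calls$cell_id, dataset$cells$cell_id)]
  calls$depth_pass <- depth > min_reads
  calls
}

#' Call LOY cells by complete absence of MSY expression
#'
#' Sums transcripts over all genes of the male-specific region of Y (MSY)
#' per cell; a QC-passing cell with an MSY total of exactly zero is called a
#' LOY cell.  "Complete absence" is strict: a single MSY transcript makes
#' the cell wild-type (WT).  Cells failing QC get `is_loy = NA`.
#'
#' @param dataset a [cell_dataset()] (its `genes$is_msy` flags define the
#'   set; must be non-empty).
#' @param calls QC data.frame from [qc_filter_cells()]; computed here if
#'   missing.
#' @return `calls` with `msy_total` and logical `is_loy` columns.
#' @export
call_loy <- function(dataset, calls = NULL) {
  if (!any(dataset$genes$is_msy))
    stop("MSY gene set is empty; configure msy_genes in cell_dataset()")
  if (is.null(calls)) calls <- qc_filter_cells(dataset)
  msy <- Matrix::colSums(dataset$counts[dataset$genes$is_msy, , drop = FALSE])
  msy <- msy[match(calls$cell_id, colnames(dataset$counts))]
  calls$msy_total <- as.numeric(msy)
  calls$is_loy <- ifelse(calls$qc_pass, calls$msy_total == 0, NA)
  calls
}

#' Marker-based hierarchical cell-type annotation
#'
#' Scores each cell (or each externally supplied cluster) against a marker
#' table at up to three levels: major type, then - for leukocytes -
#' immune lineage, then - for macrophages - polarization subtype.  The score
#' of a label is the mean library-size-normalized, log1p-transformed
#' expression of its marker genes; the maximal score wins, with
#' deterministic lexicographic tie-breaking.  M1 and M2b share IL1B as a
#' marker; the tie is resolved by MRC1 negativity (an M1 call requires zero
#' normalized MRC1, otherwise M2b is assigned).
#'
#' @param dataset a [cell_dataset()].
#' @param marker_table data.frame as [default_marker_table()].
#' @param clusters optional factor/character of cluster ids per cell; when
#'   given, scores are averaged within cluster and the whole cluster is
#'   labelled.
#' @return data.frame: `cell_id`, `major_type`, `lineage`, `subtype`,
#'   `cell_type` (finest available label).
#' @export
annotate_cell_types <- function(dataset, marker_table = default_marker_table(),
                                clusters = NULL) {
  norm <- lognorm_matrix(dataset)
  if (!is.null(clusters)) {
    stopifnot(length(clusters) == ncol(norm))
    cl <- as.character(clusters)
    groups <- split(seq_len(ncol(norm)), cl)
    prof <- vapply(groups, function(ix)
      Matrix::rowMeans(norm[, ix, drop = FALSE]), numeric(nrow(norm)))
    norm_use <- prof
  } else {
    norm_use <- norm
  }

  score_level <- function(level, parent_filter = NULL) {
    tab <- marker_table[marker_table$level == level, , drop = FALSE]
    if (!is.null(parent_filter))
      tab <- tab[tab$parent %in% parent_filter, , drop = FALSE]
    labels <- sort(unique(tab$label))      # lexicographic tie-break order
    scores <- vapply(labels, function(lb) {
      g <- intersect(tab$gene[tab$label == lb], rownames(norm_use))
      if (length(g) == 0L) {
        warning(sprintf("no markers of label '%s' present in matrix", lb))
        return(rep(-Inf, ncol(norm_use)))
      }
      Matrix::colMeans(norm_use[g, , drop = FALSE])
    }, numeric(ncol(norm_use)))
    if (all(!is.finite(scores)))
      stop(sprintf("no marker genes present for level '%s'", level))
    labels[max.col(scores, ties.method = "first")]
  }

  major <- score_level("major")
  lineage <- rep(NA_character_, length(major))
  leuk <- major == "leukocyte"
  if (any(leuk) && any(marker_table$level == "lineage"))
    lineage[leuk] <- score_level("lineage")[leuk]
  subtype <- rep(NA_character_, length(major))
  mac <- !is.na(lineage) & lineage == "macrophage"
  if (any(mac) && any(marker_table$level == "subtype")) {
    sub_all <- score_level("subtype")
    ## M1 vs M2b disambiguation: both marked by IL1B; require MRC1-negative
    ## normalized expression for an M1 call
    if ("MRC1" %in% rownames(norm_use)) {
      mrc1 <- as.numeric(norm_use["MRC1", ])
      sub_all[sub_all == "M1" & mrc1 > 0] <- "M2b"
      sub_all[sub_all == "M2b" & mrc1 == 0] <- "M1"
    }
    subtype[mac] <- sub_all[mac]
  }
  finest <- ifelse(!is.na(subtype), subtype,
                   ifelse(!is.na(lineage), lineage, major))
  out_ids <- if (is.null(clusters)) dataset$cells$cell_id else names(groups)
  res <- data.frame(id = out_ids, major_type = major, lineage = lineage,
                    subtype = subtype, cell_type = finest,
                    stringsAsFactors = FALSE)
  if (!is.null(clusters)) {
    res <- res[match(cl, res$id), ]
    res$id <- dataset$cells$cell_id
  }
  names(res)[1] <- "cell_id"
  rownames(res) <- NULL
  res
}

#' Per-cell-type LOY enrichment between conditions
#'
#' For each cell type, builds the 2x2 table of LOY/WT cells in case vs
#' control donors and applies Fisher's exact test (two-sided).  The reported
#' odds ratio is the conditional maximum-likelihood estimate with its exact
#' conditional confidence interval; when a zero cell makes that estimate
#' degenerate (0 or infinite), a Woolf interval with Haldane-Anscombe 0.5
#' correction is reported instead and annotated in `or_method`.  P-values
#' are reported unadjusted with star marks at 0.05/0.01/0.001/0.0001, plus a
#' Benjamini-Hochberg column across types.
#'
#' @param calls output of [call_loy()].
#' @param labels character vector of cell-type labels aligned with `calls`
#'   (e.g. `annotate_cell_types(...)$cell_type` or metadata labels).
#' @param condition character vector aligned with `calls`.
#' @param case,control condition values contrasted (default "IPF" vs
#'   "control"); types missing either arm are skipped with a note.
#' @param conf_level CI level.
#' @return data.frame: `cell_type`, counts `a` (LOY case), `b` (WT case),
#'   `c` (LOY control), `d` (WT control), `sample_or`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `or_method`, `p_value`, `q_value`, `stars`.
#' @export
loy_enrichment_by_type <- function(calls, labels, condition, case = "IPF",
                                   control = "control", conf_level = 0.95) {
  stopifnot(length(labels) == nrow(calls), length(condition) == nrow(calls))
  keep <- !is.na(calls$is_loy) & condition %in% c(case, control) &
    !is.na(labels)
  loy <- calls$is_loy[keep]; lab <- labels[keep]
  is_case <- condition[keep] == case
  res <- lapply(sort(unique(lab)), function(tp) {
    sel <- lab == tp
    if (!any(sel & is_case) || !any(sel & !is_case)) {
      message(sprintf("cell type '%s' missing one condition; skipped", tp))
      return(NULL)
    }
    a <- sum(loy[sel] & is_case[sel]);  b <- sum(!loy[sel] & is_case[sel])
    cc <- sum(loy[sel] & !is_case[sel]); d <- sum(!loy[sel] & !is_case[sel])
    tab <- matrix(c(a, cc, b, d), 2)
    ft <- fisher.test(tab, conf.level = conf_level)
    or <- unname(ft$estimate); ci <- ft$conf.int; method <- "conditional_mle"
    if (!is.finite(or) || or == 0) {
      w <- woolf_or_ci(a, b, cc, d, conf_level)
      or <- unname(w["or"]); ci <- c(w["lo"], w["hi"])
      method <- "woolf_haldane"
    }
    samp <- if (b * cc > 0) (a * d) / (b * cc) else NA_real_
    data.frame(cell_type = tp, a = a, b = b, c = cc, d = d,
               sample_or = samp, odds_ratio = or, ci_low = ci[1],
               ci_high = ci[2], or_method = method, p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(out)
  out$q_value <- bh_adjust(out$p_value)
  out$stars <- star_marks(out$p_value)
  rownames(out) <- NULL
  out
}

#' Percent LOY per group with exact binomial confidence intervals
#'
#' Summarizes LOY calls by any grouping (donor, cell type, lineage,
#' condition, or combinations): counts, percent LOY, and the Clopper-Pearson
#' exact binomial interval.  Empty groups are dropped; groups with zero LOY
#' cells get a one-sided upper bound.
#'
#' @param calls output of [call_loy()].
#' @param groups data.frame (or vector) of grouping variables aligned with
#'   `calls`.
#' @param conf_level CI level.
#' @return data.frame with grouping columns plus `n_cells`, `n_loy`,
#'   `percent_loy`, `ci_low`, `ci_high` (percent scale).
#' @export
loy_fraction_summary <- function(calls, groups, conf_level = 0.95) {
  if (!is.data.frame(groups)) groups <- data.frame(group = groups)
  stopifnot(nrow(groups) == nrow(calls))
  keep <- !is.na(calls$is_loy)
  loy <- calls$is_loy[keep]
  groups <- groups[keep, , drop = FALSE]
  key <- interaction(groups, drop = TRUE, sep = "\r")
  idx <- split(seq_along(loy), key)
  rows <- lapply(idx, function(ix) {
    n <- length(ix); k <- sum(loy[ix])
    ci <- binom.test(k, n, conf.level = conf_level)$conf.int
    cbind(groups[ix[1], , drop = FALSE],
          data.frame(n_cells = n, n_loy = k, percent_loy = 100 * k / n,
                     ci_low = 100 * ci[1], ci_high = 100 * ci[2]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
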