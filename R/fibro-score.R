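#' Binned-control gene-module score per cell
#'
#' The module score of a gene set in a cell is the mean normalized (log1p)
#' expression of the set genes minus the mean of a pool of control genes
#' matched on overall expression level: all genes are ranked by their
#' average normalized expression and cut into `n_bins` equal-frequency bins;
#' for each set gene, `n_ctrl` control genes are sampled with replacement
#' from its bin, and the pooled controls form the reference.  The
#' subtraction removes cell-level technical scale, so adding a constant to
#' every gene's normalized expression leaves every score unchanged, and the
#' expected score of a random set is zero.  Deterministic given `seed`.
#'
#' @param dataset a [cell_dataset()] or a pre-computed normalized matrix
#'   (genes x cells).
#' @param gene_set character vector of gene identifiers; at least one must
#'   be present in the matrix.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes sampled per set gene (default 100).
#' @param seed integer seed for control sampling.
#' @return data.frame: `cell_id`, `score`, with attribute `"controls"`
#'   (the sampled control gene pool) and `"set_genes"` (set genes used).
#' @export
module_score <- function(dataset, gene_set, n_bins = 24, n_ctrl = 100, seed) {
  norm <- if (inherits(dataset, "CellDataset")) lognorm_matrix(dataset)
          else dataset
  present <- intersect(gene_set, rownames(norm))
  if (length(present) == 0L)
    stop("no gene of the set is present in the expression matrix")
  avg <- Matrix::rowMeans(norm)
  n_bins_eff <- min(n_bins, length(avg))
  bin <- as.integer(cut(rank(avg, ties.method = "first"),
                        breaks = n_bins_eff, labels = FALSE,
                        include.lowest = TRUE))
  names(bin) <- rownames(norm)
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- names(bin)[bin == bin[g]]
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }))
  })
  set_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  out <- data.frame(cell_id = colnames(norm),
                    score = as.numeric(set_mean - ctrl_mean),
                    stringsAsFactors = FALSE)
  attr(out, "controls") <- ctrl
  attr(out, "set_genes") <- present
  out
}

#' LOY-vs-WT module-score comparison within groups
#'
#' Two-sample t test of module scores between LOY and WT cells within each
#' group (typically leukocyte lineages), with Bonferroni correction over the
#' number of groups tested.  Student's pooled-variance t is used by default;
#' if either arm has (near-)zero variance the Welch form is used and
#' annotated.
#'
#' @param scores data.frame from [module_score()] (aligned with `calls`).
#' @param calls output of [call_loy()].
#' @param groups character/factor of group labels aligned with `calls`.
#' @param min_cells minimum cells per arm per group.
#' @return data.frame: `group`, `n_loy`, `n_wt`, `mean_loy`, `mean_wt`,
#'   `t_statistic`, `p_value`, `p_adjusted` (Bonferroni), `method`.
#' @export
score_group_test <- function(scores, calls, groups, min_cells = 2) {
  stopifnot(nrow(scores) == nrow(calls), length(groups) == nrow(calls))
  keep <- !is.na(calls$is_loy) & !is.na(groups)
  s <- scores$score[keep]; loy <- calls$is_loy[keep]; g <- groups[keep]
  res <- lapply(sort(unique(as.character(g))), function(gr) {
    sl <- s[g == gr & loy]; sw <- s[g == gr & !loy]
    if (length(sl) < min_cells || length(sw) < min_cells) return(NULL)
    degenerate <- var(sl) < 1e-12 || var(sw) < 1e-12
    tt <- tryCatch(
      t.test(sl, sw, var.equal = !degenerate),
      error = function(e) NULL)
    if (is.null(tt)) return(NULL)
    data.frame(group = gr, n_loy = length(sl), n_wt = length(sw),
               mean_loy = mean(sl), mean_wt = mean(sw),
               t_statistic = unname(tt$statistic), p_value = tt$p.value,
               method = if (degenerate) "welch" else "student",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(out)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}

#' Donor-level regression of fibroblast activation on percent LOY
#'
#' Ordinary least squares of a per-donor activation score (mean module score
#' among fibroblasts) on the donor's percent of LOY leukocytes, with the
#' two-sided slope test.  Optionally weighted by donor cell counts.
#'
#' @param per_donor data.frame with columns `percent_loy` and `score`
#'   (one row per donor); an optional `weight` column is used when
#'   `weighted = TRUE`.
#' @param weighted weight donors by `weight` (e.g. fibroblast cell count).
#' @return list of class `ActivationRegression`: `slope`, `intercept`,
#'   `slope_se`, `r_squared`, `p_value`, `n_donors`, `fit` (the `lm`).
#' @export
loy_activation_regression <- function(per_donor, weighted = FALSE) {
  stopifnot(all(c("percent_loy", "score") %in% names(per_donor)))
  per_donor <- per_donor[complete.cases(per_donor[c("percent_loy", "score")]), ]
  if (nrow(per_donor) < 3L) stop("need >= 3 donors")
  if (var(per_donor$percent_loy) == 0)
    stop("zero variance in percent LOY: slope undefined")
  w <- if (weighted) per_donor$weight else NULL
  fit <- lm(score ~ percent_loy, data = per_donor, weights = w)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n_donors = nrow(per_donor), fit = fit),
            class = "ActivationRegression")
}

#' @export
print.ActivationRegression <- function(x, ...) {
  cat(sprintf(paste0("Activation ~ %%LOY over %d donors: slope %.4g ",
                     "(se %.3g), R^2 = %.3f, p = %.3g\n"),
              x$n_donors, x$slope, x$slope_se, x$r_squared, x$p_value))
  invisible(x)
}
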