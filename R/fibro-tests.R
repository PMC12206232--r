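#' Detection-odds test of a gene between LOY and WT cells, per condition
#'
#' Within each condition, models whether a cell expresses the gene (count
#' > 0) against its LOY status by logistic regression and reports the
#' likelihood-ratio p-value of the LOY term (deviance difference of the
#' nested models on 1 df) and the LOY effect on the odds scale.  Complete
#' separation (a zero cell in the detection x LOY table) is handled by a
#' Haldane-Anscombe 0.5 correction of the odds ratio and annotated.
#'
#' @param dataset a [cell_dataset()].
#' @param calls output of [call_loy()] (depth filter applied if present).
#' @param gene gene identifier, must be in the matrix.
#' @param conditions character vector aligned with `calls`.
#' @param which_conditions conditions to test (default all present).
#' @return data.frame: `condition`, `gene`, `n_loy`, `n_wt`, `det_loy`,
#'   `det_wt`, `odds_ratio`, `lr_statistic`, `p_value`, `penalized`.
#' @export
expression_condition_test <- function(dataset, calls, gene, conditions,
                                      which_conditions = NULL) {
  if (!gene %in% rownames(dataset$counts))
    stop(sprintf("gene '%s' not present in the matrix", gene))
  stopifnot(length(conditions) == nrow(calls))
  if (is.null(which_conditions))
    which_conditions <- sort(unique(conditions[!is.na(conditions)]))
  detected <- as.numeric(
    dataset$counts[gene, match(calls$cell_id, colnames(dataset$counts))]) > 0
  use <- !is.na(calls$is_loy)
  if (!is.null(calls$depth_pass)) use <- use & calls$depth_pass
  res <- lapply(which_conditions, function(cd) {
    sel <- use & conditions == cd
    y <- detected[sel]; x <- calls$is_loy[sel]
    if (length(unique(x)) < 2L) return(NULL)
    fit1 <- glm(y ~ x, family = stats::binomial())
    fit0 <- glm(y ~ 1, family = stats::binomial())
    lr <- fit0$deviance - fit1$deviance
    p <- pchisq(lr, df = 1, lower.tail = FALSE)
    a <- sum(y & x); b <- sum(!y & x); cc <- sum(y & !x); d <- sum(!y & !x)
    sep <- any(c(a, b, cc, d) == 0)
    or <- if (sep) unname(woolf_or_ci(a, b, cc, d)["or"])
          else unname(exp(coef(fit1)[2]))
    data.frame(condition = cd, gene = gene, n_loy = sum(x), n_wt = sum(!x),
               det_loy = mean(y[x]), det_wt = mean(y[!x]), odds_ratio = or,
               lr_statistic = lr, p_value = p, penalized = sep,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric tail test per gene set: the probability of
#' observing at least the realized overlap between the query genes and the
#' set, drawing `|query|` genes from the universe.  Sets are intersected
#' with the universe first; the query must be contained in the universe.
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param query_genes character vector of genes of interest.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all testable genes.
#' @return data.frame: `set`, `set_size`, `overlap`, `expected`,
#'   `fold_enrichment`, `p_value`, `q_value`, sorted by p.
#' @export
ora <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query_genes)
  if (!all(query %in% universe))
    stop("query genes must be contained in the universe")
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    m <- length(set); k <- length(intersect(query, set))
    N <- length(universe); n <- length(query)
    expected <- n * m / N
    p <- if (m == 0) 1 else phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, overlap = k, expected = expected,
               fold_enrichment = if (expected > 0) k / expected else 0,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  out
}
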