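# construct a small dataset with controlled QC metadata: many singleton
# genes set the expressed-gene count, one mito gene sets the mito fraction
qc_toy <- function() {
  genes <- c("MT-CO1", sprintf("G%04d", 1:2500), "RPS4Y1")
  m <- matrix(0L, length(genes), 4,
              dimnames = list(genes, c("mito_high", "few_genes", "ok", "loy")))
  m[1 + (1:2000), "mito_high"] <- 1L   # 2000 expressed + mito
  m["MT-CO1", "mito_high"] <- 267L     # 267 / 2268 = 11.8% mito
  m[1 + (1:699), "few_genes"] <- 1L    # 700 expressed genes with MT
  m["MT-CO1", "few_genes"] <- 10L
  m[1 + (1:2000), "ok"] <- 1L
  m["MT-CO1", "ok"] <- 100L            # 100 / 2101 = 4.8% mito
  m["RPS4Y1", "ok"] <- 2L
  m[1 + (1:2000), "loy"] <- 1L
  m["MT-CO1", "loy"] <- 50L
  cell_dataset(m, msy_genes = "RPS4Y1")
}

test_that("cell QC applies the mito and expressed-gene windows", {
  ds <- qc_toy()
  qc <- qc_filter_cells(ds)
  expect_identical(qc$qc_pass,
                   c(mito_high = FALSE, few_genes = FALSE, ok = TRUE,
                     loy = TRUE)[qc$cell_id] |> unname())
  expect_match(qc$qc_reasons[qc$cell_id == "mito_high"], "mito")
  expect_match(qc$qc_reasons[qc$cell_id == "few_genes"], "low_genes")
  expect_identical(qc$qc_reasons[qc$cell_id == "ok"], "")
  # boundary: exactly 800 expressed genes and exactly 10% mito pass
  qc2 <- qc_filter_cells(ds, genes_min = 2001, mito_max = 100 / 2101)
  expect_true(qc2$qc_pass[qc2$cell_id == "ok"])
})

test_that("depth gate for functional analyses is strictly greater-than", {
  m <- matrix(c(4001L, 4000L, 0L), 1, dimnames = list("G1", c("a", "b", "c")))
  ds <- cell_dataset(rbind(m, RPS4Y1 = c(0L, 0L, 0L)), msy_genes = "RPS4Y1")
  calls <- qc_filter_depth(ds, data.frame(cell_id = c("a", "b", "c")))
  expect_identical(calls$depth_pass, c(TRUE, FALSE, FALSE))
})

test_that("LOY calling requires complete MSY absence among QC-passing cells", {
  ds <- qc_toy()
  calls <- call_loy(ds)
  expect_identical(calls$is_loy[calls$cell_id == "loy"], TRUE)
  expect_identical(calls$is_loy[calls$cell_id == "ok"], FALSE)  # 2 transcripts
  expect_true(is.na(calls$is_loy[calls$cell_id == "mito_high"]))
  expect_equal(calls$msy_total[calls$cell_id == "ok"], 2)
  # a single MSY transcript is enough to be wild-type
  one <- qc_toy()
  one$counts["RPS4Y1", "loy"] <- 1
  expect_identical(call_loy(one)$is_loy[calls$cell_id == "loy"], FALSE)
  # empty MSY set is a configuration error
  noset <- cell_dataset(matrix(1L, 2, 2, dimnames = list(c("A", "B"),
                                                         c("c1", "c2"))),
                        msy_genes = character(0))
  expect_error(call_loy(noset), "MSY gene set is empty")
})

test_that("marker annotation is hierarchical with deterministic ties", {
  genes <- c("PTPRC", "CD68", "CDH5", "EPCAM", "PDGFRA", "ACTA2", "CD3G",
             "MRC1", "IL1B")
  m <- matrix(0L, length(genes), 3,
              dimnames = list(genes, c("mac", "fib", "tie")))
  m[c("PTPRC", "CD68"), "mac"] <- 20L
  m["PDGFRA", "fib"] <- 20L
  m[, "tie"] <- 1L                       # all markers equal
  ds <- cell_dataset(m, msy_genes = "RPS4Y1")
  ann <- suppressWarnings(annotate_cell_types(ds))
  expect_identical(ann$major_type[ann$cell_id == "mac"], "leukocyte")
  expect_identical(ann$lineage[ann$cell_id == "mac"], "macrophage")
  expect_identical(ann$major_type[ann$cell_id == "fib"], "fibroblast")
  # lexicographic tie-break over major labels
  expect_identical(ann$major_type[ann$cell_id == "tie"], "endothelial")
})

test_that("marker annotation recovers synthetic types at 4x effect size", {
  sim <- gen_sc_cohort(c(IPF = 2), cells_per_donor = 400,
                       marker_strength = 4, seed = 17)
  ann <- annotate_cell_types(sim$dataset)
  called <- ifelse(is.na(ann$lineage), ann$major_type, ann$lineage)
  expect_gt(mean(called == sim$truth$cell_type), 0.95)
})

test_that("per-type enrichment matches the sample odds ratio and exact p", {
  calls <- data.frame(cell_id = sprintf("c%03d", 1:200),
                      qc_pass = TRUE,
                      is_loy = c(rep(TRUE, 10), rep(FALSE, 90),
                                 rep(TRUE, 2), rep(FALSE, 98)))
  cond <- rep(c("IPF", "control"), each = 100)
  res <- loy_enrichment_by_type(calls, rep("macrophage", 200), cond)
  expect_equal(res$sample_or, (10 * 98) / (90 * 2), tolerance = 1e-12)
  expect_equal(res$p_value, oracle_fisher_p(10, 90, 2, 98), tolerance = 1e-12)
  expect_true(res$ci_low <= res$odds_ratio & res$odds_ratio <= res$ci_high)
  expect_identical(res$stars, "*")
  # balanced identical tables: OR estimate 1, p = 1
  calls2 <- data.frame(cell_id = sprintf("d%03d", 1:40), qc_pass = TRUE,
                       is_loy = rep(c(TRUE, FALSE, TRUE, FALSE),
                                    times = c(5, 15, 5, 15)))
  res2 <- loy_enrichment_by_type(calls2, rep("T_cell", 40),
                                 rep(c("IPF", "control"), each = 20))
  expect_equal(res2$p_value, 1)
  expect_equal(res2$sample_or, 1)
  # zero cells fall back to annotated Woolf interval
  calls3 <- data.frame(cell_id = sprintf("e%03d", 1:60), qc_pass = TRUE,
                       is_loy = rep(c(TRUE, FALSE, FALSE),
                                    times = c(6, 24, 30)))
  res3 <- loy_enrichment_by_type(calls3, rep("NK_cell", 60),
                                 rep(c("IPF", "control"), each = 30))
  expect_identical(res3$or_method, "woolf_haldane")
  expect_true(is.finite(res3$odds_ratio) && res3$odds_ratio > 1)
})

test_that("LOY fraction summaries carry exact binomial intervals", {
  calls <- data.frame(cell_id = sprintf("c%02d", 1:70), qc_pass = TRUE,
                      is_loy = rep(c(TRUE, FALSE, FALSE),
                                   times = c(5, 45, 20)))
  g <- rep(c("A", "B"), times = c(50, 20))
  s <- loy_fraction_summary(calls, g)
  expect_equal(s$percent_loy[s$group == "A"], 10)
  ciA <- binom.test(5, 50)$conf.int
  expect_equal(s$ci_low[s$group == "A"], 100 * ciA[1])
  expect_equal(s$percent_loy[s$group == "B"], 0)
  expect_equal(s$ci_low[s$group == "B"], 0)
  expect_gt(s$ci_high[s$group == "B"], 0)
  # synthetic per-type fractions recovered within the binomial interval
  lf <- data.frame(condition = c("IPF", "IPF"),
                   cell_type = c("macrophage", "T_cell"),
                   loy_frac = c(0.25, 0.05))
  sim <- gen_sc_cohort(c(IPF = 2), cells_per_donor = 500, loy_frac = lf,
                       seed = 23)
  cl <- call_loy(sim$dataset)
  fr <- loy_fraction_summary(cl, sim$truth$cell_type)
  for (tp in c("macrophage", "T_cell")) {
    truth <- 100 * lf$loy_frac[lf$cell_type == tp]
    row <- fr[fr$group == tp, ]
    expect_true(row$ci_low <= truth && truth <= row$ci_high)
  }
})
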