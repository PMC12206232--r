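# toy expression dataset: identical non-MSY expression (and total depth) in
# LOY and WT cells; LOY status driven purely by the MSY gene, with a PAD
# gene keeping depths equal across arms
dge_toy <- function(n_per_arm = 25) {
  genes <- c("RPS4Y1", "PAD", sprintf("G%02d", 1:8))
  n <- 2 * n_per_arm
  m <- matrix(0L, length(genes), n,
              dimnames = list(genes, sprintf("c%03d", 1:n)))
  for (g in 3:10) m[g, ] <- 600L         # identical across all cells
  m["RPS4Y1", seq_len(n_per_arm)] <- 5L  # WT arm
  m["PAD", n_per_arm + seq_len(n_per_arm)] <- 5L
  cell_dataset(m, msy_genes = "RPS4Y1")
}

test_that("DGE is null on identical groups and flags MSY genes", {
  ds <- dge_toy()
  calls <- qc_filter_depth(ds, call_loy(ds, data.frame(
    cell_id = ds$cells$cell_id, qc_pass = TRUE)), min_reads = 100)
  res <- dge_loy_vs_wt(ds, calls, min_cells = 10)
  non_msy <- res[grepl("^G", res$gene), ]
  expect_true(all(non_msy$p_value == 1))
  expect_true(all(abs(non_msy$log2fc) < 1e-12))
  expect_true(all(res$log2fc[res$is_msy] < 0))   # LOY-defining genes go down
  # too few cells is a skip, not an error
  expect_message(
    expect_null(dge_loy_vs_wt(ds, calls, min_cells = 1000)), "skipping")
})

test_that("small-sample rank-sum p matches brute-force enumeration", {
  set.seed(31)
  for (i in 1:12) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    x <- sample(0:4, m, replace = TRUE)   # heavy ties on purpose
    y <- sample(0:4, n, replace = TRUE)
    expect_equal(ranksum_test(x, y)$p_value, oracle_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("normalization contract: rank-based p unaffected by library size", {
  ds <- dge_toy()
  set.seed(7)
  ds$counts[2:9, ] <- matrix(rpois(8 * 50, 500), 8, 50)
  calls <- qc_filter_depth(ds, call_loy(ds, data.frame(
    cell_id = ds$cells$cell_id, qc_pass = TRUE)), min_reads = 100)
  r1 <- dge_loy_vs_wt(ds, calls, min_cells = 10, scale = 1e4)
  r2 <- dge_loy_vs_wt(ds, calls, min_cells = 10, scale = 1e6)
  expect_equal(r1$p_value, r2$p_value[match(r1$gene, r2$gene)],
               tolerance = 1e-12)
})

test_that("module score matches a hand computation on a toy", {
  # 6 genes in 2 expression bins; genes within a bin have identical
  # expression in every cell, so the control pool mean is deterministic
  # regardless of which control genes are sampled: for the set {H1, L1} it
  # is (h_c + l_c)/2 per cell, exactly the set mean, and the hand-computed
  # score is 0.  Any mis-binning (e.g. L1 controls drawn from the high bin)
  # would produce nonzero scores.
  m <- matrix(0, 6, 3, dimnames = list(c("L1", "L2", "L3", "H1", "H2", "H3"),
                                       c("c1", "c2", "c3")))
  m[1:3, ] <- rep(c(1, 2, 4), each = 3)     # low bin: value l_c per cell
  m[4:6, ] <- rep(c(50, 60, 80), each = 3)  # high bin: value h_c per cell
  sc <- module_score(m, c("H1", "L1"), n_bins = 2, n_ctrl = 10, seed = 1)
  expect_equal(sc$score, c(0, 0, 0), tolerance = 1e-12)
  ctrl <- attr(sc, "controls")
  expect_length(ctrl, 20)
  expect_true(all(ctrl[1:10] %in% c("H1", "H2", "H3")))
  expect_true(all(ctrl[11:20] %in% c("L1", "L2", "L3")))
})

test_that("module scores are shift-invariant, seeded, and self-centred", {
  set.seed(12)
  norm <- matrix(rexp(300, 1), 30, 10,
                 dimnames = list(sprintf("g%02d", 1:30),
                                 sprintf("c%02d", 1:10)))
  set_genes <- c("g03", "g11", "g25")
  s1 <- module_score(norm, set_genes, n_bins = 5, n_ctrl = 20, seed = 9)
  # bit-reproducible under the same seed
  expect_identical(s1, module_score(norm, set_genes, n_bins = 5, n_ctrl = 20,
                                    seed = 9))
  # additive shift leaves every score unchanged
  s2 <- module_score(norm + 3.7, set_genes, n_bins = 5, n_ctrl = 20, seed = 9)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
  # self-control: expected score of the all-genes set is 0
  means <- vapply(1:200, function(sd)
    mean(module_score(norm, rownames(norm), n_bins = 5, n_ctrl = 5,
                      seed = sd)$score), numeric(1))
  expect_lt(abs(mean(means)), 0.02)
  # score variability shrinks as the control pool grows
  cell_scores <- function(nc) vapply(1:30, function(sd)
    module_score(norm, set_genes, n_bins = 5, n_ctrl = nc, seed = sd)$score[1],
    numeric(1))
  expect_gt(var(cell_scores(2)), var(cell_scores(50)))
  expect_error(module_score(norm, "absent_gene", seed = 1), "no gene")
})

test_that("group score test: null, power, and Bonferroni", {
  calls <- data.frame(cell_id = sprintf("c%03d", 1:400),
                      is_loy = rep(c(TRUE, FALSE), 200))
  set.seed(41)
  base <- rnorm(400)
  scores <- data.frame(cell_id = calls$cell_id, score = base)
  # identical distributions: same values in both arms -> t = 0, p = 1
  scores_null <- scores; scores_null$score <- rep(rnorm(200), each = 2)
  res0 <- score_group_test(scores_null, calls, rep("mac", 400))
  expect_equal(res0$p_value, 1)
  expect_equal(res0$t_statistic, 0)
  # a 1-sd shift at n = 200/arm: closed-form power exceeds 0.99...
  ncp <- 1 * sqrt(200 * 200 / 400)
  power <- 1 - (pt(qt(0.975, 398), 398, ncp) - pt(qt(0.025, 398), 398, ncp))
  expect_gt(power, 0.99)
  # ...and the observed test rejects
  scores$score <- base + calls$is_loy * 1
  res1 <- score_group_test(scores, calls, rep("mac", 400))
  expect_lt(res1$p_value, 0.001)
  # Bonferroni is definitional over the number of groups tested
  g3 <- rep(c("a", "b", "c"), length.out = 400)
  res3 <- score_group_test(scores, calls, g3)
  expect_equal(res3$p_adjusted, pmin(1, res3$p_value * 3))
})

test_that("detection-odds LR test matches a from-scratch IRLS fit", {
  set.seed(55)
  n <- 100
  loy <- rep(c(TRUE, FALSE), each = n / 2)
  det <- rbinom(n, 1, ifelse(loy, 0.7, 0.35))
  counts <- matrix(0L, 2, n, dimnames = list(c("FN1", "RPS4Y1"),
                                             sprintf("c%03d", 1:n)))
  counts["FN1", ] <- as.integer(det * 3)
  counts["RPS4Y1", ] <- as.integer(!loy)
  ds <- cell_dataset(counts, msy_genes = "RPS4Y1")
  calls <- data.frame(cell_id = ds$cells$cell_id, qc_pass = TRUE,
                      is_loy = loy)
  res <- expression_condition_test(ds, calls, "FN1", rep("IPF", n))
  X <- cbind(1, loy)
  fit1 <- oracle_logistic(X, det)
  fit0 <- oracle_logistic(X[, 1, drop = FALSE], det)
  expect_equal(res$lr_statistic, fit0$deviance - fit1$deviance,
               tolerance = 1e-8)
  expect_equal(res$odds_ratio, unname(exp(fit1$beta[2])), tolerance = 1e-6)
  # equal detection rates: LR ~ 0
  det_eq <- rep(c(1L, 0L), n / 2)
  counts["FN1", ] <- det_eq
  ds2 <- cell_dataset(counts, msy_genes = "RPS4Y1")
  res2 <- expression_condition_test(ds2, calls, "FN1", rep("IPF", n))
  expect_lt(res2$lr_statistic, 1e-8)
})

test_that("detection-odds effect is recovered at its generating value", {
  set.seed(67)
  n <- 1000
  loy <- rep(c(TRUE, FALSE), each = n / 2)
  det <- rbinom(n, 1, ifelse(loy, 0.6, 0.3))
  counts <- matrix(0L, 2, n, dimnames = list(c("SPP1", "RPS4Y1"),
                                             sprintf("c%04d", 1:n)))
  counts["SPP1", ] <- as.integer(det)
  counts["RPS4Y1", ] <- as.integer(!loy)
  ds <- cell_dataset(counts, msy_genes = "RPS4Y1")
  calls <- data.frame(cell_id = ds$cells$cell_id, qc_pass = TRUE,
                      is_loy = loy)
  res <- expression_condition_test(ds, calls, "SPP1", rep("IPF", n))
  # generating odds ratio (0.6/0.4)/(0.3/0.7) = 3.5
  expect_equal(log(res$odds_ratio), log(3.5), tolerance = 0.25)
  expect_lt(res$p_value, 1e-10)
})

test_that("over-representation matches direct tail summation", {
  # universe 1000, set 50, query 100, overlap 20
  universe <- sprintf("u%04d", 1:1000)
  set50 <- universe[1:50]
  query <- c(universe[1:20], universe[501:580])
  res <- ora(query, list(S = set50), universe)
  manual <- sum(choose(50, 20:50) * choose(950, 100 - (20:50))) /
    choose(1000, 100)
  expect_equal(res$p_value, manual, tolerance = 1e-10)
  expect_equal(res$fold_enrichment, (20 / 100) / (50 / 1000))
  # query equals the whole universe-set: boundary p = 1
  res_full <- ora(set50, list(S = set50), set50)
  expect_equal(res_full$p_value, 1)
  # disjoint query and set: fold enrichment 0, p = 1
  res_dis <- ora(universe[900:999], list(S = set50), universe)
  expect_equal(res_dis$overlap, 0)
  expect_equal(res_dis$p_value, 1)
  expect_error(ora("g", list(S = "g"), character(0)), "empty universe")
})

test_that("BH q-values are monotone in sorted p-values", {
  set.seed(3)
  p <- runif(200)^2
  q <- mloykit:::bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_true(all(q >= p - 1e-15))
})

test_that("activation regression behaves on exact and noisy donors", {
  exact <- data.frame(percent_loy = c(0, 10, 20, 30),
                      score = 0.1 + 0.02 * c(0, 10, 20, 30))
  fit <- suppressWarnings(loy_activation_regression(exact))  # perfect fit
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.02)
  # invariant to donor order
  fit2 <- suppressWarnings(loy_activation_regression(exact[c(3, 1, 4, 2), ]))
  expect_equal(fit2$slope, fit$slope)
  expect_error(loy_activation_regression(exact[1:2, ]), ">= 3 donors")
  flat <- data.frame(percent_loy = rep(5, 4), score = rnorm(4))
  expect_error(loy_activation_regression(flat), "zero variance")
})
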