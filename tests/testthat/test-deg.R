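log2_expr <- function(m) {
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(ncol(m))))
  expr_matrix(m, "log2")
}

test_that("two-group statistics obey their closed-form definitions", {
  set.seed(3)
  x <- matrix(rnorm(40, 8), 4, 10)
  m <- log2_expr(cbind(x, x))            # group B duplicates group A
  a <- colnames(m)[1:10]; b <- colnames(m)[11:20]
  gs <- gene_statistics(m, a, b)
  expect_equal(gs$t_stat, rep(0, 4))
  expect_equal(gs$lmr_stat, rep(0, 4))
  expect_equal(gs$fold_change, rep(1, 4))

  # linear medians 8 vs 2 -> log2-median-ratio = 2
  m2 <- log2_expr(matrix(log2(c(rep(8, 3), rep(2, 3))), 1, 6))
  gs2 <- gene_statistics(m2, colnames(m2)[1:3], colnames(m2)[4:6])
  expect_equal(gs2$lmr_stat, 2)

  # log2 group means 5 vs 3 -> fold change 4
  m3 <- log2_expr(matrix(c(4.5, 5.5, 5, 2.5, 3.5, 3), 1, 6))
  gs3 <- gene_statistics(m3, colnames(m3)[1:3], colnames(m3)[4:6])
  expect_equal(gs3$fold_change, 4)
  expect_equal(gs3$abs_fc, 4)

  expect_error(gene_statistics(m, a, a), "disjoint")
  expect_error(gene_statistics(m, a[1], b), ">= 2 samples")
})

test_that("swapping the groups flips signs but preserves |FC| and p-values", {
  sc <- small_cohort()
  sub <- expr_matrix(unclass(sc$logm)[1:60, ], "log2")
  a <- sc$tumors[1:12]; b <- sc$normals[1:10]
  r1 <- deg_test(sub, a, b, B = 120, seed = 5)
  r2 <- deg_test(sub, b, a, B = 120, seed = 5)
  expect_equal(r2$t_stat, -r1$t_stat)
  expect_equal(r2$lmr_stat, -r1$lmr_stat)
  expect_equal(r2$fold_change, 1 / r1$fold_change)
  expect_equal(r2$abs_fc, r1$abs_fc)
  expect_identical(r2$p_t, r1$p_t)
  expect_identical(r2$p_lmr, r1$p_lmr)
  expect_identical(r2$p_combined, r1$p_combined)
})

test_that("the permutation p-value convention and enumeration behave as defined", {
  # observed above the whole pool: p = 1/(1 + pool size)
  expect_equal(permutation_pvalue(10, c(1, 2, 3)), 1 / 4)
  # observed below the whole pool: p = 1
  expect_equal(permutation_pvalue(0.5, c(1, 2, 3)), 1)
  # ties count as >= observed
  expect_equal(permutation_pvalue(2, c(1, 2, 3)), 3 / 4)

  # tiny two-group design: B above the number of distinct arrangements
  # triggers exact enumeration; the identity arrangement contributes the
  # observed statistic itself, so no p-value can reach the 1/(1+pool) floor
  set.seed(8)
  m <- log2_expr(matrix(rnorm(5 * 6, 8), 5, 6))
  pv <- permutation_null_pvalues(m, colnames(m)[1:3], colnames(m)[4:6],
                                 B = 1000, seed = 1)
  expect_equal(pv$pool_size, 5 * choose(6, 3))
  expect_true(all(pv$p_t >= 2 / (1 + pv$pool_size)))
  expect_true(all(pv$p_t <= 1))
  expect_error(permutation_null_pvalues(m, colnames(m)[1:3], colnames(m)[4:6],
                                        B = 50), ">= 100")
})

test_that("Stouffer combination matches its closed form and direction rules", {
  # two concordant p = 0.5 results reinforce each other slightly:
  # z = qnorm(0.75) = 0.6745 each, z_comb = 0.9539, two-sided p = 0.3401
  expect_equal(stouffer_combine(0.5, 0.5, 1, 1),
               2 * pnorm(-2 * qnorm(0.75) / sqrt(2)), tolerance = 1e-10)
  expect_equal(stouffer_combine(0.5, 0.5, 1, 1), 0.3401482, tolerance = 1e-6)
  # p = (0.05, 0.05), same direction: z = 1.959964, z_comb = 2.771808
  expect_equal(stouffer_combine(0.05, 0.05, 1, 1), 0.005574597, tolerance = 1e-7)
  expect_equal(stouffer_combine(0.05, 0.05, 1, 1),
               2 * pnorm(-2 * qnorm(1 - 0.05 / 2) / sqrt(2)),
               tolerance = 1e-10)
  # equal evidence in opposite directions cancels exactly
  expect_equal(stouffer_combine(0.01, 0.01, 1, -1), 1)
  # monotone: decreasing either input p never increases the combined p
  p_grid <- c(0.5, 0.2, 0.05, 0.01, 0.001)
  comb <- outer(p_grid, p_grid,
                Vectorize(function(p, q) stouffer_combine(p, q, 1, 1)))
  expect_true(all(diff(comb) <= 1e-12))        # rows: first p decreasing
  expect_true(all(apply(comb, 1, diff) <= 1e-12))
  expect_warning(stouffer_combine(0, 0.5, 1, 1), "clamped")
})

test_that("DEG selection applies strict thresholds and nests monotonically", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    t_stat = 1, lmr_stat = 1,
                    fold_change = c(2.5, 2.0, 3.0, 0.25),
                    abs_fc = c(2.5, 2.0, 3.0, 4.0),
                    p_t = 0.01, p_lmr = 0.01,
                    p_combined = c(0.01, 0.01, 0.05, 0.001))
  sel <- select_degs(res, fc_min = 2, p_max = 0.05)
  expect_identical(sel$gene, c("d", "a"))      # |FC| desc; b and c at strict
  expect_false("b" %in% sel$gene)              # |FC| = 2 exactly is dropped
  expect_false("c" %in% sel$gene)              # p = 0.05 exactly is dropped
  loose <- select_degs(res, fc_min = 1.5, p_max = 0.1)
  expect_true(all(sel$gene %in% loose$gene))   # threshold nesting
})

test_that("planted tumor-vs-normal DEGs are recovered on the synthetic cohort", {
  sc <- small_cohort()
  deg <- small_cohort_deg()
  sel <- select_degs(deg, fc_min = 2, p_max = 0.01)
  planted <- c(sc$truth$deg_up, sc$truth$deg_down)
  sens <- mean(planted %in% sel$gene)
  fdr <- mean(!(sel$gene %in% planted))
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})
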