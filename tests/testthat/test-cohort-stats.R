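test_that("cross-tabulation reproduces the published group-vs-CMS table", {
  labs <- reference_cohort_labels()
  ct <- cross_tabulate(setNames(labs$group, labs$sample_id),
                       setNames(labs$cms, labs$sample_id))
  ref <- reference_crosstab_counts()
  expect_equal(ct$counts, ref$counts)
  expect_equal(ct$undetermined, ref$undetermined)
  expect_equal(unname(ct$col_totals), unname(ref$group_sizes))
  expect_equal(ct$n_determined, 80L)
  expect_equal(sum(ct$undetermined), 21L)
  expect_equal(ct$n_total, 101L)
  # published row: CMS2 over groups 1..4 reads (3, 4, 0, 31), total 38
  expect_equal(unname(ct$counts["CMS2", ]), c(3L, 4L, 0L, 31L))
  expect_equal(sum(ct$counts["CMS2", ]), 38L)
})

test_that("cross-tabulation boundary cases behave", {
  ct <- cross_tabulate(c(1, 2, 1, 2), c("A", "B", "A", "B"))
  expect_equal(unname(diag(ct$counts)), c(2L, 2L))
  expect_equal(ct$n_determined, 4L)
  ct2 <- cross_tabulate(c(1, 2), rep("undetermined", 2))
  expect_equal(ct2$n_determined, 0L)
  expect_equal(unname(ct2$undetermined), c(1L, 1L))
  expect_error(cross_tabulate(c(a = 1, b = 2), c(a = "A", z = "B")),
               "same samples")
})

test_that("optimal matching maximizes agreement, matching an exhaustive oracle", {
  labs <- reference_cohort_labels()
  ct <- cross_tabulate(setNames(labs$group, labs$sample_id),
                       setNames(labs$cms, labs$sample_id))
  om <- optimal_match(ct)
  expect_equal(om$matched, 63L)
  expect_equal(om$determined, 80L)
  expect_equal(om$percent, 78.8)        # 63/80 under the printing convention
  expect_equal(om$mapping[["group1"]], "CMS3")
  expect_equal(om$mapping[["group2"]], "CMS1")
  expect_equal(om$mapping[["group3"]], "CMS4")
  expect_equal(om$mapping[["group4"]], "CMS2")

  # diagonal table: 100% matched
  d <- diag(c(5L, 3L, 7L)); dimnames(d) <- list(1:3, 1:3)
  expect_equal(optimal_match(d)$percent, 100)

  # random 4x4 tables vs an independent enumeration of all 24 mappings
  set.seed(14)
  for (rep in 1:5) {
    tab <- matrix(rpois(16, 6), 4, 4, dimnames = list(LETTERS[1:4], letters[1:4]))
    oracle <- max(vapply(all_perms(1:4),
                         function(p) sum(tab[cbind(p, 1:4)]), numeric(1)))
    expect_equal(optimal_match(tab)$matched, as.integer(oracle))
    # invariance under row/column permutation
    rp <- sample(4); cp <- sample(4)
    expect_equal(optimal_match(tab[rp, cp])$matched, as.integer(oracle))
    # dominance over the identity mapping
    expect_gte(oracle, sum(diag(tab)))
  }
})

test_that("association tests match brute-force oracles and printed conventions", {
  # chi-square equals sum (O-E)^2/E computed directly
  set.seed(15)
  for (rep in 1:5) {
    tab <- matrix(rpois(8, 10) + 1, 2, 4)
    at <- association_test(tab, method = "chi_square")
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(at$statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
    expect_equal(at$df, 3)
  }
  # identical group distributions: statistic 0, p = 1
  flat <- matrix(c(5, 5, 5, 5), 2, 2)
  at0 <- association_test(flat, method = "chi_square")
  expect_equal(at0$statistic, 0)
  expect_equal(at0$p, 1)
  # zero expected count is rejected with a pointer to Fisher
  bad <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  expect_error(association_test(bad, method = "chi_square"), "Fisher")
  # Fisher 2x2 (3,0 / 0,3): two-sided p = 2/choose(6,3) = 0.1
  expect_equal(association_test(rbind(c(3, 0), c(0, 3)),
                                method = "fisher_2x2")$p, 0.1)
  # rank tests accept numeric covariates by group
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  g <- rep(c("a", "b"), each = 4)
  kw <- association_test(x, g, method = "kruskal_wallis")
  mw <- association_test(x, g, method = "mann_whitney")
  expect_lt(kw$p, 0.05)
  expect_true(mw$p > 0 && mw$p <= 1)
  # auto selection: Fisher for a sparse 2x2, chi-square otherwise
  expect_message(association_test(rbind(c(2, 1), c(1, 2)), method = "auto"),
                 "fisher_2x2")
  expect_message(association_test(matrix(20, 2, 3), method = "auto"),
                 "chi_square")
})

test_that("percentages follow the half-away-from-zero printing convention", {
  expect_equal(percent(14, 22), 63.6)
  expect_equal(percent(31, 39), 79.5)
  expect_equal(percent(6, 21), 28.6)
  expect_equal(percent(0, 7), 0)
  expect_equal(percent(1, 16), 6.3)      # 6.25 rounds away from zero
  expect_equal(percent(1, 3, decimals = 0), 33)
  expect_error(percent(1, 0), "denominator")
})
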