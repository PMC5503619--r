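fake_set <- function(genes, fc) {
  data.frame(gene = genes, t_stat = 1, lmr_stat = 1, fold_change = fc,
             abs_fc = pmax(fc, 1 / fc), p_t = 0.001, p_lmr = 0.001,
             p_combined = 0.001, stringsAsFactors = FALSE)
}

test_that("marker candidates are the per-group intersection of the two upregulated sets", {
  vs_n <- list(g1 = fake_set(c("a", "b", "c"), c(3, 2.5, 4)),
               g2 = fake_set(c("d", "b"), c(2.2, 5)))
  vs_r <- list(g1 = fake_set(c("a", "x"), c(2.1, 3)),
               g2 = fake_set(c("d", "b"), c(2.8, 2.0)))
  cand <- suppressMessages(marker_candidates(vs_n, vs_r))
  # a: in both g1 sets -> kept; c: vs-normal only -> dropped; x: vs-rest only
  expect_true("a" %in% cand$gene[cand$group == "g1"])
  expect_false("c" %in% cand$gene)
  expect_false("x" %in% cand$gene)
  # b qualifies for g1 (not in vs_r$g1) -> only via g2; attribution is unique
  expect_equal(sum(cand$gene == "b"), 1)
  expect_equal(cand$group[cand$gene == "b"], "g2")
  # downregulated genes never qualify
  vs_n2 <- list(g1 = fake_set(c("dn"), 0.3))
  vs_r2 <- list(g1 = fake_set(c("dn"), 0.25))
  expect_equal(nrow(marker_candidates(vs_n2, vs_r2)), 0)
  expect_error(marker_candidates(vs_n, list(g1 = vs_r$g1)), "same groups")
})

test_that("top marker ranking reproduces the published panel ordering", {
  ref <- reference_marker_fcs()
  top <- top_markers(ref, fc_min = 1.5, n = 10)
  # every published row passes the 1.5-fold double filter
  expect_equal(nrow(top), 40)
  # group 3's strongest marker by group-vs-rest fold change is HOPX
  g3 <- top[top$group == "group3", ]
  expect_equal(g3$gene[g3$rank == 1], "HOPX")
  expect_equal(g3$fc_t_vs_n[g3$rank == 1], 4.26)
  expect_equal(g3$fc_group_vs_rest[g3$rank == 1], 4.11)
  # group 1 genes above 2.0-fold vs the other groups
  g1 <- top[top$group == "group1", ]
  expect_setequal(g1$gene[g1$fc_group_vs_rest > 2],
                  c("DEFA5", "DUOX2", "KLK12", "ALDOB"))
  # attribution is a partition
  expect_equal(anyDuplicated(top$gene), 0)
  # within-group ordering is by vs-rest fold change, descending
  for (g in unique(top$group))
    expect_true(all(diff(top$fc_group_vs_rest[top$group == g]) <= 0))
})

test_that("top marker filtering is strict and monotone in the threshold", {
  cand <- data.frame(gene = c("a", "b", "c"), group = "g1",
                     fc_t_vs_n = c(3, 1.4, 2), fc_group_vs_rest = c(1.4, 3, 2))
  suppressMessages({
    top <- top_markers(cand, fc_min = 1.5, n = 10)
    expect_equal(top$gene, "c")               # both-sided strict filter
    top2 <- top_markers(cand, fc_min = 2.5, n = 10)
  })
  expect_true(all(top2$gene %in% top$gene))   # raising fc_min never adds genes
})

test_that("planted subtype markers survive the candidate intersection on simulated data", {
  sc <- small_cohort()
  groups <- sc$truth$group
  gs <- as.character(1:4)
  suppressMessages({
    vs_n <- lapply(gs, function(g)
      group_degs(sc$logm, sc$annotation, groups, as.integer(g), "normal",
                 fc_min = 2, p_max = 0.05, B = 120, seed = 1))
    vs_r <- lapply(gs, function(g)
      group_degs(sc$logm, sc$annotation, groups, as.integer(g), "rest",
                 fc_min = 2, p_max = 0.05, B = 120, seed = 1))
    names(vs_n) <- names(vs_r) <- gs
    cand <- marker_candidates(vs_n, vs_r)
  })
  planted <- unlist(sc$truth$markers)
  n_planted <- length(planted)
  # candidate count within +/-20% of the planted marker count
  expect_gte(nrow(cand), 0.8 * n_planted)
  expect_lte(nrow(cand), 1.2 * n_planted)
  # and the candidates are overwhelmingly the planted markers, in the right group
  hit <- cand$gene %in% planted
  expect_gte(mean(hit), 0.9)
  planted_group <- rep(1:4, times = lengths(sc$truth$markers))
  names(planted_group) <- planted
  ok_group <- cand$group[hit] == planted_group[cand$gene[hit]]
  expect_gte(mean(ok_group), 0.95)
  # empty rest reference is rejected
  expect_error(group_degs(sc$logm, sc$annotation,
                          setNames(rep(1L, length(groups)), names(groups)),
                          1L, "rest"), "empty reference")
})

test_that("panel summaries report missing genes and planted marker calls", {
  sc <- small_cohort()
  panel <- c(sc$truth$markers[[2]][1:3], "NOT_A_GENE")
  suppressMessages(
    ps <- panel_summary(sc$logm, sc$annotation, sc$truth$group, panel,
                        fc_min = 1.5, p_max = 0.01, B = 120, seed = 3))
  expect_equal(ps$missing, "NOT_A_GENE")
  expect_false("NOT_A_GENE" %in% ps$calls$gene)
  # planted group-2 markers are called up vs rest in group 2
  calls2 <- ps$calls[ps$calls$group == 2 & ps$calls$mode == "vs_rest", ]
  expect_true(all(calls2$up))
  expect_error(panel_summary(sc$logm, sc$annotation, sc$truth$group,
                             character(0)), "empty panel")
})
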