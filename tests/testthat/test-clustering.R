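test_that("distance matrices obey their metric definitions", {
  m <- expr_matrix(matrix(c(1, 2, 3, 1, 2, 3, 3, 2, 1), 3, 3,
                          dimnames = list(paste0("g", 1:3), c("a", "b", "c"))),
                   "log2")
  d <- distance_matrix(m, "pearson", "samples")
  expect_equal(d["a", "b"], 0)                   # identical vectors
  expect_equal(d["a", "c"], 2)                   # perfectly anticorrelated
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_true(max(abs(d - t(d))) < 1e-12)

  m2 <- expr_matrix(matrix(c(0, 0, 3, 4), 2, 2,
                           dimnames = list(c("g1", "g2"), c("p", "q"))),
                    "linear")
  d2 <- distance_matrix(m2, "euclidean", "samples")
  expect_equal(d2["p", "q"], 5)

  m3 <- expr_matrix(matrix(c(1, 1, 1, 2, 5, 9), 3, 2,
                           dimnames = list(paste0("g", 1:3), c("flat", "x"))),
                    "linear")
  expect_error(distance_matrix(m3, "pearson", "samples"), "flat")
})

test_that("hierarchical clustering merges match a brute-force oracle", {
  # 3 points with distances (1, 1, 10): first merge joins the distance-1 pair
  d3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  hc3 <- hierarchical_cluster(d3, "complete")
  expect_equal(hc3$height[1], 1)
  expect_setequal(-hc3$merge[1, ], c(1, 2))
  # n = 2: single merge at the pairwise distance
  d2 <- matrix(c(0, 0.7, 0.7, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(hierarchical_cluster(d2, "complete")$height, 0.7)
  # random 8-leaf instances vs the oracle
  for (seed in 1:3) {
    d <- random_distance(8, seed)
    for (lk in c("complete", "average")) {
      hc <- hierarchical_cluster(d, lk)
      expect_equal(sort(hc$height), sort(brute_hclust_heights(d, lk)),
                   tolerance = 1e-12)
    }
  }
  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("tree cutting yields nested partitions with the boundary cases", {
  d <- random_distance(10, 4)
  hc <- hierarchical_cluster(d, "average")
  expect_true(all(cut_tree(hc, 1) == 1))
  expect_equal(length(unique(cut_tree(hc, 10))), 10)
  for (k in 2:8) {           # nesting: k+1 refines k
    a <- cut_tree(hc, k); b <- cut_tree(hc, k + 1)
    expect_true(all(tapply(a, b, function(v) length(unique(v))) == 1))
  }
  expect_error(cut_tree(hc, 11), "k must lie")
})

test_that("well-separated planted blobs are recovered at k = 2", {
  set.seed(21)
  x <- cbind(matrix(rnorm(40, 0, 0.3), 4, 10),
             matrix(rnorm(40, 6, 0.3), 4, 10))
  dimnames(x) <- list(paste0("g", 1:4), paste0("s", 1:20))
  m <- expr_matrix(x, "log2")
  d <- distance_matrix(m, "euclidean", "samples")
  lab <- cut_tree(hierarchical_cluster(d, "complete"), 2)
  expect_equal(length(unique(lab[1:10])), 1)
  expect_equal(length(unique(lab[11:20])), 1)
  expect_false(lab[1] == lab[11])
})

test_that("cophenetic distances equal the lowest-common-merge heights", {
  d <- random_distance(8, 9)
  hc <- hierarchical_cluster(d, "complete")
  cd <- cophenetic_distances(hc)
  expect_equal(diag(cd), setNames(rep(0, 8), rownames(cd)))
  # independent oracle: walk the merge table, recording heights
  n <- 8
  members <- vector("list", n - 1)
  oracle <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    grab <- function(v) if (v < 0) -v else members[[v]]
    left <- grab(hc$merge[i, 1]); right <- grab(hc$merge[i, 2])
    for (a in left) for (b in right) oracle[a, b] <- oracle[b, a] <- hc$height[i]
    members[[i]] <- c(left, right)
  }
  dimnames(oracle) <- list(hc$labels, hc$labels)
  expect_equal(cd, oracle[rownames(cd), colnames(cd)])
  # leaves merged first sit at the first merge height
  first <- hc$labels[-hc$merge[1, ]]
  expect_equal(cd[first[1], first[2]], hc$height[1])
  # ultrametric inequality: max of any two sides >= the third
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(cd[i, j], max(cd[i, k], cd[k, j]) + 1e-12)
})
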