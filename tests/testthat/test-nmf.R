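# small planted block matrix: k groups of samples, one boosted gene block per
# group, strictly positive
planted_blocks <- function(k = 3, genes_per = 15, per_group = 8, boost = 4,
                           noise = 0.15, seed = 1) {
  set.seed(seed)
  n_genes <- k * genes_per + 20
  n_samp <- k * per_group
  mu <- 2^rnorm(n_genes, 6, 0.5)
  A <- matrix(mu, n_genes, n_samp)
  group <- rep(seq_len(k), each = per_group)
  for (g in seq_len(k)) {
    rows <- (g - 1) * genes_per + seq_len(genes_per)
    A[rows, group == g] <- A[rows, group == g] * boost
  }
  A <- A * 2^matrix(rnorm(length(A), 0, noise), n_genes)
  dimnames(A) <- list(sprintf("g%03d", 1:n_genes), sprintf("s%02d", 1:n_samp))
  list(A = A, group = setNames(group, colnames(A)))
}

test_that("KL factorization reconstructs exact low-rank data and never increases the divergence", {
  A <- outer(c(1, 2, 5), c(3, 4, 2, 7))
  dimnames(A) <- list(paste0("g", 1:3), paste0("s", 1:4))
  fit <- nmf_factorize(A, k = 1, seed = 3)
  expect_lt(max(abs(fit$W %*% fit$H - A)) / max(A), 1e-6)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))

  pb <- planted_blocks(k = 3, seed = 5)
  f3 <- nmf_factorize(pb$A, k = 3, seed = 7)
  f2 <- nmf_factorize(pb$A, k = 2, seed = 7)
  expect_true(all(diff(f3$objective_trace) <= 1e-9))
  expect_true(all(diff(f2$objective_trace) <= 1e-9))
  # nested models: the richer rank fits the planted 3-block data better
  expect_lt(tail(f3$objective_trace, 1), tail(f2$objective_trace, 1))

  expect_error(nmf_factorize(A, k = 5), "out of range")
  Az <- A; Az[2, ] <- 0
  expect_error(nmf_factorize(Az, k = 1), "all-zero row")
})

test_that("metagene assignment is argmax with smallest-index ties and permutation equivariance", {
  H <- rbind(c(0.9, 0.1), c(0.1, 0.8))
  expect_equal(unname(assign_from_H(H)), c(1, 2))
  expect_equal(unname(assign_from_H(matrix(c(0.5, 0.5), 2, 1))), 1)
  set.seed(4)
  H3 <- matrix(runif(30), 3, 10)
  perm <- c(2, 3, 1)
  lab <- assign_from_H(H3)
  lab_p <- assign_from_H(H3[perm, ])
  expect_equal(order(perm)[lab], unname(lab_p))
  expect_error(assign_from_H(cbind(H3, 0)), "all-zero column")
})

test_that("consensus matrices average run connectivities with the exact invariants", {
  pb <- planted_blocks(k = 4, per_group = 6, seed = 11)
  cr <- consensus_matrix(pb$A, k = 4, n_runs = 12, seed = 2)
  C <- cr$consensus
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(diag(C), setNames(rep(1, ncol(pb$A)), colnames(pb$A)))
  expect_equal(C, t(C))
  # planted blocks: high within-group, low between-group consensus
  same <- outer(pb$group, pb$group, "==")
  off <- upper.tri(C)
  expect_gte(mean(C[off & same]), 0.9)
  expect_lte(mean(C[off & !same]), 0.1)
  expect_error(consensus_matrix(pb$A, k = 4, n_runs = 1), "n_runs")
})

test_that("cophenetic coefficient is 1 for exact block consensus and decreases with noise", {
  # 0/1 two-block consensus is exactly ultrametric
  C <- matrix(0, 10, 10); C[1:5, 1:5] <- 1; C[6:10, 6:10] <- 1
  expect_equal(cophenetic_coefficient(C), 1)
  # constant distances: defined as 1
  expect_message(val <- cophenetic_coefficient(matrix(1, 4, 4)), "coph")
  expect_equal(val, 1)
  # progressive blurring of the block structure lowers coph
  set.seed(6)
  noise_levels <- c(0.05, 0.15, 0.3)
  cophs <- vapply(noise_levels, function(s) {
    Cn <- C + matrix(runif(100, 0, s), 10, 10)
    Cn <- (Cn + t(Cn)) / 2; Cn <- pmin(Cn, 1); diag(Cn) <- 1
    cophenetic_coefficient(Cn)
  }, numeric(1))
  expect_true(all(diff(cophs) < 0))
  expect_true(all(cophs >= -1 & cophs <= 1))
})

test_that("final group labels recover exact blocks and are order-invariant", {
  C <- matrix(0, 9, 9, dimnames = list(paste0("s", 1:9), paste0("s", 1:9)))
  C[1:5, 1:5] <- 1; C[6:9, 6:9] <- 1
  lab <- final_groups(C, 2)
  expect_equal(unname(lab), c(rep(1, 5), rep(2, 4)))  # numbered by size
  perm <- c(7, 2, 9, 4, 1, 6, 3, 8, 5)
  lab_p <- final_groups(C[perm, perm], 2)
  expect_equal(ari(lab_p[names(lab)], lab), 1)
  expect_error(final_groups(C, 10), "exceeds")
})

test_that("rank selection picks the planted rank and handles trivial ranges", {
  pb <- planted_blocks(k = 3, per_group = 7, seed = 13)
  rs <- select_rank(pb$A, k_range = 2:4, n_runs = 10, seed = 5)
  expect_equal(rs$k, 3)
  expect_equal(ari(rs$results[["3"]]$final_labels, pb$group), 1)
  expect_equal(nrow(rs$coph_table), 3)
  # single-k range returns that k
  rs1 <- select_rank(pb$A, k_range = 3, n_runs = 6, seed = 5)
  expect_equal(rs1$k, 3)
  expect_error(select_rank(pb$A, k_range = integer(0)), "empty k_range")
})
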