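# NMF consensus clustering engine: KL-divergence multiplicative-update
# factorization (compiled kernel), consensus matrices over random restarts,
# cophenetic-coefficient rank selection, and final group assignment.

#' Nonnegative matrix factorization by KL multiplicative updates
#'
#' Factorizes a nonnegative genes-by-samples matrix `A ~ W H` (W: genes x
#' k metagenes; H: k x samples metagene expression) by minimizing the
#' generalized Kullback-Leibler divergence `D(A || WH)` with multiplicative
#' updates, which never increase the divergence. W and H are initialized
#' i.i.d. uniform(0,1) scaled to the data mean from a derived seed, so runs
#' are fully reproducible. Iterations stop once the sample connectivity
#' implied by H (argmax metagene per sample) has been unchanged for
#' `conv_window` consecutive checks (one check every `check_every`
#' iterations), or at `max_iter`.
#'
#' @param A nonnegative numeric matrix (genes x samples); entries are
#'   floored at 1e-8 before factorization. A row or column that is entirely
#'   zero is rejected.
#' @param k factorization rank, `1 <= k < min(dim(A))`.
#' @param seed integer seed for the initialization stream.
#' @param max_iter maximum number of update iterations.
#' @param check_every iterations between connectivity checks.
#' @param conv_window consecutive stable checks required for convergence.
#' @return An `nmf_fit` list: `W`, `H`, `objective_trace` (divergence at each
#'   connectivity check), `iterations`, `converged`, `k`, `seed`.
#' @export
nmf_factorize <- function(A, k, seed = 1, max_iter = 2000, check_every = 10,
                          conv_window = 40) {
  if (inherits(A, "expr_matrix")) A <- expr_values(A)
  stopifnot(is.matrix(A), is.numeric(A))
  if (any(A < 0)) stop("A must be nonnegative")
  if (any(rowSums(A) == 0)) stop("A has an all-zero row")
  if (any(colSums(A) == 0)) stop("A has an all-zero column")
  if (k < 1 || k >= min(dim(A))) stop("k out of range [1, min(dim(A)) - 1]")
  A <- pmax(A, 1e-8)
  set.seed(derive_seed(seed, "nmf-init"))
  s <- sqrt(mean(A) / k)
  W0 <- matrix(stats::runif(nrow(A) * k), nrow(A), k) * s
  H0 <- matrix(stats::runif(k * ncol(A)), k, ncol(A)) * s
  fit <- nmf_kl_cpp(A, W0, H0, as.integer(max_iter), as.integer(check_every),
                    as.integer(conv_window))
  rownames(fit$W) <- rownames(A)
  colnames(fit$H) <- colnames(A)
  fit$k <- k
  fit$seed <- seed
  class(fit) <- "nmf_fit"
  fit
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("nmf_fit: k=%d, %d iterations (%s), final divergence %.4g\n",
              x$k, x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Cluster labels from a metagene expression matrix
#'
#' Sample `j` is placed in cluster `i` if `H[i, j]` is the largest entry of
#' column `j`; ties go to the smallest metagene index.
#'
#' @param H nonnegative k x samples matrix.
#' @return Integer labels in `1..k`, named by sample if H has colnames.
#' @export
assign_from_H <- function(H) {
  stopifnot(is.matrix(H), all(H >= 0))
  if (any(colSums(H) == 0)) stop("all-zero column in H: no assignable metagene")
  labels <- max.col(t(H), ties.method = "first")
  names(labels) <- colnames(H)
  labels
}

#' Consensus matrix over random NMF restarts
#'
#' Runs [nmf_factorize()] `n_runs` times with per-run seeds derived from the
#' master seed, assigns samples per run via [assign_from_H()], and averages
#' the run connectivity matrices (`C_r(i,j) = 1` iff samples i and j share a
#' cluster in run r). The consensus entry (i, j) is therefore the fraction
#' of runs co-clustering i and j; the matrix is symmetric with unit
#' diagonal. Runs that hit `max_iter` without a stable connectivity are
#' still used, with a warning (standard consensus practice).
#'
#' @inheritParams nmf_factorize
#' @param n_runs number of random restarts (>= 2).
#' @param ... further arguments passed to [nmf_factorize()].
#' @return A `consensus_result` list: `k`, `consensus` (samples x samples),
#'   `runs` (n_runs x samples label matrix), `n_converged`, `coph` (NULL
#'   until [cophenetic_coefficient()] is applied), `final_labels` (NULL
#'   until [final_groups()] is applied).
#' @export
consensus_matrix <- function(A, k, n_runs = 50, seed = 1, ...) {
  if (inherits(A, "expr_matrix")) A <- expr_values(A)
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (k < 2) stop("consensus clustering needs k >= 2")
  M <- ncol(A)
  runs <- matrix(NA_integer_, n_runs, M,
                 dimnames = list(NULL, colnames(A)))
  consensus <- matrix(0, M, M, dimnames = list(colnames(A), colnames(A)))
  n_converged <- 0L
  for (r in seq_len(n_runs)) {
    fit <- nmf_factorize(A, k, seed = derive_seed(seed, paste0("consensus-run-", r)),
                         ...)
    if (fit$converged) n_converged <- n_converged + 1L
    lab <- assign_from_H(fit$H)
    runs[r, ] <- lab
    consensus <- consensus + outer(lab, lab, "==")
  }
  if (n_converged < n_runs)
    warning(sprintf("%d of %d NMF runs did not reach a stable connectivity",
                    n_runs - n_converged, n_runs))
  consensus <- consensus / n_runs
  consensus <- (consensus + t(consensus)) / 2
  diag(consensus) <- 1
  structure(list(k = k, consensus = consensus, runs = runs,
                 n_converged = n_converged, coph = NULL, final_labels = NULL),
            class = "consensus_result")
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Converts the consensus matrix to distances `1 - consensus`, builds an
#' average-linkage dendrogram, and returns the Pearson correlation between
#' the off-diagonal consensus distances and the corresponding cophenetic
#' distances of that tree. Values near 1 indicate that the consensus is
#' close to ultrametric, i.e. a stable clustering at this rank. A constant
#' distance matrix (all samples identical) is defined as coph = 1, with a
#' message.
#'
#' @param consensus a `consensus_result` or a consensus matrix in `[0, 1]`.
#' @return The cophenetic coefficient in `[-1, 1]`.
#' @export
cophenetic_coefficient <- function(consensus) {
  C <- if (inherits(consensus, "consensus_result")) consensus$consensus
       else consensus
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  d <- stats::as.dist(1 - C)
  if (stats::sd(d) == 0) {
    message("constant consensus distances; coph defined as 1")
    return(1)
  }
  hc <- stats::hclust(d, method = "average")
  stats::cor(as.numeric(d), as.numeric(stats::cophenetic(hc)))
}

#' Final group assignment from a consensus matrix
#'
#' Cuts the average-linkage tree of `1 - consensus` into k groups and
#' renumbers them by decreasing size (ties broken by first sample index),
#' so group 1 is always the largest.
#'
#' @param consensus a `consensus_result` or consensus matrix.
#' @param k number of groups (defaults to the consensus result's k).
#' @return Integer group labels named by sample id.
#' @export
final_groups <- function(consensus, k = NULL) {
  C <- if (inherits(consensus, "consensus_result")) consensus$consensus
       else consensus
  if (is.null(k)) {
    if (inherits(consensus, "consensus_result")) k <- consensus$k
    else stop("k must be supplied for a bare consensus matrix")
  }
  if (k > ncol(C)) stop("k exceeds the sample count")
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  raw <- stats::cutree(hc, k = k)
  sizes <- table(raw)
  first_idx <- vapply(names(sizes), function(g) min(which(raw == g)), 0)
  ord <- order(-as.numeric(sizes), first_idx)
  remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- remap[as.character(raw)]
  names(out) <- names(raw)
  out
}

#' Rank selection by cophenetic coefficient
#'
#' Runs [consensus_matrix()] and [cophenetic_coefficient()] for each rank in
#' `k_range` and chooses the rank maximizing coph. Exact ties are broken to
#' the **largest** tied rank: a coarser partition of a perfectly
#' reproducible finer clustering is itself always perfectly reproducible
#' (merging stable clusters cannot destabilize them), so among equally
#' stable ranks the finest resolution is the informative one — this
#' operationalizes selecting the rank where the cophenetic coefficient
#' "begins to fall" rather than its first global maximum. A landscape where
#' every candidate rank has coph > 0.99 is flagged as `degenerate`
#' (e.g. a cohort with a single dominant block, where consensus stability
#' carries no rank signal).
#'
#' @inheritParams consensus_matrix
#' @param k_range candidate ranks (each >= 2 and < number of samples).
#' @return A `rank_selection` list: `k` (chosen rank), `coph_table` (data
#'   frame of k and coph), `results` (named list of `consensus_result`, one
#'   per k, with `coph` and `final_labels` filled in).
#' @export
select_rank <- function(A, k_range = 2:7, n_runs = 50, seed = 1, ...) {
  if (length(k_range) == 0) stop("empty k_range")
  if (inherits(A, "expr_matrix")) A <- expr_values(A)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range >= ncol(A)))
    stop("k_range must lie within [2, n_samples - 1]")
  results <- list()
  coph <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cr <- consensus_matrix(A, k, n_runs = n_runs,
                           seed = derive_seed(seed, paste0("rank-", k)), ...)
    cr$coph <- cophenetic_coefficient(cr)
    cr$final_labels <- final_groups(cr)
    results[[as.character(k)]] <- cr
    coph[i] <- cr$coph
  }
  # ties resolve to the largest k; 1e-9 absorbs floating-point noise in the
  # correlation (a perfectly reproducible consensus can score 1 - 1 ulp)
  chosen <- max(k_range[coph >= max(coph) - 1e-9])
  degenerate <- all(coph > 0.99)
  if (degenerate)
    message("all candidate ranks have coph > 0.99; ",
            "rank selection is degenerate for this cohort")
  structure(list(k = chosen,
                 coph_table = data.frame(k = k_range, coph = coph),
                 results = results, degenerate = degenerate),
            class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("NMF consensus rank selection (cophenetic coefficient):\n")
  print(x$coph_table, row.names = FALSE)
  cat("chosen k =", x$k,
      if (isTRUE(x$degenerate)) "(degenerate: all ranks highly stable)" else "",
      "\n")
  invisible(x)
}
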