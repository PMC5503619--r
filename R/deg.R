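# Integrated differential-expression statistic: Welch t and log2-median-ratio
# tests, each calibrated against a genome-wide pooled permutation null, then
# combined per gene with Stouffer's method.

# cap for infinite t statistics (zero-variance gene pairs); the p-value comes
# from the permutation null either way, so the exact value is immaterial
T_CAP <- 1e8
LOG2_MEDIAN_FLOOR <- log2(1e-8)

# core statistics for one column split; x is a log2-scale plain matrix
.two_group_stats <- function(x, ia, ib) {
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- matrixStats::rowVars(xa); vb <- matrixStats::rowVars(xb)
  se <- sqrt(va / na + vb / nb)
  t_stat <- (ma - mb) / se
  t_stat[is.nan(t_stat)] <- 0                      # 0/0: identical constant rows
  t_stat[is.infinite(t_stat)] <- sign(t_stat[is.infinite(t_stat)]) * T_CAP
  t_stat <- pmin(pmax(t_stat, -T_CAP), T_CAP)
  meda <- pmax(matrixStats::rowMedians(xa), LOG2_MEDIAN_FLOOR)
  medb <- pmax(matrixStats::rowMedians(xb), LOG2_MEDIAN_FLOOR)
  list(t_stat = t_stat, lmr_stat = meda - medb, mean_a = ma, mean_b = mb)
}

#' Per-gene two-group statistics on log2 expression
#'
#' Computes, for each gene, the Welch (unequal-variance) two-sample t
#' statistic, the log2-median-ratio statistic (difference of group medians
#' on the log2 scale, equivalently the log2 ratio of linear-scale medians,
#' with linear medians floored at 1e-8), and the geometric-mean fold change
#' `2^(mean_A - mean_B)` (`fc > 1` means up in group A; `abs_fc =
#' max(fc, 1/fc)`).
#'
#' @param m a log2-scale [expr_matrix()].
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @return Data frame: `gene`, `t_stat`, `lmr_stat`, `fold_change`, `abs_fc`.
#' @export
gene_statistics <- function(m, group_a, group_b) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "log2") stop("gene_statistics expects log2 values")
  if (length(intersect(group_a, group_b)) > 0) stop("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples")
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) stop("samples absent from matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  x <- expr_values(m)
  s <- .two_group_stats(x, match(group_a, colnames(x)),
                        match(group_b, colnames(x)))
  fc <- 2^(s$mean_a - s$mean_b)
  data.frame(gene = rownames(x), t_stat = s$t_stat, lmr_stat = s$lmr_stat,
             fold_change = fc, abs_fc = pmax(fc, 1 / fc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation p-values from a genome-wide pooled null
#'
#' For each statistic family (|t| and |log2-median-ratio|) the null pool is
#' the set of absolute statistics over all genes and `B` random relabelings
#' of the samples; each gene's p-value is the add-one tail proportion
#' `(1 + #(null >= |observed|)) / (1 + pool size)` (see
#' [permutation_pvalue()]). If `B` is at least the number of distinct
#' two-group label arrangements, all arrangements are enumerated exactly
#' instead (the identity arrangement then contributes the observed statistic
#' itself to the pool).
#'
#' @inheritParams gene_statistics
#' @param B number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return List with numeric vectors `p_t` and `p_lmr` (one per gene) and
#'   `pool_size`.
#' @export
permutation_null_pvalues <- function(m, group_a, group_b, B = 1000, seed = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (B < 100) stop("B must be >= 100 (unstable tail estimates otherwise)")
  obs <- gene_statistics(m, group_a, group_b)
  x <- expr_values(m)
  # canonical column order and subset size, so that swapping the two groups
  # realizes the identical label arrangements (p-values are swap-invariant)
  cols <- sort(match(c(group_a, group_b), colnames(x)))
  x <- x[, cols, drop = FALSE]
  n <- ncol(x)
  n_small <- min(length(group_a), length(group_b))
  n_arrangements <- choose(n, n_small)
  set.seed(derive_seed(seed, "permutation-null"))
  if (B >= n_arrangements) {
    splits <- utils::combn(n, n_small, simplify = FALSE)
  } else {
    splits <- replicate(B, sample.int(n, n_small), simplify = FALSE)
  }
  G <- nrow(x)
  null_t <- matrix(0, G, length(splits))
  null_lmr <- matrix(0, G, length(splits))
  for (r in seq_along(splits)) {
    ia <- splits[[r]]; ib <- setdiff(seq_len(n), ia)
    s <- .two_group_stats(x, ia, ib)
    null_t[, r] <- abs(s$t_stat)
    null_lmr[, r] <- abs(s$lmr_stat)
  }
  list(p_t = permutation_pvalue(abs(obs$t_stat), as.numeric(null_t)),
       p_lmr = permutation_pvalue(abs(obs$lmr_stat), as.numeric(null_lmr)),
       pool_size = G * length(splits))
}

#' Combine two-sided p-values with Stouffer's method
#'
#' Each two-sided p is converted to a signed z-score
#' `z = sign * qnorm(1 - p/2)` using the direction of its statistic; the
#' combined z is `(z1 + z2)/sqrt(2)` and the combined p the two-sided normal
#' tail `2 * (1 - pnorm(|z|))`. A p-value of exactly 1 contributes z = 0;
#' p-values at or below 0 are clamped to the smallest positive double, with
#' a warning, before the normal quantile.
#'
#' @param p_t,p_lmr numeric vectors of two-sided p-values in (0,1).
#' @param sign_t,sign_lmr direction of each statistic (sign(t),
#'   sign(log2-median-ratio)); a direction of 0 contributes z = 0.
#' @return Numeric vector of combined two-sided p-values.
#' @export
stouffer_combine <- function(p_t, p_lmr, sign_t, sign_lmr) {
  stopifnot(length(p_t) == length(p_lmr),
            length(sign_t) == length(p_t), length(sign_lmr) == length(p_t))
  clamp <- function(p) {
    # p = 1 maps to z = 0 exactly and needs no warning (the add-one
    # permutation estimator produces it routinely); p <= 0 would send
    # qnorm to infinity and is flagged
    if (any(p <= 0)) warning("p-values at or below 0 clamped before qnorm")
    pmin(pmax(p, .Machine$double.xmin), 1)
  }
  z1 <- sign(sign_t) * stats::qnorm(1 - clamp(p_t) / 2)
  z2 <- sign(sign_lmr) * stats::qnorm(1 - clamp(p_lmr) / 2)
  zc <- (z1 + z2) / sqrt(2)
  2 * stats::pnorm(-abs(zc))
}

#' Integrated differential-expression test
#'
#' Runs [gene_statistics()], calibrates both statistics against the pooled
#' permutation null ([permutation_null_pvalues()]) and combines the two
#' p-values per gene with [stouffer_combine()].
#'
#' @inheritParams permutation_null_pvalues
#' @return A `deg_result` data frame: `gene`, `t_stat`, `lmr_stat`,
#'   `fold_change`, `abs_fc`, `p_t`, `p_lmr`, `p_combined`, with the groups,
#'   `B` and seed recorded as attributes.
#' @export
deg_test <- function(m, group_a, group_b, B = 1000, seed = 1) {
  res <- gene_statistics(m, group_a, group_b)
  pv <- permutation_null_pvalues(m, group_a, group_b, B = B, seed = seed)
  res$p_t <- pv$p_t
  res$p_lmr <- pv$p_lmr
  res$p_combined <- stouffer_combine(pv$p_t, pv$p_lmr,
                                     sign(res$t_stat), sign(res$lmr_stat))
  attr(res, "group_a") <- group_a
  attr(res, "group_b") <- group_b
  attr(res, "B") <- B
  attr(res, "seed") <- seed
  attr(res, "pool_size") <- pv$pool_size
  class(res) <- c("deg_result", "data.frame")
  res
}

#' Threshold a DEG result into a DEG set
#'
#' Keeps genes with `abs_fc > fc_min` **and** `p_combined < p_max` (both
#' strict), ordered by `abs_fc` descending then gene id.
#'
#' @param result a `deg_result` from [deg_test()].
#' @param fc_min fold-change threshold (> 0), e.g. 2.
#' @param p_max p-value threshold, e.g. 0.05.
#' @return A `deg_set` data frame (subset of `result`) with the thresholds
#'   stored as attributes `fc_min` and `p_max`.
#' @export
select_degs <- function(result, fc_min = 2, p_max = 0.05) {
  stopifnot(fc_min > 0, p_max > 0)
  keep <- result$abs_fc > fc_min & result$p_combined < p_max
  out <- result[keep, , drop = FALSE]
  out <- out[order(-out$abs_fc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fc_min") <- fc_min
  attr(out, "p_max") <- p_max
  class(out) <- c("deg_set", "data.frame")
  out
}
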