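# Cross-classification concordance, clinicopathologic association tests, and
# the percentage-printing convention of cohort tables.

#' Cross-tabulate an internal grouping against an external labeling
#'
#' Counts samples by (external class, internal group) over samples whose
#' external label is determined; samples labeled `"undetermined"` are
#' tallied separately per internal group. The grand total equals the number
#' of samples.
#'
#' @param internal per-sample internal group labels (e.g. NMF groups);
#'   vector named by sample id, or aligned with `external`.
#' @param external per-sample external class labels (e.g. CMS1-4), possibly
#'   `"undetermined"`.
#' @param undetermined label marking an undetermined external class.
#' @return A `crosstab` list: `counts` (external x internal matrix),
#'   `undetermined` (per internal group), `col_totals`, `n_determined`,
#'   `n_total`.
#' @export
cross_tabulate <- function(internal, external, undetermined = "undetermined") {
  if (length(internal) != length(external))
    stop("labelings must cover the same samples")
  if (!is.null(names(internal)) && !is.null(names(external))) {
    if (!setequal(names(internal), names(external)))
      stop("labelings must cover the same samples")
    external <- external[names(internal)]
  }
  internal <- as.character(internal)
  external <- as.character(external)
  int_levels <- sort(unique(internal))
  det <- external != undetermined
  ext_levels <- sort(unique(external[det]))
  counts <- table(factor(external[det], levels = ext_levels),
                  factor(internal[det], levels = int_levels))
  counts <- matrix(as.integer(counts), nrow = length(ext_levels),
                   ncol = length(int_levels),
                   dimnames = list(ext_levels, int_levels))
  und <- vapply(int_levels, function(g) sum(!det & internal == g), 0L)
  structure(list(counts = counts, undetermined = und,
                 col_totals = colSums(counts) + und,
                 n_determined = sum(counts), n_total = length(internal)),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  m <- rbind(x$counts, undetermined = x$undetermined, total = x$col_totals)
  print(m)
  invisible(x)
}

# all injective assignments of `k` columns into `n` rows (k <= n), as a list
# of integer vectors (row index per column)
.injections <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) { out[[length(out) + 1L]] <<- prefix; return() }
    for (r in remaining) rec(c(prefix, r), setdiff(remaining, r))
  }
  rec(integer(0), seq_len(n))
  out
}

#' Optimal one-to-one matching of two classifications
#'
#' Finds the injective assignment of internal groups to external classes
#' maximizing the number of agreeing samples in the cross-tabulation
#' (exhaustive search over assignments; intended for <= 7 classes).
#' Undetermined samples are excluded from both the matched count and the
#' percentage denominator.
#'
#' @param ct a `crosstab` from [cross_tabulate()].
#' @return List: `mapping` (named character vector internal -> external),
#'   `matched` (agreeing sample count), `determined` (denominator),
#'   `percent` (matched / determined, 1 decimal, halves away from zero).
#' @export
optimal_match <- function(ct) {
  if (is.matrix(ct))
    ct <- structure(list(counts = ct, undetermined = rep(0L, ncol(ct)),
                         col_totals = colSums(ct), n_determined = sum(ct),
                         n_total = sum(ct)), class = "crosstab")
  stopifnot(inherits(ct, "crosstab"))
  counts <- ct$counts
  if (length(counts) == 0 || ct$n_determined == 0)
    stop("empty cross-tabulation")
  nr <- nrow(counts); nc <- ncol(counts)
  if (max(nr, nc) > 8) stop("exhaustive matching supports at most 8 classes")
  if (nc <= nr) {
    assigns <- .injections(nr, nc)
    scores <- vapply(assigns, function(a) sum(counts[cbind(a, seq_len(nc))]), numeric(1))
    best <- assigns[[which.max(scores)]]
    mapping <- stats::setNames(rownames(counts)[best], colnames(counts))
  } else {
    assigns <- .injections(nc, nr)
    scores <- vapply(assigns, function(a) sum(counts[cbind(seq_len(nr), a)]), numeric(1))
    best <- assigns[[which.max(scores)]]
    mapping <- stats::setNames(rownames(counts), colnames(counts)[best])
    mapping <- mapping[order(names(mapping))]
  }
  matched <- max(scores)
  list(mapping = mapping, matched = as.integer(matched),
       determined = ct$n_determined,
       percent = percent(matched, ct$n_determined))
}

#' Association test between a grouping and a covariate
#'
#' Dispatches to the standard tests used for cohort tables: Pearson
#' chi-square on an r x c contingency table (no continuity correction),
#' Fisher's exact test on a 2 x 2 table, or Kruskal-Wallis / Mann-Whitney
#' rank tests on a numeric covariate by group (midrank ties). With
#' `method = "auto"` on a table: Fisher when the table is 2 x 2 with any
#' expected count < 5, else chi-square (the choice is reported via a
#' message).
#'
#' @param x a contingency table (matrix of counts) for `chi_square` /
#'   `fisher_2x2`, or a numeric vector for the rank tests.
#' @param groups group labels aligned with `x` (rank tests only).
#' @param method one of `"chi_square"`, `"fisher_2x2"`, `"kruskal_wallis"`,
#'   `"mann_whitney"`, `"auto"`.
#' @return List: `statistic`, `df` (where defined), `p`, `method`.
#' @export
association_test <- function(x, groups = NULL,
                             method = c("auto", "chi_square", "fisher_2x2",
                                        "kruskal_wallis", "mann_whitney")) {
  method <- match.arg(method)
  if (method == "auto") {
    if (!is.matrix(x)) {
      method <- if (length(unique(groups)) == 2) "mann_whitney"
                else "kruskal_wallis"
    } else {
      expected <- outer(rowSums(x), colSums(x)) / sum(x)
      method <- if (all(dim(x) == c(2, 2)) && any(expected < 5)) "fisher_2x2"
                else "chi_square"
    }
    message("association_test: auto-selected ", method)
  }
  switch(method,
    chi_square = {
      stopifnot(is.matrix(x), all(x >= 0))
      expected <- outer(rowSums(x), colSums(x)) / sum(x)
      if (any(expected == 0))
        stop("expected cell count of 0; consider Fisher's exact test")
      ht <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
      list(statistic = unname(ht$statistic), df = unname(ht$parameter),
           p = ht$p.value, method = "chi_square")
    },
    fisher_2x2 = {
      stopifnot(is.matrix(x), all(dim(x) == c(2, 2)))
      ht <- stats::fisher.test(x)
      list(statistic = NA_real_, df = NA_real_, p = ht$p.value,
           method = "fisher_2x2")
    },
    kruskal_wallis = {
      stopifnot(is.numeric(x), length(x) == length(groups))
      ht <- stats::kruskal.test(x, factor(groups))
      list(statistic = unname(ht$statistic), df = unname(ht$parameter),
           p = ht$p.value, method = "kruskal_wallis")
    },
    mann_whitney = {
      stopifnot(is.numeric(x), length(x) == length(groups))
      g <- factor(groups)
      if (nlevels(g) != 2) stop("mann_whitney needs exactly two groups")
      ht <- suppressWarnings(stats::wilcox.test(x[g == levels(g)[1]],
                                                x[g == levels(g)[2]]))
      list(statistic = unname(ht$statistic), df = NA_real_, p = ht$p.value,
           method = "mann_whitney")
    })
}

#' Printed percentage convention
#'
#' `100 * count / denom`, rounded to `decimals` places with halves away
#' from zero (the convention of printed cohort tables).
#'
#' @param count numerator.
#' @param denom denominator (> 0).
#' @param decimals decimal places (default 1).
#' @return The rounded percentage.
#' @export
percent <- function(count, denom, decimals = 1) {
  if (any(denom <= 0)) stop("denominator must be > 0")
  round_half_away(100 * count / denom, decimals)
}
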