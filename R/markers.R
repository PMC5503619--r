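# Subtype marker selection: per-group DEGs versus normal and versus the other
# tumor groups, their intersection (candidate markers), and ranked top-n
# panels.

# internal: sample ids for a group contrast
.contrast_samples <- function(annotation, labels, group, reference) {
  tumors <- annotation$sample_id[annotation$tissue == "tumor"]
  labs <- labels[tumors]
  if (anyNA(labs)) stop("every tumor sample needs a group label")
  ga <- tumors[labs == group]
  if (length(ga) == 0) stop("unknown or empty group: ", group)
  gb <- if (reference == "normal") {
    annotation$sample_id[annotation$tissue == "normal"]
  } else {
    tumors[labs != group]
  }
  if (length(gb) == 0)
    stop("empty reference set for contrast (", reference, ")")
  list(group_a = ga, group_b = gb)
}

#' Differential expression of one tumor group against a reference
#'
#' Runs the integrated DEG test ([deg_test()]) contrasting the samples of
#' group `g` against either the normal samples or all other tumor groups,
#' and thresholds the result with [select_degs()] (per-gene fold changes are
#' retained in the returned set).
#'
#' @param m a log2-scale [expr_matrix()].
#' @param annotation data frame with `sample_id` and `tissue` columns.
#' @param labels named integer vector of group labels for tumor samples.
#' @param group group id to contrast.
#' @param reference `"normal"` or `"rest"` (other tumor groups).
#' @param fc_min,p_max selection thresholds (strict, on `abs_fc` and
#'   `p_combined`).
#' @param B,seed permutation settings, see [permutation_null_pvalues()].
#' @return A `deg_set` data frame.
#' @export
group_degs <- function(m, annotation, labels, group,
                       reference = c("normal", "rest"),
                       fc_min = 2, p_max = 0.05, B = 1000, seed = 1) {
  reference <- match.arg(reference)
  cs <- .contrast_samples(annotation, labels, group, reference)
  res <- deg_test(m, cs$group_a, cs$group_b, B = B, seed = seed)
  select_degs(res, fc_min = fc_min, p_max = p_max)
}

#' Candidate subtype markers from two DEG families
#'
#' A gene is a candidate marker for group g iff it is upregulated
#' (`fold_change > 1`, having passed the selection thresholds) in g versus
#' normal *and* in g versus the other tumor groups. A gene qualifying for
#' several groups is attributed to the single group with the largest
#' group-versus-rest fold change (reported via a message), so the output is
#' a partition.
#'
#' @param vs_normal named list (one `deg_set` per group) of group-vs-normal
#'   selections.
#' @param vs_rest named list (same groups) of group-vs-rest selections.
#' @return Data frame: `gene`, `group`, `fc_t_vs_n` (fold change of the
#'   group's tumors vs normal), `fc_group_vs_rest`.
#' @export
marker_candidates <- function(vs_normal, vs_rest) {
  if (!identical(sort(names(vs_normal)), sort(names(vs_rest))))
    stop("the two DEG families must cover the same groups")
  rows <- list()
  for (g in names(vs_normal)) {
    up_n <- vs_normal[[g]]
    up_r <- vs_rest[[g]]
    up_n <- up_n[up_n$fold_change > 1, , drop = FALSE]
    up_r <- up_r[up_r$fold_change > 1, , drop = FALSE]
    genes <- intersect(up_n$gene, up_r$gene)
    if (length(genes) == 0) next
    rows[[g]] <- data.frame(
      gene = genes, group = g,
      fc_t_vs_n = up_n$fold_change[match(genes, up_n$gene)],
      fc_group_vs_rest = up_r$fold_change[match(genes, up_r$gene)],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(), group = character(),
                      fc_t_vs_n = numeric(), fc_group_vs_rest = numeric(),
                      stringsAsFactors = FALSE))
  dup <- unique(out$gene[duplicated(out$gene)])
  if (length(dup)) {
    message(length(dup), " gene(s) qualified for multiple groups; ",
            "attributed to the group with the largest vs-rest fold change")
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$gene), function(i)
      i[which.max(out$fc_group_vs_rest[i])]))
    out <- out[sort(keep), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Top marker panel per group
#'
#' Keeps candidates whose fold change exceeds `fc_min` against both normal
#' tissue and the other tumor groups (strict), then takes the `n` largest
#' per group by vs-rest fold change (ties by vs-normal fold change, then
#' gene id). A group with fewer than `n` survivors returns what exists,
#' with a message.
#'
#' @param candidates output of [marker_candidates()] (or any data frame
#'   with `gene`, `group`, `fc_t_vs_n`, `fc_group_vs_rest`).
#' @param fc_min fold-change floor applied to both columns (default 1.5).
#' @param n panel size per group (default 10).
#' @return A `marker_table` data frame: `gene`, `group`, `fc_t_vs_n`,
#'   `fc_group_vs_rest`, `rank` (within group, by vs-rest fold change
#'   descending).
#' @export
top_markers <- function(candidates, fc_min = 1.5, n = 10) {
  stopifnot(all(c("gene", "group", "fc_t_vs_n", "fc_group_vs_rest") %in%
                  names(candidates)))
  keep <- candidates$fc_t_vs_n > fc_min & candidates$fc_group_vs_rest > fc_min
  surv <- candidates[keep, , drop = FALSE]
  rows <- lapply(split(surv, surv$group), function(df) {
    df <- df[order(-df$fc_group_vs_rest, -df$fc_t_vs_n, df$gene), ,
             drop = FALSE]
    if (nrow(df) < n)
      message("group ", df$group[1], ": only ", nrow(df),
              " marker(s) pass the ", fc_min, "-fold filter")
    df <- utils::head(df, n)
    df$rank <- seq_len(nrow(df))
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- candidates[0, , drop = FALSE]
    out$rank <- integer(0)
  }
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Panel gene behaviour across groups
#'
#' For each gene of a fixed panel (e.g. a published classifier gene list)
#' and each tumor group, records whether the gene passes the
#' (`fc_min`, `p_max`) up-regulation filter versus normal tissue and versus
#' the other tumor groups. Panel genes absent from the matrix are reported
#' under `missing` and excluded from counts.
#'
#' @inheritParams group_degs
#' @param panel character vector of gene ids (nonempty).
#' @param fc_min,p_max thresholds (defaults 1.5 and 0.01).
#' @return List with `calls` (data frame gene x group x mode with logical
#'   `up`), `missing` (absent panel genes), and `summary` (per group and
#'   mode: number of panel genes up; plus `n_specific` per mode = genes up
#'   in exactly one group).
#' @export
panel_summary <- function(m, annotation, labels, panel,
                          fc_min = 1.5, p_max = 0.01, B = 1000, seed = 1) {
  if (length(panel) == 0) stop("empty panel")
  missing <- setdiff(panel, rownames(m))
  present <- intersect(panel, rownames(m))
  groups <- sort(unique(labels[!is.na(labels)]))
  calls <- list()
  for (g in groups) {
    for (ref in c("normal", "rest")) {
      cs <- .contrast_samples(annotation, labels, g, ref)
      res <- deg_test(m, cs$group_a, cs$group_b, B = B,
                      seed = derive_seed(seed, paste0("panel-", g, "-", ref)))
      res <- res[match(present, res$gene), , drop = FALSE]
      calls[[paste(g, ref, sep = "-")]] <- data.frame(
        gene = present, group = g, mode = paste0("vs_", ref),
        up = res$fold_change > fc_min & res$p_combined < p_max,
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  summary <- stats::aggregate(up ~ group + mode, data = calls, FUN = sum)
  n_specific <- vapply(unique(calls$mode), function(md) {
    per_gene <- tapply(calls$up[calls$mode == md], calls$gene[calls$mode == md],
                       sum)
    sum(per_gene == 1)
  }, 0)
  list(calls = calls, missing = missing, summary = summary,
       n_specific = n_specific)
}
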