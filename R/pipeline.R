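# End-to-end orchestration: normalize -> DEGs -> NMF consensus subtyping ->
# markers -> concordance -> clinical associations -> survival, from a single
# seeded configuration. Every stage's thresholds, seeds and gene-set sizes
# are recorded in a manifest so the filtered counts stay auditable, and a
# rerun with the same configuration reproduces every output bit-identically.

#' Pipeline configuration
#'
#' @param expression an [expr_matrix()] (linear scale) or path to a TSV.
#' @param annotation a data frame (see [read_annotation()]) or path to a TSV.
#' @param out_dir directory for persisted stage outputs (NULL: in-memory
#'   only).
#' @param deg_unsupervised `c(fc, p)` thresholds for the broad
#'   tumor-vs-normal DEG list used for unsupervised hierarchical clustering
#'   (default |FC| > 2, P < 0.05).
#' @param deg_nmf `c(fc, p)` thresholds for the stricter tumor-vs-normal DEG
#'   list feeding NMF consensus clustering (default |FC| > 2, P < 0.01).
#' @param hclust_k number of clusters reported from the unsupervised tree.
#' @param k_range candidate NMF ranks.
#' @param n_runs NMF restarts per rank.
#' @param B permutation count for DEG p-values.
#' @param marker_fc,marker_p candidate-marker thresholds for the per-group
#'   contrasts (default |FC| > 2, P < 0.05).
#' @param marker_fc_top,top_n final marker-panel filter (fold change > 1.5
#'   against both references) and panel size.
#' @param panel optional gene panel for [panel_summary()] (thresholds
#'   |FC| > 1.5, P < 0.01).
#' @param time_col,event_col annotation columns holding survival time
#'   (months) and event status.
#' @param covariates annotation columns to test for association with the
#'   groups (default: auto-detect categorical extras).
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, annotation, out_dir = NULL,
                            deg_unsupervised = c(fc = 2, p = 0.05),
                            deg_nmf = c(fc = 2, p = 0.01),
                            hclust_k = 4,
                            k_range = 2:7, n_runs = 50, B = 1000,
                            marker_fc = 2, marker_p = 0.05,
                            marker_fc_top = 1.5, top_n = 10,
                            panel = NULL,
                            time_col = "time_months", event_col = "event",
                            covariates = NULL, seed = 1) {
  stopifnot(deg_unsupervised[1] > 0, deg_unsupervised[2] > 0,
            deg_nmf[1] > 0, deg_nmf[2] > 0, marker_fc > 0, marker_p > 0)
  cfg <- list(expression = expression, annotation = annotation,
              out_dir = out_dir,
              deg_unsupervised = deg_unsupervised, deg_nmf = deg_nmf,
              hclust_k = hclust_k, k_range = k_range, n_runs = n_runs, B = B,
              marker_fc = marker_fc, marker_p = marker_p,
              marker_fc_top = marker_fc_top, top_n = top_n, panel = panel,
              time_col = time_col, event_col = event_col,
              covariates = covariates, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

.write_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full subtyping pipeline
#'
#' Executes, in order: input validation, quantile normalization,
#' tumor-vs-normal DEG selection (broad and strict lists), unsupervised
#' hierarchical clustering (Pearson distance, complete linkage, on gene
#' median-centered log2 values of the broad DEG list), NMF consensus rank
#' selection and final grouping on the strict DEG list (linear-scale
#' normalized intensities), per-group marker selection, concordance against
#' an `external_label` annotation column if present, association tests for
#' clinical covariates, and per-group survival analysis if time/event
#' columns are present. Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return A `report_bundle` list with all stage outputs and a `manifest`
#'   recording thresholds, seeds and gene-set sizes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      # flag partial outputs so a resumed run cannot mistake them for a
      # completed analysis
      if (!is.null(config$out_dir) && dir.exists(config$out_dir)) {
        fdir <- file.path(config$out_dir, "failed")
        dir.create(fdir, showWarnings = FALSE)
        writeLines(c(stage, conditionMessage(e)),
                   file.path(fdir, "FAILED_STAGE"))
      }
      stage_stop(stage, conditionMessage(e))
    })
  }

  # -- inputs -----------------------------------------------------------
  bundle <- list()
  m <- run_stage("read_expression", {
    if (is.character(config$expression)) {
      if (!file.exists(config$expression))
        stop("expression file not found: ", config$expression)
      read_expression(config$expression)
    } else config$expression
  })
  ann <- run_stage("read_annotation", {
    if (is.character(config$annotation)) {
      if (!file.exists(config$annotation))
        stop("annotation file not found: ", config$annotation)
      read_annotation(config$annotation)
    } else config$annotation
  })
  run_stage("validate_inputs", {
    if (!all(ann$sample_id %in% colnames(m)))
      stop("annotation samples missing from expression matrix")
    invisible(NULL)
  })
  tumors <- ann$sample_id[ann$tissue == "tumor"]
  normals <- ann$sample_id[ann$tissue == "normal"]

  # -- normalization ----------------------------------------------------
  norm <- run_stage("quantile_normalize", quantile_normalize(m))
  logm <- run_stage("log2_transform", to_log2(norm, pseudo = 1))

  # -- tumor-vs-normal DEGs --------------------------------------------
  deg_tn <- run_stage("deg_tumor_vs_normal",
    deg_test(logm, tumors, normals, B = config$B,
             seed = derive_seed(config$seed, "deg-tumor-vs-normal")))
  deg_broad <- select_degs(deg_tn, config$deg_unsupervised[1],
                           config$deg_unsupervised[2])
  deg_strict <- select_degs(deg_tn, config$deg_nmf[1], config$deg_nmf[2])
  message(sprintf("DEG tumor-vs-normal: %d broad (|FC|>%s, P<%s), %d strict (|FC|>%s, P<%s)",
                  nrow(deg_broad), config$deg_unsupervised[1],
                  config$deg_unsupervised[2], nrow(deg_strict),
                  config$deg_nmf[1], config$deg_nmf[2]))
  bundle$deg_tumor_vs_normal <- deg_tn
  bundle$deg_broad <- deg_broad
  bundle$deg_strict <- deg_strict
  .write_tsv(deg_broad, config$out_dir, "deg_broad.tsv")
  .write_tsv(deg_strict, config$out_dir, "deg_nmf.tsv")

  # -- unsupervised hierarchical clustering ----------------------------
  bundle$hclust <- run_stage("hierarchical_clustering", {
    if (nrow(deg_broad) < 2) stop("fewer than 2 broad DEGs")
    sub <- expr_matrix(expr_values(logm)[deg_broad$gene, , drop = FALSE],
                       scale = "log2")
    d <- distance_matrix(center_genes(sub), metric = "pearson",
                         axis = "samples")
    tree <- hierarchical_cluster(d, linkage = "complete")
    list(tree = tree, labels = cut_tree(tree, config$hclust_k))
  })

  # -- NMF consensus subtyping -----------------------------------------
  rank_sel <- run_stage("nmf_consensus", {
    if (nrow(deg_strict) < max(config$k_range) + 1)
      stop("too few strict DEGs for the requested k_range")
    A <- expr_values(norm)[deg_strict$gene, tumors, drop = FALSE]
    select_rank(A, k_range = config$k_range, n_runs = config$n_runs,
                seed = derive_seed(config$seed, "nmf-consensus"))
  })
  groups <- rank_sel$results[[as.character(rank_sel$k)]]$final_labels
  message(sprintf("NMF consensus: chosen k = %d (coph = %.4f)", rank_sel$k,
                  max(rank_sel$coph_table$coph)))
  bundle$rank_selection <- rank_sel
  bundle$groups <- groups
  .write_tsv(rank_sel$coph_table, config$out_dir, "coph_table.tsv")
  .write_tsv(data.frame(sample_id = names(groups), group = groups),
             config$out_dir, "labels.tsv")

  # -- markers ----------------------------------------------------------
  bundle$markers <- run_stage("markers", {
    gs <- sort(unique(groups))
    vs_n <- lapply(gs, function(g)
      group_degs(logm, ann, groups, g, "normal", config$marker_fc,
                 config$marker_p, B = config$B,
                 seed = derive_seed(config$seed, paste0("marker-n-", g))))
    vs_r <- lapply(gs, function(g)
      group_degs(logm, ann, groups, g, "rest", config$marker_fc,
                 config$marker_p, B = config$B,
                 seed = derive_seed(config$seed, paste0("marker-r-", g))))
    names(vs_n) <- names(vs_r) <- gs
    cand <- marker_candidates(vs_n, vs_r)
    top <- top_markers(cand, fc_min = config$marker_fc_top, n = config$top_n)
    list(vs_normal_sizes = vapply(vs_n, nrow, 0L),
         vs_rest_sizes = vapply(vs_r, nrow, 0L),
         candidates = cand, top = top)
  })
  .write_tsv(bundle$markers$top, config$out_dir, "markers.tsv")

  # -- panel summary (optional) ----------------------------------------
  if (!is.null(config$panel)) {
    bundle$panel <- run_stage("panel_summary",
      panel_summary(logm, ann, groups, config$panel, B = config$B,
                    seed = derive_seed(config$seed, "panel")))
  }

  # -- concordance with external labels --------------------------------
  if ("external_label" %in% names(ann)) {
    bundle$concordance <- run_stage("concordance", {
      ext <- stats::setNames(ann$external_label, ann$sample_id)[names(groups)]
      ct <- cross_tabulate(groups, ext)
      list(crosstab = ct, match = optimal_match(ct))
    })
    .write_tsv(as.data.frame(bundle$concordance$crosstab$counts),
               config$out_dir, "crosstab.tsv")
  }

  # -- clinical associations -------------------------------------------
  covars <- config$covariates
  if (is.null(covars))
    covars <- setdiff(names(ann), c("sample_id", "tissue", "group",
                                    "external_label", config$time_col,
                                    config$event_col))
  if (length(covars)) {
    bundle$associations <- run_stage("associations", {
      tum <- ann[match(names(groups), ann$sample_id), , drop = FALSE]
      out <- lapply(covars, function(cv) {
        v <- tum[[cv]]
        if (is.numeric(v)) association_test(v, groups, "kruskal_wallis")
        else association_test(as.matrix(table(v, groups)), method = "auto")
      })
      names(out) <- covars
      out
    })
    .write_tsv(data.frame(covariate = covars,
                          method = vapply(bundle$associations, `[[`, "", "method"),
                          p = vapply(bundle$associations, `[[`, 0, "p")),
               config$out_dir, "assoc.tsv")
  }

  # -- survival ---------------------------------------------------------
  if (all(c(config$time_col, config$event_col) %in% names(ann))) {
    bundle$survival <- run_stage("survival", {
      tum <- ann[match(names(groups), ann$sample_id), , drop = FALSE]
      time <- tum[[config$time_col]]; event <- tum[[config$event_col]]
      ok <- !is.na(time) & !is.na(event)
      list(curves = km_by_group(time[ok], event[ok], groups[ok]),
           logrank = logrank_test(time[ok], event[ok], groups[ok]))
    })
  }

  # -- manifest ---------------------------------------------------------
  manifest <- list(
    seed = config$seed,
    thresholds = list(unsupervised = as.list(config$deg_unsupervised),
                      nmf = as.list(config$deg_nmf),
                      marker = list(fc = config$marker_fc, p = config$marker_p),
                      marker_top = list(fc = config$marker_fc_top,
                                        n = config$top_n)),
    B = config$B, n_runs = config$n_runs,
    k_range = config$k_range, chosen_k = rank_sel$k,
    coph = rank_sel$coph_table,
    gene_set_sizes = list(broad = nrow(deg_broad), strict = nrow(deg_strict)),
    group_sizes = as.list(table(groups)),
    n_samples = list(tumor = length(tumors), normal = length(normals)),
    package_version = as.character(utils::packageVersion("subtypenmf")))
  bundle$manifest <- manifest
  if (!is.null(config$out_dir))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  class(bundle) <- "report_bundle"
  bundle
}
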