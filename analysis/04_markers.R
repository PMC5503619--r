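#!/usr/bin/env Rscript
# Stage 4 — subtype-specific marker panels.
#
# For each NMF group: DEGs versus normal mucosa and versus the other tumor
# groups (|FC| > 2, P < 0.05), their intersection as candidate markers
# (each gene attributed to one group), and the top-10 panel per group by
# group-vs-rest fold change with both fold changes > 1.5. Checks recovery of
# the planted markers and ranks the published panel fold changes as a
# consistency exercise.

suppressPackageStartupMessages(library(subtypenmf))

norm <- read_expression("results/expression_normalized.tsv")
ann <- read_annotation("results/cohort/annotation.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json", simplifyVector = TRUE)
labels <- read.table("results/labels.tsv", header = TRUE, sep = "\t")
groups <- setNames(labels$group, labels$sample_id)
logm <- to_log2(norm, pseudo = 1)

gs <- sort(unique(groups))
vs_n <- lapply(gs, function(g)
  group_degs(logm, ann, groups, g, "normal", fc_min = 2, p_max = 0.05,
             B = 500, seed = 20260904 + g))
vs_r <- lapply(gs, function(g)
  group_degs(logm, ann, groups, g, "rest", fc_min = 2, p_max = 0.05,
             B = 500, seed = 20260914 + g))
names(vs_n) <- names(vs_r) <- gs

cand <- marker_candidates(vs_n, vs_r)
top <- top_markers(cand, fc_min = 1.5, n = 10)
write.table(cand, "results/marker_candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(top, "results/markers_top10.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("candidate markers: %d (planted: %d)\n", nrow(cand),
            length(unlist(truth$markers))))
planted <- unlist(truth$markers)
cat(sprintf("fraction of candidates that are planted markers: %.3f\n",
            mean(cand$gene %in% planted)))
cat("top-10 panel sizes per group:\n")
print(table(top$group))

# replay the published panel ranking from its printed fold changes
pub <- top_markers(reference_marker_fcs(), fc_min = 1.5, n = 10)
cat("published panel, strongest marker per group by vs-rest fold change:\n")
print(pub[pub$rank == 1, c("group", "gene", "fc_t_vs_n", "fc_group_vs_rest")])
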