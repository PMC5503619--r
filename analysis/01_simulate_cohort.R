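#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates a synthetic analogue of the reference cohort: 101 stage III
# colorectal tumors in four planted molecular subtypes (22/21/16/42) plus 35
# matched normal mucosa samples, 2,000 genes, with planted tumor-vs-normal
# DEGs, subtype markers, group-dependent clinical covariates and
# group-specific survival hazards. Writes expression.tsv, annotation.tsv and
# truth.json under results/cohort/.

suppressPackageStartupMessages(library(subtypenmf))

out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 20260901)
sim <- simulate_cohort(cfg)
sv <- simulate_survival(sim$truth$group, cfg)
cl <- simulate_clinical(sim$truth$group, cfg)

ann <- sim$annotation
idx <- match(sv$sample_id, ann$sample_id)
ann$time_months <- NA_real_; ann$event <- NA_integer_
ann$time_months[idx] <- round(sv$time_months, 2)
ann$event[idx] <- sv$event
for (nm in setdiff(names(cl), c("sample_id", "group")))
  ann[[nm]] <- cl[[nm]][match(ann$sample_id, cl$sample_id)]

write_expression(sim$expression, file.path(out_dir, "expression.tsv"))
write.table(ann, file.path(out_dir, "annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
truth_out <- sim$truth
truth_out$group <- as.list(truth_out$group)   # keep sample names in JSON
jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                     auto_unbox = TRUE)

cat(sprintf("cohort: %d genes x %d samples (%d tumors / %d normals)\n",
            nrow(sim$expression), ncol(sim$expression),
            sum(ann$tissue == "tumor"), sum(ann$tissue == "normal")))
cat(sprintf("planted: %d tumor-vs-normal DEGs (up incl. %d markers), %d down\n",
            length(sim$truth$deg_up), length(unlist(sim$truth$markers)),
            length(sim$truth$deg_down)))
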