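#!/usr/bin/env Rscript
# Stage 6 — survival by molecular subtype.
#
# Kaplan-Meier curves per recovered NMF group on the simulated cohort and
# the pooled multi-group log-rank test, plus the two-superset comparison
# (the low-hazard groups against the rest) that mirrors how favorable- and
# unfavorable-prognosis subtypes are contrasted.

suppressPackageStartupMessages(library(subtypenmf))

ann <- read_annotation("results/cohort/annotation.tsv")
labels <- read.table("results/labels.tsv", header = TRUE, sep = "\t")
groups <- setNames(labels$group, labels$sample_id)
tum <- ann[match(names(groups), ann$sample_id), ]

dir.create("results/survival", showWarnings = FALSE)
curves <- km_by_group(tum$time_months, tum$event, groups)
for (g in names(curves))
  write.table(curves[[g]], sprintf("results/survival/km_group%s.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)

lt <- logrank_test(tum$time_months, tum$event, groups)
cat(sprintf("pooled %d-group log-rank: X2 = %.2f (df = %d), p = %.4f\n",
            length(curves), lt$statistic, lt$df, lt$p))

# favorable (lowest event rates) vs the rest
events_per_group <- tapply(tum$event, groups, mean)
fav <- names(sort(events_per_group))[1:2]
super <- ifelse(groups %in% fav, "favorable", "other")
lt2 <- logrank_test(tum$time_months, tum$event, super)
cat(sprintf("groups {%s} vs rest log-rank: X2 = %.2f, p = %.4f\n",
            paste(fav, collapse = ","), lt2$statistic, lt2$p))
write.table(data.frame(comparison = c("all_groups", "favorable_vs_rest"),
                       statistic = c(lt$statistic, lt2$statistic),
                       df = c(lt$df, lt2$df), p = c(lt$p, lt2$p)),
            "results/survival/logrank.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
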