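#!/usr/bin/env Rscript
# ROC sensitivity: per-patient AUCs for T2L vs NAWM, T1L vs NAWM and
# T1L vs T2L for the four metrics plus the PCA composite, and the ten
# Bonferroni-corrected pairwise comparisons per problem.

# run from the repository root: Rscript analysis/06_roc_sensitivity.R
source("analysis/00_common.R")

out <- file.path(RESULTS, "06_roc")
dir.create(out, showWarnings = FALSE)

res <- get_run()

write.table(res$rocs, file.path(out, "roc_per_patient.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$roc_comparisons, file.path(out, "roc_comparisons.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

say("group mean +/- SD AUC per metric and classification problem:")
agg <- aggregate(auc ~ metric + problem, res$rocs, function(x)
  c(mean = mean(x), sd = sd(x)))
summary_tab <- data.frame(metric = agg$metric, problem = agg$problem,
                          mean_auc = round(agg$auc[, "mean"], 3),
                          sd_auc = round(agg$auc[, "sd"], 3))
print(summary_tab[order(summary_tab$problem, -summary_tab$mean_auc), ],
      row.names = FALSE)
write.table(summary_tab, file.path(out, "roc_group_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (pr in unique(res$roc_comparisons$problem)) {
  sub <- res$roc_comparisons[res$roc_comparisons$problem == pr, ]
  say("%s: %d/%d pairwise comparisons significant at 0.05/10", pr,
      sum(sub$significant), nrow(sub))
}
say("wrote %s", out)
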