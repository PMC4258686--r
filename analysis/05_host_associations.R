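#!/usr/bin/env Rscript
# Stage 5: enterotype associations with biomarkers and long-term diet.
#
# Traits and food groups are compared between enterotypes with two-sided
# Wilcoxon rank-sum tests (BH-adjusted within family).  Nutrients are
# first energy-adjusted (standardized residuals of nutrient ~ energy over
# complete cases), tested the same way, then clustered (UPGMA, Euclidean)
# both on all 23 residual profiles and on the enterotype-associated subset,
# with Fisher's exact test of cluster-enterotype association.  Finally,
# enterotype-discordant co-twins are contrasted with signed-rank tests.

library(enterotyper)

design <- read_twin_design("results/cohort/design.tsv")
metadata <- read_metadata_table("results/cohort/metadata.tsv")
assign_df <- read_assignments("results/enterotype_assignments.tsv")
ent <- setNames(assign_df$enterotype, assign_df$sample_id)

for (fam in c("trait", "food")) {
  res <- wilcoxon_association(metadata, ent, fam)
  write.table(res, sprintf("results/assoc_%ss.tsv", fam), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sig <- res[res$p_adj < 0.05, ]
  cat(sprintf("%ss: %d/%d significant at adj. P < 0.05\n", fam, nrow(sig),
              nrow(res)))
  for (i in seq_len(nrow(sig)))
    cat(sprintf("  %-14s adj. P = %.3g (%s)\n", sig$variable[i],
                sig$p_adj[i], sig$direction[i]))
}

resid <- energy_adjust(metadata)
cat(sprintf("energy adjustment over %d complete cases\n",
            attr(resid, "n_complete")))
res_df <- data.frame(sample_id = rownames(resid), as.data.frame(resid),
                     check.names = FALSE)
nut <- wilcoxon_association(res_df, ent, "nutrient",
                            variables = colnames(resid))
write.table(nut, "results/assoc_nutrients.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig_nut <- nut$variable[nut$p_adj < 0.05]
cat(sprintf("nutrients: %d/23 significant at adj. P < 0.05: %s\n",
            length(sig_nut), paste(sig_nut, collapse = ", ")))

all23 <- nutrient_cluster(resid, 2)
f_all <- fisher_association(all23$groups, ent)
cat(sprintf("2 groups on all 23 residuals vs enterotypes: Fisher P = %.3g\n",
            f_all$p_value))
if (length(sig_nut) >= 2L) {
  sub <- nutrient_cluster(resid, 2, subset = sig_nut)
  f_sub <- fisher_association(sub$groups, ent)
  cat(sprintf("2 groups on the %d associated residuals: Fisher P = %.3g\n",
              length(sig_nut), f_sub$p_value))
  write.table(data.frame(sample_id = names(sub$groups),
                         nutrient_group = sub$groups,
                         enterotype = ent[names(sub$groups)]),
              "results/nutrient_clusters.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
}

disc <- tryCatch(discordant_twin_test(metadata, design, ent),
                 error = function(e) NULL)
if (is.null(disc)) {
  cat("discordant-twin screen skipped (fewer than 2 discordant pairs)\n")
} else {
  write.table(disc, "results/discordant_twins.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("discordant-twin screen: %d/%d variables significant at FDR 5%%\n",
              sum(disc$significant), nrow(disc)))
}
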