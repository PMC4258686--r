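#!/usr/bin/env Rscript
# Stage 3: enterotype-enriched features and functional clusters.
#
# LEfSe-style differential abundance (rank-sum screen at alpha = 0.01,
# bootstrapped LDA effect size, |log10 score| >= 2) is run on the genus
# table between the two enterotypes; the KEGG pathway table is clustered
# the same way as the genus table and cross-tabulated against the
# enterotypes; LEfSe then contrasts the KEGG features between enterotypes.

library(enterotyper)

genus <- read_abundance_table("results/cohort/genus.tsv",
                              orientation = "samples_as_rows")
kegg <- read_abundance_table("results/cohort/kegg.tsv",
                             orientation = "samples_as_rows",
                             level = "kegg_pathway")
assign_df <- read_assignments("results/enterotype_assignments.tsv")
ent <- setNames(assign_df$enterotype, assign_df$sample_id)

gnorm <- normalize_profiles(genus)
knorm <- normalize_profiles(kegg)

lf <- lefse_run(gnorm, ent, alpha = 0.01, lda_threshold = 2, seed = 20141L)
write.table(lf, "results/lefse_genus.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("genus LEfSe: %d enriched features\n", nrow(lf)))
for (i in seq_len(nrow(lf)))
  cat(sprintf("  %-18s enterotype %s  LDA = %+0.2f\n", lf$feature_id[i],
              lf$enriched_class[i], lf$lda_score[i]))

kd <- pairwise_distance(knorm, "js")
kres <- select_k(kd, 2:6)
cat(sprintf("KEGG functional clustering: selected k = %d (support: %s)\n",
            kres$selected_k, kres$support))
ct <- crosstab_enterotype_function(
  setNames(ent[kres$sample_ids], kres$sample_ids), kres)
print(ct$counts)
print(ct$percent)
write.table(as.data.frame(ct$counts), "results/crosstab_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

klf <- lefse_run(knorm, ent, alpha = 0.01, lda_threshold = 2, seed = 20142L)
write.table(klf, "results/lefse_kegg.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("KEGG LEfSe: %d enriched pathways\n", nrow(klf)))
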