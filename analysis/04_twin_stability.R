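#!/usr/bin/env Rscript
# Stage 4: genetic and temporal stability of enterotypes.
#
# Concordance = share of pair-at-a-time-point observations where both
# co-twins hold the same enterotype; persistency = share of twice-sampled
# subjects keeping their enterotype.  Community distances are then
# stratified by relationship (same subject over time, co-twins at the
# same/different times, unrelated) and each related stratum is compared to
# the unrelated one with a one-sided two-sample permutation test
# (alternative: related distances are shorter).

library(enterotyper)

design <- read_twin_design("results/cohort/design.tsv")
genus <- read_abundance_table("results/cohort/genus.tsv",
                              orientation = "samples_as_rows")
assign_df <- read_assignments("results/enterotype_assignments.tsv")
ent <- setNames(assign_df$enterotype, assign_df$sample_id)

obs <- paired_observations(design, ent)
cr <- concordance_rate(obs)
cat(sprintf("concordance: %d/%d paired observations (%.1f%%)\n",
            cr$n_concordant, cr$n_total, cr$percent))
cat(sprintf("  concordant for enterotype 1: %s, for enterotype 2: %s\n",
            cr$by_enterotype[["1"]], cr$by_enterotype[["2"]]))

pr <- persistency_rate(design, ent)
cat(sprintf("persistency: %d/%d subjects stable over time (%.1f%%)\n",
            pr$n_stable, pr$n_longitudinal, pr$percent))
print(pr$transition_counts)

D <- pairwise_distance(normalize_profiles(genus), "js")
sets <- relationship_distance_sets(D, design)
cat("mean JS distance by relationship:\n")
rows <- list()
for (nm in names(sets))
  cat(sprintf("  %-16s n = %3d  mean = %.4f\n", nm, length(sets[[nm]]),
              mean(sets[[nm]])))
for (nm in c("self_over_time", "twin_same_time", "twin_diff_time")) {
  pt <- permutation_test(sets[[nm]], sets$unrelated, n_perm = 10000L,
                         alternative = "less", seed = 20143L)
  cat(sprintf("  %s vs unrelated: P = %.4f\n", nm, pt$p_value))
  rows[[nm]] <- data.frame(comparison = paste0(nm, "_vs_unrelated"),
                           n_x = length(sets[[nm]]),
                           n_y = length(sets$unrelated),
                           mean_diff = pt$statistic, p_value = pt$p_value)
}
write.table(do.call(rbind, rows), "results/twin_permutation_tests.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
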