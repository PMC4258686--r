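# End-to-end orchestration: normalize -> distances -> clustering (genus and
# KEGG) -> cross-tab -> LEfSe -> twin statistics -> host associations, with
# a single seed fanning out to per-stage streams.

#' Configure a pipeline run
#'
#' @param metrics distance metrics to cluster under (first is primary).
#' @param pseudocount pseudocount for [normalize_profiles()].
#' @param k_range cluster numbers to scan (`NULL` = `2:min(10, n-1)`).
#' @param markers marker genera for [label_enterotypes()].
#' @param lefse_alpha,lefse_lda_min,lefse_n_boot LEfSe parameters.
#' @param n_perm permutations for the distance-stratum tests.
#' @param perm_alternative alternative for the distance-stratum tests
#'   (default `"less"`: twin/self distances shorter than unrelated).
#' @param fdr FDR level for the discordant-twin screen.
#' @param associations run the metadata association block (needs metadata).
#' @param seed global seed; stages derive their own streams via
#'   [derive_seed()].
#' @return a `run_config` list.
#' @export
run_config <- function(metrics = c("js", "bc", "eu"), pseudocount = 1e-6,
                       k_range = NULL, markers = c("Bacteroides", "Prevotella"),
                       lefse_alpha = 0.01, lefse_lda_min = 2,
                       lefse_n_boot = 30L, n_perm = 10000L,
                       perm_alternative = "less", fdr = 0.05,
                       associations = TRUE, seed = 1L) {
  stopifnot(all(metrics %in% c("js", "bc", "eu")), length(metrics) >= 1L)
  structure(list(metrics = metrics, pseudocount = pseudocount,
                 k_range = k_range, markers = markers,
                 lefse_alpha = lefse_alpha, lefse_lda_min = lefse_lda_min,
                 lefse_n_boot = as.integer(lefse_n_boot),
                 n_perm = as.integer(n_perm),
                 perm_alternative = perm_alternative, fdr = fdr,
                 associations = associations, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full enterotyping and association pipeline
#'
#' Stages: profile normalization; pairwise distances under every configured
#' metric; PAM + CH/SI cluster-number selection per metric for the genus
#' table; enterotype labeling by marker dominance on the primary metric;
#' cross-metric agreement; functional clustering of the KEGG table (primary
#' metric); enterotype x functional-cluster cross-tab; LEfSe on genus and
#' KEGG features; twin concordance, persistency and relationship-stratified
#' permutation tests; and (if metadata is given and enabled) trait, food
#' and energy-adjusted nutrient associations, nutrient-profile clustering
#' with Fisher's exact enterotype association, and the discordant-twin
#' signed-rank screen.
#'
#' @param genus genus-level [abundance_table()].
#' @param design a `twin_design`.
#' @param kegg optional KEGG [abundance_table()].
#' @param metadata optional `metadata_table`.
#' @param config a [run_config()].
#' @return a `pipeline_bundle` list; see [report_summary()] and
#'   [summary_list()].
#' @export
run_enterotype_pipeline <- function(genus, design, kegg = NULL,
                                    metadata = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input validation"
  bundle <- tryCatch({
    joined <- join_cohort(genus, design, metadata)
    genus <- joined$abundance; design <- joined$design
    metadata <- joined$metadata

    stage <- "normalization and distances"
    gnorm <- normalize_profiles(genus, config$pseudocount)
    dists <- lapply(setNames(config$metrics, config$metrics),
                    function(mt) pairwise_distance(gnorm, mt))

    stage <- "genus clustering"
    cl <- lapply(dists, select_k, k_range = config$k_range)
    primary_metric <- config$metrics[1L]
    cl <- lapply(cl, label_enterotypes, t = gnorm, markers = config$markers)
    enterotypes <- setNames(cl[[primary_metric]]$assignments,
                            cl[[primary_metric]]$sample_ids)
    agreement <- list()
    for (mt in setdiff(config$metrics, primary_metric))
      agreement[[paste(primary_metric, mt, sep = "_vs_")]] <-
        cross_metric_agreement(cl[[primary_metric]]$assignments,
                               cl[[mt]]$assignments)

    stage <- "functional clustering"
    kegg_cl <- crosstab <- kegg_lefse <- NULL
    if (!is.null(kegg)) {
      kn <- normalize_profiles(
        abundance_table(unclass(kegg)[rownames(genus), , drop = FALSE],
                        level = attr(kegg, "level")), config$pseudocount)
      kd <- pairwise_distance(kn, primary_metric)
      kegg_cl <- select_k(kd, k_range = config$k_range)
      crosstab <- crosstab_enterotype_function(cl[[primary_metric]], kegg_cl)
    }

    stage <- "differential abundance"
    lefse_seed <- derive_seed(config$seed, "lefse")
    genus_lefse <- lefse_run(gnorm, enterotypes, alpha = config$lefse_alpha,
                             lda_threshold = config$lefse_lda_min,
                             n_boot = config$lefse_n_boot, seed = lefse_seed)
    if (!is.null(kegg))
      kegg_lefse <- lefse_run(kn, enterotypes, alpha = config$lefse_alpha,
                              lda_threshold = config$lefse_lda_min,
                              n_boot = config$lefse_n_boot,
                              seed = derive_seed(config$seed, "lefse_kegg"))

    stage <- "twin statistics"
    obs <- paired_observations(design, enterotypes)
    conc <- if (nrow(obs)) concordance_rate(obs) else NULL
    pers <- if (attr(design, "n_longitudinal") > 0L)
      persistency_rate(design, enterotypes) else NULL
    strata <- relationship_distance_sets(dists[[primary_metric]], design)
    perm_seed <- derive_seed(config$seed, "permutation")
    perm <- list()
    for (nm in c("self_over_time", "twin_same_time", "twin_diff_time")) {
      if (length(strata[[nm]]) && length(strata$unrelated))
        perm[[paste0(nm, "_vs_unrelated")]] <-
          permutation_test(strata[[nm]], strata$unrelated,
                           n_perm = config$n_perm,
                           alternative = config$perm_alternative,
                           seed = derive_seed(perm_seed, nm))
    }

    stage <- "host associations"
    assoc <- NULL
    if (config$associations && !is.null(metadata)) {
      assoc <- list()
      if (length(attr(metadata, "trait_cols")))
        assoc$traits <- wilcoxon_association(metadata, enterotypes, "trait")
      if (length(attr(metadata, "food_cols")))
        assoc$foods <- wilcoxon_association(metadata, enterotypes, "food")
      if (length(attr(metadata, "nutrient_cols")) &&
          !is.null(attr(metadata, "energy_col"))) {
        resid <- energy_adjust(metadata)
        res_df <- data.frame(sample_id = rownames(resid),
                             as.data.frame(resid), check.names = FALSE)
        assoc$nutrients <- wilcoxon_association(res_df, enterotypes,
                                                "nutrient",
                                                variables = colnames(resid))
        assoc$nutrient_residuals <- resid
        nc_all <- nutrient_cluster(resid, n_groups = 2L)
        assoc$nutrient_clusters_all <- nc_all$groups
        assoc$fisher_all <- fisher_association(nc_all$groups, enterotypes)
        assoc_nutr <- assoc$nutrients$variable[assoc$nutrients$p_adj < 0.05]
        if (length(assoc_nutr) >= 2L) {
          nc_sub <- nutrient_cluster(resid, n_groups = 2L, subset = assoc_nutr)
          assoc$nutrient_clusters_associated <- nc_sub$groups
          assoc$fisher_associated <- fisher_association(nc_sub$groups,
                                                        enterotypes)
        }
      }
      disc_try <- tryCatch(
        discordant_twin_test(metadata, design, enterotypes, fdr = config$fdr),
        error = function(e) NULL)
      assoc$discordant <- disc_try
    }

    list(config = config, n_samples = nrow(genus),
         distances = dists, clustering = cl, enterotypes = enterotypes,
         agreement = agreement, kegg_clustering = kegg_cl,
         crosstab = crosstab, genus_lefse = genus_lefse,
         kegg_lefse = kegg_lefse, paired_obs = obs, concordance = conc,
         persistency = pers, distance_strata = strata,
         permutation_tests = perm, associations = assoc)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(bundle) <- "pipeline_bundle"
  bundle
}

#' Machine-readable summary of a pipeline run
#'
#' Percentages are rounded to 1 decimal.  Serializing this list with
#' `jsonlite::write_json(..., auto_unbox = TRUE)` gives a stable
#' machine-readable run record.
#'
#' @param bundle a `pipeline_bundle`.
#' @return a plain named list.
#' @export
summary_list <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  cl <- bundle$clustering[[bundle$config$metrics[1L]]]
  counts <- table(bundle$enterotypes)
  out <- list(
    n_samples = bundle$n_samples,
    seed = bundle$config$seed,
    selected_k = setNames(lapply(bundle$clustering, `[[`, "selected_k"),
                          names(bundle$clustering)),
    silhouette_support = cl$support,
    enterotype_counts = as.list(setNames(as.integer(counts), names(counts))),
    enterotype_percent = as.list(setNames(
      round_half_up(100 * as.integer(counts) / sum(counts), 1), names(counts))),
    cross_metric_agreement = lapply(bundle$agreement, function(a)
      list(agreement = a$agreement, exact_match = a$exact_match)))
  if (!is.null(bundle$concordance))
    out$concordance <- bundle$concordance[c("n_concordant", "n_total", "percent")]
  if (!is.null(bundle$persistency))
    out$persistency <- c(bundle$persistency[c("n_stable", "n_longitudinal",
                                              "percent")],
                         list(transitions = as.data.frame(bundle$persistency$transition_counts)))
  if (!is.null(bundle$crosstab)) {
    out$kegg_selected_k <- bundle$kegg_clustering$selected_k
    out$crosstab_counts <- as.data.frame(bundle$crosstab$counts)
    out$crosstab_percent <- as.data.frame(bundle$crosstab$percent)
  }
  out$permutation_tests <- lapply(bundle$permutation_tests, function(p)
    p[c("p_value", "statistic", "alternative")])
  out$genus_lefse <- bundle$genus_lefse
  if (!is.null(bundle$kegg_lefse)) out$kegg_lefse <- bundle$kegg_lefse
  if (!is.null(bundle$associations)) {
    a <- bundle$associations
    out$associations <- list()
    for (nm in c("traits", "foods", "nutrients", "discordant"))
      if (!is.null(a[[nm]])) out$associations[[nm]] <- a[[nm]]
    if (!is.null(a$fisher_all))
      out$associations$fisher_all_nutrients_p <- a$fisher_all$p_value
    if (!is.null(a$fisher_associated))
      out$associations$fisher_associated_nutrients_p <- a$fisher_associated$p_value
  }
  out
}

#' Write the pipeline summary as JSON
#'
#' @param bundle a `pipeline_bundle`.
#' @param path output path.
#' @export
write_summary_json <- function(bundle, path) {
  jsonlite::write_json(summary_list(bundle), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Human-readable report of a pipeline run
#'
#' Prints the enterotype split, cross-metric agreement, twin concordance
#' and persistency with counts, the enterotype x functional-cluster
#' cross-tab, the permutation tests and the top host associations.
#'
#' @param bundle a `pipeline_bundle`.
#' @param max_assoc how many association rows to show per family.
#' @return the report lines, invisibly.
#' @export
report_summary <- function(bundle, max_assoc = 5L) {
  s <- summary_list(bundle)
  lines <- character()
  add <- function(...) lines <<- c(lines, sprintf(...))
  add("Enterotype analysis of %d samples (seed %d)", s$n_samples, s$seed)
  for (mt in names(s$selected_k))
    add("  %s: selected k = %d", mt, s$selected_k[[mt]])
  add("  silhouette support (primary metric): %s", s$silhouette_support)
  tot <- sum(unlist(s$enterotype_counts))
  for (e in names(s$enterotype_counts))
    add("  enterotype %s: %d/%d (%.1f%%)", e, s$enterotype_counts[[e]], tot,
        s$enterotype_percent[[e]])
  for (nm in names(s$cross_metric_agreement))
    add("  agreement %s: %.3f%s", nm, s$cross_metric_agreement[[nm]]$agreement,
        if (s$cross_metric_agreement[[nm]]$exact_match) " (identical partitions)" else "")
  if (!is.null(s$concordance))
    add("  twin concordance: %d/%d paired observations (%.1f%%)",
        s$concordance$n_concordant, s$concordance$n_total, s$concordance$percent)
  if (!is.null(s$persistency))
    add("  persistency over time: %d/%d subjects (%.1f%%)",
        s$persistency$n_stable, s$persistency$n_longitudinal,
        s$persistency$percent)
  if (!is.null(s$crosstab_counts)) {
    add("  functional clusters (KEGG, k = %d):", s$kegg_selected_k)
    ct <- bundle$crosstab$counts
    pc <- bundle$crosstab$percent
    for (i in seq_len(nrow(ct) - 1L))
      add("    %s: %s", rownames(ct)[i],
          paste(sprintf("%s %d (%.1f%%)", colnames(ct), ct[i, ], pc[i, ]),
                collapse = ", "))
  }
  for (nm in names(s$permutation_tests))
    add("  permutation %s: P = %.4f", nm, s$permutation_tests[[nm]]$p_value)
  if (nrow(bundle$genus_lefse))
    add("  LEfSe genus hits: %s",
        paste(sprintf("%s (%.2f)", bundle$genus_lefse$feature_id,
                      bundle$genus_lefse$lda_score), collapse = ", "))
  if (!is.null(s$associations)) {
    for (fam in c("traits", "foods", "nutrients")) {
      df <- s$associations[[fam]]
      if (is.null(df) || nrow(df) == 0L) next
      top <- head(df, max_assoc)
      add("  top %s associations:", fam)
      for (i in seq_len(nrow(top)))
        add("    %s: adj. P = %.3g (%s)", top$variable[i], top$p_adj[i],
            top$direction[i])
    }
    if (!is.null(s$associations$fisher_associated_nutrients_p))
      add("  Fisher (associated-nutrient clusters vs enterotypes): P = %.3g",
          s$associations$fisher_associated_nutrients_p)
    disc <- s$associations$discordant
    if (!is.null(disc))
      add("  discordant-twin screen: %d/%d variables significant at FDR %.0f%%",
          sum(disc$significant), nrow(disc), 100 * bundle$config$fdr)
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
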