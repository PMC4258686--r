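# Enterotype-host association tests: Wilcoxon rank-sum per variable with
# Benjamini-Hochberg adjustment within family, energy adjustment of
# nutrient intakes, hierarchical clustering of nutrient profiles, Fisher's
# exact association of cluster groups with enterotypes, and signed-rank
# tests within enterotype-discordant twin pairs.

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up procedure:
#' sorted ascending, `adj_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' mapped back to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_validation("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Wilcoxon rank-sum associations of variables with enterotype
#'
#' Runs a two-sided Wilcoxon rank-sum test per variable between the two
#' enterotypes (exact null when both groups have <= 10 non-missing values
#' and no ties, tie-corrected normal approximation otherwise), then adjusts
#' p-values with Benjamini-Hochberg within the variable family.  Variables
#' with fewer than 2 non-missing values in either group are skipped with a
#' message.
#'
#' @param metadata a `metadata_table` (or plain data.frame of numeric
#'   variables with a `sample_id` column).
#' @param enterotypes named enterotype vector or `clustering_result`.
#' @param family which metadata family to test: `"trait"`, `"food"` or
#'   `"nutrient"`; or supply `variables` explicitly.
#' @param variables optional explicit column names, overriding `family`.
#' @return data.frame with variable, family, n_1, n_2, statistic (rank-sum
#'   W), p, p_adj, direction (enterotype with the higher median).
#' @export
wilcoxon_association <- function(metadata, enterotypes,
                                 family = c("trait", "food", "nutrient"),
                                 variables = NULL) {
  family <- match.arg(family)
  enterotypes <- as_assignment_vector(enterotypes)
  if (is.null(variables)) {
    variables <- switch(family,
      trait = attr(metadata, "trait_cols"),
      food = attr(metadata, "food_cols"),
      nutrient = attr(metadata, "nutrient_cols"))
    if (is.null(variables))
      stop_validation("metadata has no recorded %s columns; pass `variables`", family)
  }
  md <- as.data.frame(metadata)
  ent <- enterotypes[md$sample_id]
  levs <- sort(unique(ent))
  if (length(levs) != 2L) stop_validation("exactly two enterotypes required")
  rows <- list()
  for (v in variables) {
    x <- md[[v]][ent == levs[1L]]
    y <- md[[v]][ent == levs[2L]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      message(sprintf("wilcoxon_association: skipping %s (a group has < 2 values)", v))
      next
    }
    wt <- suppressWarnings(wilcox.test(x, y, exact = length(x) <= 10L &&
                                         length(y) <= 10L &&
                                         !anyDuplicated(c(x, y))))
    rows[[v]] <- data.frame(
      variable = v, family = family, n_1 = length(x), n_2 = length(y),
      statistic = unname(wt$statistic), p = wt$p.value,
      direction = if (stats::median(y) > stats::median(x))
        paste0("higher_in_", levs[2L]) else paste0("higher_in_", levs[1L]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(variable = character(), family = character(),
                      n_1 = integer(), n_2 = integer(), statistic = numeric(),
                      p = numeric(), p_adj = numeric(), direction = character()))
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[order(out$p_adj, out$p), c("variable", "family", "n_1", "n_2",
                                 "statistic", "p", "p_adj", "direction")]
}

#' Energy-adjusted nutrient intakes
#'
#' For each nutrient, ordinary least squares of the nutrient's daily intake
#' on energy intake (with intercept) over complete cases; residuals are
#' standardized to mean 0, sd 1.  Nutrients with zero residual variance
#' yield an all-zero column with a warning.
#'
#' @param metadata a `metadata_table` with nutrient columns and an energy
#'   column.
#' @return matrix of standardized residuals (complete-case samples x
#'   nutrients), rownames = sample ids; attribute `n_complete` records the
#'   complete-case count.
#' @export
energy_adjust <- function(metadata) {
  nutr <- attr(metadata, "nutrient_cols")
  en <- attr(metadata, "energy_col")
  if (is.null(nutr) || length(nutr) == 0L || is.null(en))
    stop_validation("metadata lacks nutrient and/or energy columns")
  md <- as.data.frame(metadata)
  complete <- !is.na(md[[en]]) & stats::complete.cases(md[, nutr, drop = FALSE])
  if (sum(complete) < 3L)
    stop_validation("fewer than 3 complete cases for energy adjustment")
  md <- md[complete, , drop = FALSE]
  out <- matrix(NA_real_, nrow(md), length(nutr),
                dimnames = list(md$sample_id, sub("^nutr_", "", nutr)))
  for (i in seq_along(nutr)) {
    r <- residuals(lm(md[[nutr[i]]] ~ md[[en]]))
    # relative tolerance: an exact linear dependence leaves only rounding
    if (sd(r) <= 1e-10 * max(1, sd(md[[nutr[i]]]))) {
      warning(sprintf("nutrient %s has zero residual variance; residuals set to 0", nutr[i]))
      out[, i] <- 0
    } else out[, i] <- as.numeric(scale(r))
  }
  attr(out, "n_complete") <- nrow(md)
  out
}

#' Hierarchical clustering of nutrient-residual profiles
#'
#' Agglomerative UPGMA (average linkage) on the Euclidean distance between
#' samples' standardized nutrient residuals, cut into `n_groups` groups.
#'
#' @param residuals matrix from [energy_adjust()].
#' @param n_groups number of groups to cut (default 2).
#' @param subset optional nutrient-name subset (e.g. the nine
#'   enterotype-associated nutrients).
#' @return list with `groups` (named integer vector), `hclust` (the tree)
#'   and `merge_heights`.
#' @export
nutrient_cluster <- function(residuals, n_groups = 2L, subset = NULL) {
  m <- residuals
  if (!is.null(subset)) {
    miss <- setdiff(subset, colnames(m))
    if (length(miss))
      stop_validation("nutrient(s) not present: %s", paste(miss, collapse = ", "))
    m <- m[, subset, drop = FALSE]
  }
  if (nrow(m) < n_groups)
    stop_validation("fewer samples than requested groups")
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  list(groups = cutree(hc, k = n_groups), hclust = hc,
       merge_heights = hc$height)
}

#' Fisher's exact association between cluster groups and enterotypes
#'
#' Two-sided exact test on the 2x2 contingency table, using the
#' probability-mass rule (sum over tables no more probable than the
#' observed one).
#'
#' @param groups named group labels (2 levels) from [nutrient_cluster()].
#' @param enterotypes named enterotype vector or `clustering_result`;
#'   restricted to the samples present in `groups`.
#' @return list with `p_value`, `table`.
#' @export
fisher_association <- function(groups, enterotypes) {
  enterotypes <- as_assignment_vector(enterotypes)
  ids <- intersect(names(groups), names(enterotypes))
  if (length(ids) == 0L) stop_validation("no shared samples")
  tab <- table(group = groups[ids], enterotype = enterotypes[ids])
  if (!all(dim(tab) == c(2L, 2L)))
    stop_validation("fisher_association needs a 2x2 table (got %dx%d)",
                    nrow(tab), ncol(tab))
  list(p_value = fisher.test(tab)$p.value, table = tab)
}

#' Wilcoxon signed-rank tests within enterotype-discordant twin pairs
#'
#' For each variable, computes the within-pair difference (enterotype-2
#' co-twin minus enterotype-1 co-twin) over discordant pair-at-a-time-point
#' observations and runs a two-sided Wilcoxon signed-rank test (exact when
#' <= 10 non-zero differences without ties).  Zero differences are dropped
#' (standard Wilcoxon convention); if all differences are zero the variable
#' gets p = 1 with a warning.  P-values are BH-adjusted across variables.
#'
#' @param metadata a `metadata_table`.
#' @param design a `twin_design`.
#' @param assignments named enterotype vector or `clustering_result`.
#' @param variables columns to test; default all trait, food and nutrient
#'   columns.
#' @param fdr the FDR level used to flag `significant` (default 0.05).
#' @return data.frame with variable, n_pairs, statistic (V), p, p_adj,
#'   significant.
#' @export
discordant_twin_test <- function(metadata, design, assignments,
                                 variables = NULL, fdr = 0.05) {
  assignments <- as_assignment_vector(assignments)
  obs <- paired_observations(design, assignments)
  disc <- obs[!obs$concordant, , drop = FALSE]
  if (nrow(disc) < 2L)
    stop_validation("need at least 2 discordant paired observations")
  if (is.null(variables))
    variables <- c(attr(metadata, "trait_cols"), attr(metadata, "food_cols"),
                   attr(metadata, "nutrient_cols"))
  md <- as.data.frame(metadata)
  de <- as.data.frame(design)
  value_of <- function(v, pair, tp, ent) {
    sids <- de$sample_id[de$pair_id == pair & de$time_point == tp]
    sids <- sids[assignments[sids] == ent]
    md[[v]][match(sids[1L], md$sample_id)]
  }
  rows <- list()
  for (v in variables) {
    diffs <- vapply(seq_len(nrow(disc)), function(i) {
      v2 <- value_of(v, disc$pair_id[i], disc$time_point[i], 2L)
      v1 <- value_of(v, disc$pair_id[i], disc$time_point[i], 1L)
      v2 - v1
    }, numeric(1L))
    diffs <- diffs[!is.na(diffs)]
    if (length(diffs) < 2L) next
    nz <- diffs[diffs != 0]
    if (length(nz) == 0L) {
      warning(sprintf("all within-pair differences are zero for %s", v))
      rows[[v]] <- data.frame(variable = v, n_pairs = length(diffs),
                              statistic = NA_real_, p = 1,
                              stringsAsFactors = FALSE)
      next
    }
    wt <- suppressWarnings(wilcox.test(nz, exact = length(nz) <= 10L &&
                                         !anyDuplicated(abs(nz))))
    rows[[v]] <- data.frame(variable = v, n_pairs = length(diffs),
                            statistic = unname(wt$statistic), p = wt$p.value,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(variable = character(), n_pairs = integer(),
                      statistic = numeric(), p = numeric(),
                      p_adj = numeric(), significant = logical()))
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < fdr
  rownames(out) <- NULL
  out[order(out$p_adj, out$p), ]
}
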