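# Twin concordance, longitudinal persistency, and relationship-stratified
# permutation tests on community distances.

#' Build pair-at-a-time-point observations
#'
#' One observation per (pair, time point) at which both co-twins were
#' sampled, carrying the two co-twins' enterotype labels.
#'
#' @param design a `twin_design`.
#' @param assignments named integer vector of enterotype labels (names =
#'   sample ids), or a `clustering_result`.
#' @return data.frame with pair_id, time_point, enterotype_a, enterotype_b,
#'   concordant.
#' @export
paired_observations <- function(design, assignments) {
  assignments <- as_assignment_vector(assignments)
  miss <- setdiff(design$sample_id, names(assignments))
  if (length(miss))
    stop_validation("no enterotype assignment for sample(s): %s",
                    paste(head(miss, 3L), collapse = ", "))
  out <- list()
  for (d in split(as.data.frame(design),
                  list(design$pair_id, design$time_point), drop = TRUE)) {
    if (nrow(d) != 2L) next
    ea <- assignments[[d$sample_id[1L]]]
    eb <- assignments[[d$sample_id[2L]]]
    out[[length(out) + 1L]] <- data.frame(
      pair_id = d$pair_id[1L], time_point = d$time_point[1L],
      enterotype_a = ea, enterotype_b = eb, concordant = ea == eb,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(pair_id = character(), time_point = integer(),
                      enterotype_a = integer(), enterotype_b = integer(),
                      concordant = logical()))
  do.call(rbind, out)
}

as_assignment_vector <- function(assignments) {
  if (inherits(assignments, "clustering_result"))
    return(setNames(assignments$assignments, assignments$sample_ids))
  if (is.null(names(assignments)))
    stop_validation("assignments must be named by sample id")
  assignments
}

#' Twin-pair enterotype concordance rate
#'
#' Percentage of pair-at-a-time-point observations in which both co-twins
#' share the enterotype.  The denominator is paired observations (pair x
#' time), not pairs.
#'
#' @param obs data.frame from [paired_observations()].
#' @return list with `n_concordant`, `n_total`, `percent` (1 decimal) and
#'   `by_enterotype` (concordant counts per shared enterotype).
#' @export
concordance_rate <- function(obs) {
  if (nrow(obs) == 0L) stop_validation("no paired observations")
  n_total <- nrow(obs)
  n_conc <- sum(obs$concordant)
  by_ent <- table(factor(obs$enterotype_a[obs$concordant]))
  list(n_concordant = n_conc, n_total = n_total,
       percent = round_half_up(100 * n_conc / n_total, 1),
       by_enterotype = by_ent)
}

#' Longitudinal enterotype persistency rate
#'
#' Percentage of subjects sampled at both time points that keep the same
#' enterotype, plus the 2x2 time-1 x time-2 transition table.
#'
#' @param design a `twin_design`.
#' @param assignments named enterotype vector or `clustering_result`.
#' @return list with `n_stable`, `n_longitudinal`, `percent` (1 decimal)
#'   and `transition_counts` (enterotype at time 1 x enterotype at time 2).
#' @export
persistency_rate <- function(design, assignments) {
  assignments <- as_assignment_vector(assignments)
  by_subj <- split(as.data.frame(design), design$subject_id)
  long <- by_subj[vapply(by_subj, function(d) length(unique(d$time_point)) == 2L,
                         logical(1L))]
  if (length(long) == 0L) stop_validation("no subjects sampled at both time points")
  levs <- sort(unique(assignments))
  e1 <- e2 <- integer(length(long))
  for (i in seq_along(long)) {
    d <- long[[i]][order(long[[i]]$time_point), ]
    e1[i] <- assignments[[d$sample_id[1L]]]
    e2[i] <- assignments[[d$sample_id[2L]]]
  }
  trans <- table(time1 = factor(e1, levels = levs),
                 time2 = factor(e2, levels = levs))
  n_stable <- sum(e1 == e2)
  list(n_stable = n_stable, n_longitudinal = length(long),
       percent = round_half_up(100 * n_stable / length(long), 1),
       transition_counts = trans)
}

#' Stratify pairwise distances by twin relationship
#'
#' Every unordered pair of distinct samples falls in exactly one stratum:
#' `self_over_time` (same subject, different time points),
#' `twin_same_time` (co-twins at the same time point), `twin_diff_time`
#' (co-twins at different time points) or `unrelated` (different twin
#' pairs).
#'
#' @param D a [distance_matrix()].
#' @param design a `twin_design` covering all samples in `D`.
#' @return list of four numeric distance vectors, named as above.
#' @export
relationship_distance_sets <- function(D, design) {
  ids <- rownames(D)
  miss <- setdiff(ids, design$sample_id)
  if (length(miss))
    stop_validation("sample(s) missing from design: %s",
                    paste(head(miss, 3L), collapse = ", "))
  idx <- match(ids, design$sample_id)
  subj <- design$subject_id[idx]
  pair <- design$pair_id[idx]
  tp <- design$time_point[idx]
  sets <- list(self_over_time = numeric(), twin_same_time = numeric(),
               twin_diff_time = numeric(), unrelated = numeric())
  n <- length(ids)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- unclass(D)[i, j]
    key <- if (subj[i] == subj[j]) "self_over_time"
      else if (pair[i] == pair[j] && tp[i] == tp[j]) "twin_same_time"
      else if (pair[i] == pair[j]) "twin_diff_time"
      else "unrelated"
    sets[[key]] <- c(sets[[key]], d)
  }
  sets
}

#' Two-sample permutation test on distance sets
#'
#' Statistic: `mean(x) - mean(y)`.  The null is built by re-assigning the
#' pooled values at random to two sets of the original sizes, `n_perm`
#' times.  P-values use the add-one estimator
#' `(1 + #extreme) / (1 + n_perm)`, so they are never zero.
#'
#' The permutation unit is the individual distance value; distances sharing
#' a sample are dependent, so p-values are approximate in the usual way for
#' naive pooling of pairwise distances.
#'
#' @param x,y numeric vectors.
#' @param n_perm number of permutations (default 10000).
#' @param alternative `"less"` (mean(x) smaller), `"greater"` or
#'   `"two_sided"`.
#' @param seed optional RNG seed for the permutation stream.
#' @return list with `p_value`, `statistic`, `n_perm`, `alternative`.
#' @export
permutation_test <- function(x, y, n_perm = 10000L,
                             alternative = c("less", "greater", "two_sided"),
                             seed = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop_validation("both distance sets must be non-empty")
  if (n_perm < 1L) stop_validation("n_perm must be >= 1")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  nx <- length(x); ntot <- length(pooled)
  tot <- sum(pooled)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    sx <- sum(pooled[sample.int(ntot, nx)])
    sx / nx - (tot - sx) / (ntot - nx)
  }, numeric(1L))
  eps <- 1e-12
  extreme <- switch(alternative,
    less = sum(null_stats <= obs + eps),
    greater = sum(null_stats >= obs - eps),
    two_sided = sum(abs(null_stats) >= abs(obs) - eps))
  list(p_value = (1 + extreme) / (1 + n_perm), statistic = obs,
       n_perm = n_perm, alternative = alternative)
}

#' Permutation test with design slots as the permutation unit
#'
#' Alternative to [permutation_test()] for relationship-stratified distance
#' comparisons: randomly re-associates samples with the design's
#' (subject, pair, time) slots, rebuilds the two strata under each permuted
#' design, and recomputes the mean difference.  This respects the
#' dependence among distances sharing a sample.
#'
#' @param D a [distance_matrix()].
#' @param design a `twin_design`.
#' @param set_x,set_y names of two strata from
#'   [relationship_distance_sets()].
#' @param n_perm permutations.
#' @param alternative as in [permutation_test()].
#' @param seed RNG seed.
#' @return list as in [permutation_test()].
#' @export
permutation_test_subjects <- function(D, design, set_x, set_y,
                                      n_perm = 1000L,
                                      alternative = c("less", "greater",
                                                      "two_sided"),
                                      seed = NULL) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  stat <- function(de) {
    s <- relationship_distance_sets(D, de)
    mean(s[[set_x]]) - mean(s[[set_y]])
  }
  obs <- stat(design)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    de <- as.data.frame(design)
    de$sample_id <- sample(de$sample_id)
    stat(de)
  }, numeric(1L))
  eps <- 1e-12
  extreme <- switch(alternative,
    less = sum(null_stats <= obs + eps),
    greater = sum(null_stats >= obs - eps),
    two_sided = sum(abs(null_stats) >= abs(obs) - eps))
  list(p_value = (1 + extreme) / (1 + n_perm), statistic = obs,
       n_perm = n_perm, alternative = alternative)
}
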