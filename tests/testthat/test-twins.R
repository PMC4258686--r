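# Twin concordance, persistency, relationship strata and permutation tests.

table1_assignments <- function() {
  # enterotype assignment reproducing the published pair-level counts:
  # 18 paired observations = 13 concordant (5 enterotype 1, 8 enterotype 2)
  # + 5 discordant from 4 pairs (3 pairs at one time point, 1 at both);
  # 16 longitudinal subjects of which 3 switch
  d <- paper_design()
  ent <- setNames(integer(nrow(d)), d$sample_id)
  for (i in seq_len(nrow(d))) {
    p <- d$pair_id[i]; tw <- d$subject_id[i]; tm <- d$time_point[i]
    ent[d$sample_id[i]] <-
      if (p %in% c("P01", "P02")) 1L              # E1-concordant at both times
      else if (p %in% c("P03", "P04")) 2L         # E2-concordant at both times
      else if (p %in% c("P05", "P06", "P08"))     # E2-concordant at t1,
        (if (tm == 1L) 2L                         # discordant at t2
         else if (endsWith(tw, "T1")) 1L else 2L) # (first twin switches)
      else if (p == "P07")                        # discordant at both times
        (if (endsWith(tw, "T1")) 1L else 2L)
      else if (p == "P09") 1L                     # single-time, E1-concordant
      else 2L                                     # P10 single-time, E2-concordant
  }
  list(design = d, ent = ent)
}

test_that("concordance over paired observations reproduces the published counts", {
  fx <- table1_assignments()
  obs <- paired_observations(fx$design, fx$ent)
  expect_equal(nrow(obs), 18L)
  cr <- concordance_rate(obs)
  expect_equal(cr$n_total, 18L)
  expect_equal(cr$n_concordant, 13L)
  expect_equal(cr$percent, 72.2)
  expect_equal(unname(cr$by_enterotype["1"]), 5L)
  expect_equal(unname(cr$by_enterotype["2"]), 8L)
})

test_that("persistency over longitudinal subjects reproduces the published rate", {
  fx <- table1_assignments()
  pr <- persistency_rate(fx$design, fx$ent)
  expect_equal(pr$n_longitudinal, 16L)
  expect_equal(pr$n_stable, 13L)
  expect_equal(pr$percent, 81.3)
  # transition rows conserve the time-1 margins: 5 subjects start in E1
  # (pairs P01, P02, and the discordant P07 first twin), 11 in E2
  expect_equal(unname(rowSums(pr$transition_counts)), c(5, 11))
  expect_equal(sum(pr$transition_counts), 16)
})

test_that("degenerate concordance and persistency rates", {
  d <- twin_design(data.frame(
    sample_id = c("a1", "a2", "b1", "b2"),
    subject_id = c("s1", "s2", "s3", "s4"),
    pair_id = c("p1", "p1", "p2", "p2"), time_point = 1L))
  all_same <- setNames(rep(1L, 4), d$sample_id)
  expect_equal(concordance_rate(paired_observations(d, all_same))$percent, 100.0)
  half <- setNames(c(1L, 1L, 1L, 2L), d$sample_id)
  expect_equal(concordance_rate(paired_observations(d, half))$percent, 50.0)
  expect_error(persistency_rate(d, all_same), "both time points")
  expect_error(concordance_rate(paired_observations(d, all_same)[0, ]),
               "no paired observations")
})

test_that("relationship strata have the study's cardinalities and conserve pairs", {
  d <- paper_design()
  D <- random_euclidean_dist(36, seed = 3)
  D <- distance_matrix(unclass(D), metric = "js", sample_ids = d$sample_id)
  sets <- relationship_distance_sets(D, d)
  expect_length(sets$self_over_time, 16L)
  expect_length(sets$twin_same_time, 18L)
  # twin-diff-time: 8 longitudinal pairs x 2 cross-time co-twin pairs
  expect_length(sets$twin_diff_time, 16L)
  total <- sum(lengths(sets))
  expect_equal(total, choose(36, 2))

  # two unrelated singletons
  d2 <- twin_design(data.frame(
    sample_id = c("a", "b", "c", "d"),
    subject_id = c("s1", "s2", "s3", "s4"),
    pair_id = c("p1", "p1", "p2", "p2"), time_point = 1L))
  D2 <- random_euclidean_dist(4, seed = 1)
  D2 <- distance_matrix(unclass(D2), "js", sample_ids = d2$sample_id)
  sets2 <- relationship_distance_sets(D2, d2)
  expect_length(sets2$self_over_time, 0L)
  expect_length(sets2$unrelated, 4L)
  expect_length(sets2$twin_same_time, 2L)
})

test_that("permutation p-values: identical sets give 1, extreme splits the add-one floor", {
  x <- rep(1, 5); y <- rep(1, 7)
  expect_equal(permutation_test(x, y, n_perm = 99L, seed = 1L)$p_value, 1)

  x2 <- 1:6; y2 <- 101:108
  p <- permutation_test(x2, y2, n_perm = 10000L, alternative = "less",
                        seed = 2L)$p_value
  # only splits assigning the 6 smallest pooled values to x achieve the
  # observed statistic: expected extreme fraction 1/C(14,6) = 1/3003
  expect_lte(p, (1 + ceiling(3 * 10000 / 3003)) / 10001)
  expect_gte(p, 1 / 10001)
})

test_that("permutation p-values stay in (0, 1] and the two one-sided tests overlap", {
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(9)
    pl <- permutation_test(x, y, n_perm = 200L, alternative = "less",
                           seed = i)$p_value
    pg <- permutation_test(x, y, n_perm = 200L, alternative = "greater",
                           seed = i)$p_value
    expect_gt(pl, 0); expect_lte(pl, 1)
    expect_gte(pl + pg, 1)
  }
})

test_that("permutation test is calibrated under the null", {
  set.seed(83)
  rej <- vapply(1:500, function(i) {
    x <- rnorm(12); y <- rnorm(12)
    permutation_test(x, y, n_perm = 300L,
                     alternative = "two_sided")$p_value < 0.05
  }, logical(1L))
  expect_gte(mean(rej), 0.025)
  expect_lte(mean(rej), 0.075)
})

test_that("within-subject distances are shorter than unrelated on correlated cohorts", {
  co <- generate_twin_cohort(cohort_spec(n_pairs = 10L, seed = 53L))
  g <- normalize_profiles(co$genus)
  D <- pairwise_distance(g, "js")
  sets <- relationship_distance_sets(D, co$design)
  expect_lt(mean(sets$self_over_time), mean(sets$unrelated))
  p <- permutation_test(sets$self_over_time, sets$unrelated,
                        n_perm = 2000L, alternative = "less", seed = 5L)$p_value
  expect_lt(p, 0.05)
})

test_that("the design-slot permutation mode agrees directionally with naive pooling", {
  co <- generate_twin_cohort(cohort_spec(n_pairs = 8L, seed = 59L))
  g <- normalize_profiles(co$genus)
  D <- pairwise_distance(g, "js")
  p <- permutation_test_subjects(D, co$design, "self_over_time", "unrelated",
                                 n_perm = 200L, alternative = "less",
                                 seed = 7L)
  expect_lt(p$p_value, 0.5)
  expect_lt(p$statistic, 0)
})
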