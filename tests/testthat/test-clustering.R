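# PAM, cluster-quality indices, k selection, labeling and cross-tabs.

test_that("pam with k = n makes every point a medoid at zero cost", {
  D <- random_euclidean_dist(5, seed = 1)
  fit <- pam_cluster(D, 5)
  expect_equal(fit$medoids, 1:5)
  expect_equal(fit$total_cost, 0)
  expect_error(pam_cluster(D, 6), "k must be")
})

test_that("pam separates two well-separated blobs and matches exhaustive cost", {
  centers <- list(c(10, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.1, 10))
  ab <- blob_abundance(c(4, 4), centers, noise = 0.005, seed = 3)
  D <- pairwise_distance(normalize_profiles(ab), "js")
  fit <- pam_cluster(D, 2)
  expect_equal(fit$assignments[1:4], rep(fit$assignments[1], 4))
  expect_equal(fit$assignments[5:8], rep(fit$assignments[5], 4))
  expect_equal(fit$total_cost, brute_force_pam_cost(unclass(D), 2),
               tolerance = 1e-12)
})

test_that("pam equals exhaustive medoid search on 50 random instances", {
  set.seed(404)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    D <- random_euclidean_dist(n, seed = 1000 + i)
    fit <- pam_cluster(D, k)
    expect_equal(fit$total_cost, brute_force_pam_cost(unclass(D), k),
                 tolerance = 1e-10)
  }
})

test_that("the BUILD+SWAP local search matches the cluster package and bounds the optimum", {
  skip_if_not_installed("cluster")
  n_local_optima <- 0L
  for (i in 1:25) {
    D <- random_euclidean_dist(8, seed = 2000 + i)
    ours <- pam_cluster(D, 2, method = "build_swap")
    exact <- pam_cluster(D, 2, method = "exhaustive")
    ref <- cluster::pam(stats::as.dist(unclass(D)), k = 2, diss = TRUE)
    ref_cost <- sum(unclass(D)[cbind(seq_len(8), ref$id.med[ref$clustering])])
    # same local search as the reference implementation
    expect_equal(ours$total_cost, ref_cost, tolerance = 1e-10)
    # a local search can only sit at or above the exact optimum
    expect_gte(ours$total_cost, exact$total_cost - 1e-10)
    if (ours$total_cost > exact$total_cost + 1e-10)
      n_local_optima <- n_local_optima + 1L
  }
  # swap-local optima above the true minimum exist but are the exception
  expect_lte(n_local_optima, 5L)
})

test_that("duplicated samples are always co-assigned", {
  m <- rbind(S1 = c(0.9, 0.1), S2 = c(0.9, 0.1), S3 = c(0.1, 0.9),
             S4 = c(0.15, 0.85))
  D <- pairwise_distance(abundance_table(m), "eu")
  fit <- pam_cluster(D, 2)
  expect_equal(fit$assignments[1], fit$assignments[2])
})

test_that("ch_index matches hand arithmetic and prefers the planted split", {
  # 6 points on a line: two tight triplets {0, 1, 2} and {10, 11, 12}
  x <- c(0, 1, 2, 10, 11, 12)
  D <- distance_matrix(as.matrix(dist(x)), metric = "eu",
                       sample_ids = paste0("S", 1:6))
  assign2 <- c(1, 1, 1, 2, 2, 2)
  # by hand: cluster medoids are x=1 and x=11; overall medoid minimizes
  # total distance (x=2, total 30; ties none).  W = (1+0+1) + (1+0+1) = 4
  # (squared distances to own medoid), B = 3*d(1,2)^2 + 3*d(11,2)^2
  W <- 1 + 0 + 1 + 1 + 0 + 1
  B <- 3 * (1)^2 + 3 * (9)^2
  expect_equal(ch_index(D, assign2), (B / 1) / (W / 4), tolerance = 1e-12)
  # an arbitrary split of the same data scores strictly lower
  expect_gt(ch_index(D, assign2), ch_index(D, c(1, 2, 1, 2, 1, 2)))
  expect_error(ch_index(D, rep(1, 6)), "one cluster")
})

test_that("ch_index returns the +Inf sentinel for zero within-cluster spread", {
  m <- rbind(S1 = c(1, 0), S2 = c(1, 0), S3 = c(0, 1), S4 = c(0, 1))
  D <- pairwise_distance(abundance_table(m), "eu")
  expect_equal(ch_index(D, c(1, 1, 2, 2)), Inf)
})

test_that("silhouette follows its formula, categories and edge cases", {
  # two tight duplicate clusters: a = 0, b > 0 -> SI = 1, strong
  m <- rbind(S1 = c(1, 0), S2 = c(1, 0), S3 = c(0, 1), S4 = c(0, 1))
  D <- pairwise_distance(abundance_table(m), "eu")
  sil <- silhouette_index(D, c(1, 1, 2, 2))
  expect_equal(sil$si, 1)
  expect_equal(sil$support, "strong")

  # all pairwise distances equal: any 2-split has s(i) <= 0 everywhere
  De <- distance_matrix(matrix(1, 4, 4) - diag(4), metric = "eu",
                        sample_ids = paste0("S", 1:4))
  sil2 <- silhouette_index(De, c(1, 1, 2, 2))
  # by hand: a(i) = 1, b(i) = 1 -> s(i) = 0 for every point
  expect_equal(sil2$widths, rep(0, 4))
  expect_lte(sil2$si, 0)

  expect_equal(silhouette_support(0.3), "weak")
  expect_equal(silhouette_support(0.25), "none")
  expect_equal(silhouette_support(0.6), "reasonable")

  # singleton cluster gets width 0
  sil3 <- silhouette_index(De, c(1, 2, 2, 2))
  expect_equal(sil3$widths[1], 0)
})

test_that("CH and SI are invariant under relabeling and sample reordering", {
  D <- random_euclidean_dist(9, seed = 12)
  assign <- c(1, 2, 1, 2, 1, 2, 3, 3, 3)
  relab <- c(3, 1, 3, 1, 3, 1, 2, 2, 2)
  expect_equal(ch_index(D, assign), ch_index(D, relab), tolerance = 1e-12)
  expect_equal(silhouette_index(D, assign)$si,
               silhouette_index(D, relab)$si, tolerance = 1e-12)
  ord <- c(5, 1, 9, 2, 8, 3, 7, 4, 6)
  Dp <- distance_matrix(unclass(D)[ord, ord], metric = "eu",
                        sample_ids = rownames(D)[ord])
  expect_equal(ch_index(Dp, assign[ord]), ch_index(D, assign),
               tolerance = 1e-12)
  expect_equal(silhouette_index(Dp, assign[ord])$si,
               silhouette_index(D, assign)$si, tolerance = 1e-12)
})

test_that("select_k picks the planted component count", {
  co <- generate_twin_cohort(cohort_spec(n_pairs = 10L, seed = 19L))
  g <- normalize_profiles(co$genus)
  res <- select_k(pairwise_distance(g, "js"), 2:6)
  expect_equal(res$selected_k, 2L)

  # three planted blobs
  centers <- list(c(10, 0.1, 0.1, 0.1, 0.1), c(0.1, 10, 0.1, 0.1, 0.1),
                  c(0.1, 0.1, 10, 0.1, 0.1))
  ab <- blob_abundance(c(6, 6, 6), centers, noise = 0.02, seed = 23)
  res3 <- select_k(pairwise_distance(normalize_profiles(ab), "js"), 2:6)
  expect_equal(res3$selected_k, 3L)

  # n = 3: a single scannable k
  ab3 <- blob_abundance(c(2, 1), list(c(5, 1), c(1, 5)), noise = 0.01, seed = 2)
  res1 <- select_k(pairwise_distance(normalize_profiles(ab3), "eu"), 2:2)
  expect_equal(res1$selected_k, 2L)
})

test_that("enterotype labels follow marker dominance with a size fallback", {
  co <- generate_twin_cohort(cohort_spec(n_pairs = 10L, seed = 29L))
  g <- normalize_profiles(co$genus)
  res <- label_enterotypes(select_k(pairwise_distance(g, "js"), 2:4), g)
  bact <- unclass(g)[, "Bacteroides"]
  expect_gt(mean(bact[res$assignments == 1]), mean(bact[res$assignments == 2]))
  # label permutation leaves the partition unchanged
  expect_true(cross_metric_agreement(
    res$assignments, 3 - res$assignments)$exact_match)
  # markers absent: fall back to size ordering with a warning
  g2 <- abundance_table(unclass(g), feature_ids = paste0("X", seq_len(ncol(g))))
  expect_warning(res2 <- label_enterotypes(select_k(pairwise_distance(g2, "js"), 2:2), g2),
                 "decreasing cluster size")
  expect_gte(sum(res2$assignments == 1), sum(res2$assignments == 2))
})

test_that("cross-metric agreement matches labels up to permutation", {
  a <- c(1, 1, 2, 2, 2)
  expect_true(cross_metric_agreement(a, c(2, 2, 1, 1, 1))$exact_match)
  moved <- c(1, 1, 2, 2, 1)
  expect_equal(cross_metric_agreement(a, moved)$agreement, 4 / 5)
  expect_false(cross_metric_agreement(a, moved)$exact_match)
  # independent k = 2 partitions at n = 100: best-permutation agreement of
  # two fair coins concentrates a little above 1/2
  set.seed(55)
  ag <- replicate(50, cross_metric_agreement(
    sample(1:2, 100, TRUE), sample(1:2, 100, TRUE))$agreement)
  expect_gt(mean(ag), 0.5)
  expect_lt(mean(ag), 0.65)
  expect_error(cross_metric_agreement(setNames(a, paste0("S", 1:5)),
                                      setNames(a, paste0("T", 1:5))),
               "different samples")
})

test_that("the enterotype x functional-cluster cross-tab reproduces printed layouts", {
  # 36 samples: 15 enterotype-1 (8 functionally with cluster 1, 7 with 2),
  # 21 enterotype-2 all in functional cluster 2
  ent <- setNames(rep(c(1L, 2L), c(15L, 21L)), paste0("S", 1:36))
  fun <- setNames(rep(c(1L, 2L, 2L), c(8L, 7L, 21L)), paste0("S", 1:36))
  ct <- crosstab_enterotype_function(ent, fun)
  expect_equal(unname(ct$counts["functional_cluster_1", "enterotype_1"]), 8)
  expect_equal(unname(ct$counts["functional_cluster_2", "enterotype_1"]), 7)
  expect_equal(unname(ct$counts["functional_cluster_1", "enterotype_2"]), 0)
  expect_equal(unname(ct$counts["functional_cluster_2", "enterotype_2"]), 21)
  expect_equal(unname(ct$percent["functional_cluster_1", "enterotype_1"]), 22.2)
  expect_equal(unname(ct$percent["functional_cluster_2", "enterotype_1"]), 19.4)
  expect_equal(unname(ct$percent["functional_cluster_2", "enterotype_2"]), 58.3)
  expect_equal(unname(ct$percent["functional_cluster_2", "total"]), 77.8)
  expect_equal(unname(ct$percent["total", "total"]), 100.0)

  # identical partitions give a diagonal table
  ct2 <- crosstab_enterotype_function(ent, ent)
  expect_equal(unname(ct2$counts["functional_cluster_1", "enterotype_2"]), 0)
  expect_equal(unname(ct2$counts["functional_cluster_2", "enterotype_1"]), 0)
  # cell percentages sum to the total within rounding
  body <- ct$percent[1:2, 1:2]
  expect_lt(abs(sum(body) - 100), 0.1 * 4)
})

test_that("full pipeline recovery: k = 2 under all metrics with accurate assignments", {
  co <- generate_twin_cohort(cohort_spec(n_pairs = 10L, seed = 37L))
  g <- normalize_profiles(co$genus)
  truth <- co$truth$enterotype
  for (mt in c("js", "bc", "eu")) {
    res <- select_k(pairwise_distance(g, mt), 2:6)
    expect_equal(res$selected_k, 2L)
    acc <- cross_metric_agreement(truth, res$assignments)$agreement
    expect_gte(acc, 0.95)
  }
})
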