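# Host-association tests: rank tests, energy adjustment, nutrient
# clustering, Fisher's exact, and the discordant-twin screen.

test_that("BH adjustment follows the step-up formula and its properties", {
  expect_equal(bh_adjust(0.2), 0.2)
  # hand application of the step-up formula
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  expect_equal(order(adj[order(p)]), seq_along(p))  # monotone in raw order
})

test_that("rank-sum associations match enumeration and flag the planted trait", {
  md <- metadata_table(data.frame(
    sample_id = paste0("S", 1:6),
    v = c(1, 2, 3, 4, 5, 6)))
  ent <- setNames(rep(1:2, each = 3), paste0("S", 1:6))
  res <- wilcoxon_association(md, ent, "trait")
  expect_equal(res$p, enum_ranksum_p(1:3, 4:6))  # = 0.1 by enumeration
  expect_equal(res$p, 0.1)
  expect_match(res$direction, "higher_in_2")

  # identical value multisets in both groups -> p = 1
  md2 <- metadata_table(data.frame(sample_id = paste0("S", 1:6),
                                   v = c(1, 2, 3, 1, 2, 3)))
  expect_equal(wilcoxon_association(md2, ent, "trait")$p, 1)

  # synthetic cohort (sized for stable rank-test power): uric acid is the
  # top trait by adjusted p
  co <- generate_twin_cohort(cohort_spec(n_pairs = 25L, seed = 67L))
  truth <- setNames(co$truth$enterotype, co$truth$sample_id)
  tr <- wilcoxon_association(co$metadata, truth, "trait")
  expect_equal(tr$variable[1L], "uric_acid")
  expect_lt(tr$p_adj[1L], 0.05)
  expect_match(tr$direction[1L], "higher_in_2")
})

test_that("rank-sum p-values equal exhaustive enumeration across group sizes", {
  set.seed(23)
  for (n1 in 3:6) for (n2 in 3:6) {
    x <- rnorm(n1); y <- rnorm(n2) + 0.5
    p_pkg <- suppressWarnings(wilcox.test(x, y, exact = TRUE))$p.value
    expect_equal(p_pkg, enum_ranksum_p(x, y), tolerance = 1e-12,
                 label = sprintf("rank-sum n1=%d n2=%d", n1, n2))
  }
})

test_that("energy adjustment produces standardized residuals with the right geometry", {
  set.seed(29)
  n <- 40
  energy <- rnorm(n, 2000, 250)
  md <- metadata_table(data.frame(
    sample_id = paste0("S", 1:n),
    energy = energy,
    nutr_prop = 2 * energy,                     # exact multiple -> zero residuals
    nutr_indep = rnorm(n, 50, 5),               # independent of energy
    nutr_mix = 0.01 * energy + rnorm(n, 0, 2)))
  expect_warning(resid <- energy_adjust(md), "zero residual variance")
  expect_equal(unname(resid[, "prop"]), rep(0, n))
  for (cl in c("indep", "mix")) {
    expect_equal(mean(resid[, cl]), 0, tolerance = 1e-9)
    expect_equal(sd(resid[, cl]), 1, tolerance = 1e-9)
  }
})

test_that("residuals of an energy-independent nutrient match its standardized values", {
  set.seed(31)
  n <- 500
  energy <- rnorm(n, 2000, 250)
  v <- rnorm(n, 50, 5)
  md <- metadata_table(data.frame(sample_id = paste0("S", 1:n),
                                  energy = energy, nutr_v = v))
  resid <- energy_adjust(md)
  expect_gt(cor(resid[, "v"], as.numeric(scale(v))), 0.99)
  expect_error(energy_adjust(metadata_table(
    data.frame(sample_id = c("a", "b"), energy = c(1, 2), nutr_v = c(1, 2)))),
    "fewer than 3")
})

test_that("UPGMA clustering separates duplicated points and matches a hand trace", {
  m <- rbind(A1 = c(0, 0), A2 = c(0, 0), B1 = c(10, 0), B2 = c(10, 0))
  nc <- nutrient_cluster(m, 2)
  expect_equal(nc$groups[["A1"]], nc$groups[["A2"]])
  expect_equal(nc$groups[["B1"]], nc$groups[["B2"]])
  expect_false(nc$groups[["A1"]] == nc$groups[["B1"]])

  # hand UPGMA on collinear points 0, 1, 5, 7:
  # merge {0,1} at 1; merge {5,7} at 2; final merge at mean cross-distance
  # (5+7+4+6)/4 = 5.5
  m2 <- cbind(c(0, 1, 5, 7), 0)
  rownames(m2) <- paste0("P", 1:4)
  nc2 <- nutrient_cluster(m2, 2)
  expect_equal(sort(nc2$merge_heights), c(1, 2, 5.5), tolerance = 1e-12)
  expect_error(nutrient_cluster(m2, 2, subset = "missing_nutrient"),
               "not present")
})

test_that("clustering on associated nutrients aligns better with enterotype", {
  co <- generate_twin_cohort(cohort_spec(seed = 71L))
  truth <- setNames(co$truth$enterotype, co$truth$sample_id)
  resid <- energy_adjust(co$metadata)
  assoc9 <- c("fiber", "potassium", "iron", "vitamin_a", "vitamin_c",
              "vitamin_e", "folate", "carotene", "retinol")
  all23 <- nutrient_cluster(resid, 2)$groups
  sub9 <- nutrient_cluster(resid, 2, subset = assoc9)$groups
  agree <- function(g) cross_metric_agreement(
    unname(g), unname(truth[names(g)]))$agreement
  expect_gte(agree(sub9), agree(all23))
  expect_gt(agree(sub9), 0.7)
})

test_that("Fisher association uses the exact two-sided probability-mass rule", {
  g <- setNames(rep(1:2, each = 5), paste0("S", 1:10))
  e <- setNames(rep(1:2, each = 5), paste0("S", 1:10))
  # [[5,0],[0,5]]: enumeration over hypergeometric tables with margins
  # (5,5;5,5) gives 2/252
  expect_equal(fisher_association(g, e)$p_value, 2 / 252, tolerance = 1e-12)
  flat <- setNames(c(1, 1, 2, 2), paste0("S", 1:4))
  alt <- setNames(c(1, 2, 1, 2), paste0("S", 1:4))
  expect_equal(fisher_association(flat, alt)$p_value, 1)
  # invariance under transposing the roles of the two factors
  set.seed(5)
  a <- setNames(sample(1:2, 12, TRUE), paste0("S", 1:12))
  b <- setNames(sample(1:2, 12, TRUE), paste0("S", 1:12))
  if (length(unique(a)) == 2 && length(unique(b)) == 2)
    expect_equal(fisher_association(a, b)$p_value,
                 fisher_association(b, a)$p_value, tolerance = 1e-12)
})

test_that("signed-rank p-values equal sign-flip enumeration", {
  # all-positive differences 1..5: two-sided p = 2/32
  expect_equal(suppressWarnings(wilcox.test(c(1, 2, 3, 4, 5)))$p.value,
               2 / 32)
  expect_equal(enum_signedrank_p(c(1, 2, 3, 4, 5)), 2 / 32)
  set.seed(37)
  for (n in 3:6) {
    d <- rnorm(n) + 0.3
    expect_equal(suppressWarnings(wilcox.test(d, exact = TRUE))$p.value,
                 enum_signedrank_p(d), tolerance = 1e-12,
                 label = sprintf("signed-rank n=%d", n))
  }
})

test_that("discordant-twin screen computes within-pair differences and FDR flags", {
  fx_design <- paper_design()
  # discordant pairs P05..P08 as in the concordance fixture
  ent <- setNames(integer(nrow(fx_design)), fx_design$sample_id)
  for (i in seq_len(nrow(fx_design))) {
    p <- fx_design$pair_id[i]; tw <- fx_design$subject_id[i]
    tm <- fx_design$time_point[i]
    ent[fx_design$sample_id[i]] <-
      if (p %in% c("P01", "P02")) 1L
      else if (p %in% c("P03", "P04")) 2L
      else if (p %in% c("P05", "P06", "P08"))
        (if (tm == 1L) 2L else if (endsWith(tw, "T1")) 1L else 2L)
      else if (p == "P07") (if (endsWith(tw, "T1")) 1L else 2L)
      else if (p == "P09") 1L else 2L
  }
  # a trait that is exactly 10 units higher in every enterotype-2 co-twin,
  # with quadratic jitter so within-pair differences are tie-free
  md <- data.frame(sample_id = fx_design$sample_id,
                   marker = 100 + 10 * (ent == 2L) + seq_len(36)^2 * 1e-4,
                   null_trait = rep(c(5, -5), 18))  # equal within co-twins
  res <- suppressWarnings(
    discordant_twin_test(metadata_table(md), fx_design, ent, fdr = 0.05))
  expect_equal(sort(res$variable), c("marker", "null_trait"))
  mk <- res[res$variable == "marker", ]
  expect_equal(mk$n_pairs, 5L)
  # 5 positive differences: enumeration gives two-sided p = 2/32
  expect_equal(mk$p, 2 / 32, tolerance = 1e-12)
  # all-zero differences collapse to p = 1, never significant
  expect_equal(res$p[res$variable == "null_trait"], 1)
  expect_false(any(res$significant[res$variable == "null_trait"]))

  # null synthetic cohorts rarely flag anything at FDR 5%
  flags <- vapply(1:10, function(i) {
    co <- generate_twin_cohort(cohort_spec(
      seed = 300L + i, rho_conc = 0.5,
      trait_effects = within(enterotyper:::default_traits(), shift <- 0),
      nutrient_shift = 0, food_shift = 1, n_missing_diet = 0L))
    truth <- setNames(co$truth$enterotype, co$truth$sample_id)
    res <- tryCatch(discordant_twin_test(co$metadata, co$design, truth),
                    error = function(e) NULL)
    if (is.null(res)) 0L else sum(res$significant)
  }, integer(1L))
  expect_gte(mean(flags == 0L), 0.9)
})

test_that("parameter recovery: shifted trait and nutrients found, few false positives", {
  sens <- fdp <- numeric(0)
  for (i in 1:8) {
    co <- generate_twin_cohort(cohort_spec(seed = 400L + i,
                                           n_missing_diet = 0L))
    truth <- setNames(co$truth$enterotype, co$truth$sample_id)
    resid <- energy_adjust(co$metadata)
    res_df <- data.frame(sample_id = rownames(resid), as.data.frame(resid),
                         check.names = FALSE)
    nut <- wilcoxon_association(res_df, truth, "nutrient",
                                variables = colnames(resid))
    tra <- wilcoxon_association(co$metadata, truth, "trait")
    hits <- c(nut$variable[nut$p_adj < 0.05],
              tra$variable[tra$p_adj < 0.05])
    true_pos <- c("fiber", "potassium", "iron", "vitamin_a", "vitamin_c",
                  "vitamin_e", "folate", "carotene", "retinol", "uric_acid")
    sens <- c(sens, length(intersect(hits, true_pos)) / length(true_pos))
    fdp <- c(fdp, if (length(hits)) length(setdiff(hits, true_pos)) / length(hits) else 0)
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdp), 0.2)
})
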