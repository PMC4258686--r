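# Synthetic twin cohorts with known latent enterotypes.
#
# The generator emulates the statistical structure the downstream analyses
# assume: two community types as Dirichlet mixtures (Bacteroides-heavy vs
# Prevotella-heavy), monozygotic co-twins sharing the index twin's
# enterotype with probability rho_conc, a symmetric two-state persistence
# step across the two sampling times (keep with probability rho_pers), an
# enterotype-shifted clinical trait (serum uric acid by default), and
# energy-driven nutrient intakes with enterotype shifts on the nine
# diet-associated nutrients.

default_genus_list <- function() {
  c("Bacteroides", "Prevotella", "Catenibacterium", "Lactobacillus",
    "Dorea", "Coprococcus", "Faecalibacterium", "Roseburia", "Blautia",
    "Ruminococcus", "Eubacterium", "Clostridium", "Alistipes",
    "Parabacteroides", "Bifidobacterium", "Akkermansia", "Streptococcus",
    "Veillonella", "Dialister", "Phascolarctobacterium", "Oscillibacter",
    "Subdoligranulum", "Collinsella", "Megamonas", "Sutterella",
    "Odoribacter", "Butyrivibrio", "Anaerostipes", "Holdemania",
    "Desulfovibrio")
}

# Dirichlet mean weights for the two community types over the default
# genus list; total concentration scales them into alpha vectors.
default_genus_weights <- function() {
  g <- default_genus_list()
  base <- rep(0.30 / (length(g) - 6L), length(g))
  names(base) <- g
  w1 <- base; w2 <- base
  w1[c("Bacteroides", "Prevotella", "Catenibacterium", "Lactobacillus",
       "Dorea", "Coprococcus")] <- c(0.50, 0.02, 0.08, 0.03, 0.03, 0.04)
  w2[c("Bacteroides", "Prevotella", "Catenibacterium", "Lactobacillus",
       "Dorea", "Coprococcus")] <- c(0.05, 0.35, 0.01, 0.09, 0.09, 0.11)
  list(w1 = w1 / sum(w1), w2 = w2 / sum(w2))
}

default_kegg_weights <- function() {
  ids <- sprintf("ko%05d", c(10, 20, 30, 40, 51, 52, 61, 71, 100, 190,
                             230, 240, 250, 260, 270, 280, 290, 300, 310, 330))
  base <- rep(1 / length(ids), length(ids))
  names(base) <- ids
  w1 <- base; w2 <- base
  w1[1:5] <- w1[1:5] * 2.2   # vitamin-biosynthesis-like block, type-1 enriched
  w2[6:10] <- w2[6:10] * 2.2 # transport-system-like block, type-2 enriched
  list(w1 = w1 / sum(w1), w2 = w2 / sum(w2))
}

default_nutrients <- function() {
  assoc <- c("fiber", "potassium", "iron", "vitamin_a", "vitamin_c",
             "vitamin_e", "folate", "carotene", "retinol")
  filler <- c("protein", "fat", "carbohydrate", "calcium", "phosphorus",
              "sodium", "zinc", "vitamin_b1", "vitamin_b2", "vitamin_b6",
              "vitamin_b12", "niacin", "vitamin_d", "cholesterol")
  list(associated = assoc, all = c(assoc, filler))
}

default_food_groups <- function() {
  c("rice", "noodles", "bread", "cereals", "potatoes", "sugars", "beans",
    "nuts", "vegetables", "kimchi", "mushrooms", "fruits", "meat",
    "poultry", "processed_meat", "eggs", "fish", "shellfish", "seaweed",
    "dairy", "oils", "beverages", "tea_coffee", "alcohol", "snacks",
    "soups", "seasonings", "pickles", "soy_products", "fast_food")
}

default_traits <- function() {
  # baseline mean, sd, enterotype-2 shift (clinical units); only uric acid
  # carries a shift by default
  data.frame(
    trait = c("age", "bmi", "systolic_bp", "diastolic_bp", "glucose",
              "total_cholesterol", "triglyceride", "hdl", "ldl",
              "uric_acid", "crp", "insulin"),
    mean = c(39, 23.5, 118, 76, 92, 190, 110, 52, 115, 5.0, 0.8, 8.0),
    sd = c(5, 2.8, 11, 8, 9, 28, 45, 11, 26, 1.2, 0.6, 3.0),
    shift = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2.0, 0, 0),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic twin cohort
#'
#' Defaults reproduce the shape of the study cohort: 10 monozygotic pairs,
#' 8 of them sampled at two time points about two years apart (36 samples),
#' a 0.583 marginal probability of the *Prevotella*-type community,
#' co-twin concordance 0.722 and two-year persistency 0.813, an
#' enterotype-2 uric-acid shift, enterotype-2 shifts on nine energy-adjusted
#' nutrients (fiber, potassium, iron, vitamins A/C/E, folate, carotene,
#' retinol) and on the fruits and eggs food groups, and 4 samples with the
#' diet block missing.
#'
#' @param n_pairs number of MZ twin pairs.
#' @param p_longitudinal fraction of pairs sampled at both time points; the
#'   first `round(p_longitudinal * n_pairs)` pairs are longitudinal so the
#'   design is deterministic.
#' @param pi2 marginal probability that the index twin is enterotype 2.
#' @param rho_conc probability the co-twin shares the index twin's
#'   enterotype.
#' @param rho_pers probability a subject keeps its enterotype at time 2.
#' @param concentration total Dirichlet concentration for community draws
#'   (within-type dispersion; larger = tighter profiles).
#' @param genus_weights,kegg_weights lists with strictly positive mean
#'   weight vectors `w1`, `w2` (normalized internally).
#' @param trait_effects data.frame with columns trait/mean/sd/shift.
#' @param nutrient_shift enterotype-2 shift, in residual standard
#'   deviations, applied to the associated nutrients.
#' @param food_shift multiplicative enterotype-2 effect on the fruits and
#'   eggs food groups (log-normal intake scale).
#' @param n_missing_diet number of samples whose food/nutrient block is
#'   masked (`NA`), emulating incomplete questionnaires.
#' @param read_depth optional multinomial resampling depth adding count
#'   noise on top of the Dirichlet draws; `NULL` (default) returns the
#'   exact compositional draws.
#' @param seed RNG seed; identical specs with identical seeds generate
#'   identical cohorts.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_pairs = 10L, p_longitudinal = 0.8, pi2 = 0.583,
                        rho_conc = 0.722, rho_pers = 0.813,
                        concentration = 50,
                        genus_weights = default_genus_weights(),
                        kegg_weights = default_kegg_weights(),
                        trait_effects = default_traits(),
                        nutrient_shift = 1.5, food_shift = 1.6,
                        n_missing_diet = 4L, read_depth = NULL,
                        seed = 1L) {
  for (p in c(p_longitudinal, pi2, rho_conc, rho_pers))
    if (p < 0 || p > 1) stop_validation("probabilities must lie in [0, 1]")
  if (n_pairs < 1L) stop_validation("n_pairs must be >= 1")
  if (concentration <= 0) stop_validation("concentration must be positive")
  for (w in c(genus_weights, kegg_weights))
    if (any(w <= 0)) stop_validation("Dirichlet weight vectors must be strictly positive")
  structure(list(n_pairs = as.integer(n_pairs),
                 p_longitudinal = p_longitudinal, pi2 = pi2,
                 rho_conc = rho_conc, rho_pers = rho_pers,
                 concentration = concentration,
                 genus_weights = genus_weights, kegg_weights = kegg_weights,
                 trait_effects = trait_effects,
                 nutrient_shift = nutrient_shift, food_shift = food_shift,
                 n_missing_diet = as.integer(n_missing_diet),
                 read_depth = read_depth, seed = as.integer(seed)),
            class = "cohort_spec")
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  x / rowSums(x)
}

#' Generate a synthetic twin cohort
#'
#' Latent model: the index twin's enterotype at time 1 is Bernoulli(pi2)
#' (enterotype 2 with probability `pi2`); the co-twin copies it with
#' probability `rho_conc`, else flips; at time 2 each sampled subject keeps
#' its time-1 enterotype with probability `rho_pers`, else flips (a
#' symmetric two-state Markov step).  Genus and KEGG profiles are exact
#' Dirichlet draws from the enterotype's alpha vector; traits are Gaussian
#' with an enterotype-2 mean shift; each nutrient is
#' `slope * energy + shift * 1[enterotype 2] + noise` with Gaussian energy.
#'
#' @param spec a [cohort_spec()].
#' @return list with `genus` and `kegg` [abundance_table()]s, `design`
#'   (`twin_design`), `metadata` (`metadata_table`) and `truth` (data.frame
#'   of per-sample latent enterotypes).
#' @export
generate_twin_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n_long <- round(spec$p_longitudinal * spec$n_pairs)
  rows <- list()
  for (p in seq_len(spec$n_pairs)) {
    times <- if (p <= n_long) 1:2 else 1L
    for (s in 1:2) for (tm in times)
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sprintf("P%03d", p),
        subject_id = sprintf("P%03d_T%d", p, s),
        twin_index = s, time_point = tm, stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, rows)
  design$sample_id <- sprintf("%s_V%d", design$subject_id, design$time_point)

  # latent enterotypes: 1 = Bacteroides type, 2 = Prevotella type
  e_t1 <- matrix(NA_integer_, spec$n_pairs, 2)
  for (p in seq_len(spec$n_pairs)) {
    idx <- 1L + rbinom(1L, 1L, spec$pi2)
    co <- if (runif(1) < spec$rho_conc) idx else 3L - idx
    e_t1[p, ] <- c(idx, co)
  }
  ent <- integer(nrow(design))
  for (r in seq_len(nrow(design))) {
    p <- as.integer(sub("^P", "", design$pair_id[r]))
    base <- e_t1[p, design$twin_index[r]]
    ent[r] <- if (design$time_point[r] == 1L) base
              else if (runif(1) < spec$rho_pers) base else 3L - base
  }
  n <- nrow(design)

  draw_profiles <- function(weights, level) {
    a1 <- spec$concentration * weights$w1 / sum(weights$w1)
    a2 <- spec$concentration * weights$w2 / sum(weights$w2)
    m <- matrix(NA_real_, n, length(a1),
                dimnames = list(design$sample_id, names(a1)))
    for (r in seq_len(n))
      m[r, ] <- rdirichlet(1L, if (ent[r] == 1L) a1 else a2)
    if (!is.null(spec$read_depth)) {
      for (r in seq_len(n)) {
        counts <- stats::rmultinom(1L, spec$read_depth, m[r, ])[, 1L]
        m[r, ] <- counts / sum(counts)
      }
    }
    abundance_table(m, level = level)
  }
  genus <- draw_profiles(spec$genus_weights, "genus")
  kegg <- draw_profiles(spec$kegg_weights, "kegg_pathway")

  te <- spec$trait_effects
  meta <- data.frame(sample_id = design$sample_id, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(te)))
    meta[[te$trait[i]]] <- te$mean[i] + te$shift[i] * (ent == 2L) +
      rnorm(n, 0, te$sd[i])
  # food groups: log-normal g/day, fruits and eggs elevated in enterotype 2
  fg <- default_food_groups()
  for (f in fg) {
    mult <- if (f %in% c("fruits", "eggs")) spec$food_shift^(ent == 2L) else 1
    meta[[paste0("food_", f)]] <- round(mult * exp(rnorm(n, log(80), 0.5)), 1)
  }
  # energy and nutrients: nutrient = slope*energy + shift*1[E2] + noise
  nutr <- default_nutrients()
  energy <- rnorm(n, 2000, 300)
  meta$energy <- round(energy, 1)
  for (nm in nutr$all) {
    slope <- 0.02
    noise_sd <- 4
    shift <- if (nm %in% nutr$associated) spec$nutrient_shift * noise_sd else 0
    meta[[paste0("nutr_", nm)]] <- slope * energy + shift * (ent == 2L) +
      rnorm(n, 0, noise_sd)
  }
  if (spec$n_missing_diet > 0L) {
    drop <- sample.int(n, min(spec$n_missing_diet, n))
    diet_cols <- c(paste0("food_", fg), "energy", paste0("nutr_", nutr$all))
    meta[drop, diet_cols] <- NA
  }

  truth <- data.frame(sample_id = design$sample_id,
                      subject_id = design$subject_id,
                      pair_id = design$pair_id,
                      time_point = design$time_point,
                      enterotype = ent, stringsAsFactors = FALSE)
  list(genus = genus, kegg = kegg,
       design = twin_design(design[, c("sample_id", "subject_id", "pair_id",
                                       "time_point")]),
       metadata = metadata_table(meta),
       truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Summarize the latent enterotype truth of a synthetic cohort
#'
#' @param truth the `truth` data.frame from [generate_twin_cohort()].
#' @return list with `enterotype_freq` (counts over samples),
#'   `paired_observations` (pair-at-a-time-point observations with both
#'   co-twins sampled), `n_concordant`, `n_discordant`, `n_longitudinal`
#'   (subjects with two time points) and `n_switch` (subjects changing
#'   enterotype between times).
#' @export
summarize_truth <- function(truth) {
  if (nrow(truth) == 0L)
    return(list(enterotype_freq = c(`1` = 0L, `2` = 0L),
                paired_observations = 0L, n_concordant = 0L,
                n_discordant = 0L, n_longitudinal = 0L, n_switch = 0L))
  freq <- table(factor(truth$enterotype, levels = 1:2))
  pt <- split(truth, list(truth$pair_id, truth$time_point), drop = TRUE)
  pt <- pt[vapply(pt, nrow, integer(1L)) == 2L]
  conc <- vapply(pt, function(d) d$enterotype[1L] == d$enterotype[2L], logical(1L))
  by_subj <- split(truth, truth$subject_id)
  long <- by_subj[vapply(by_subj, nrow, integer(1L)) == 2L]
  switch_ <- vapply(long, function(d) d$enterotype[1L] != d$enterotype[2L], logical(1L))
  list(enterotype_freq = freq,
       paired_observations = length(pt),
       n_concordant = sum(conc), n_discordant = sum(!conc),
       n_longitudinal = length(long), n_switch = sum(switch_))
}

#' Write a generated cohort to a directory of TSVs
#'
#' Writes `genus.tsv`, `kegg.tsv`, `design.tsv`, `metadata.tsv` and
#' `truth.tsv`.
#'
#' @param cohort output of [generate_twin_cohort()].
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(cohort$genus, file.path(dir, "genus.tsv"))
  write_abundance_table(cohort$kegg, file.path(dir, "kegg.tsv"))
  write_twin_design(cohort$design, file.path(dir, "design.tsv"))
  write_metadata_table(cohort$metadata, file.path(dir, "metadata.tsv"))
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
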