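# Two-class LDA-effect-size differential abundance, re-implemented.
#
# Stage 1 screens features with a Kruskal-Wallis rank test (identical to a
# two-sided Wilcoxon rank-sum for two classes) at a significance level
# alpha.  Stage 2 sizes the surviving features: profiles are scaled to a
# per-sample sum of 1e6, and over n_boot bootstrap iterations a fraction of
# each class is subsampled and a regularized two-class linear discriminant
# is fitted.  The per-feature effect in one iteration is
#
#   effect = (|class-mean gap| + |unit-discriminant weight| * separation) / 2
#
# where "separation" is the distance between the projected class means on
# the discriminant axis; the score is log10(max(effect, 1)) averaged over
# iterations, signed by the direction of the full-data class-mean gap
# (negative = enriched in the first class, positive = the second).

#' Rank-test screen for differentially abundant features
#'
#' @param t an [abundance_table()].
#' @param classes two-level factor/vector over the samples of `t` (named
#'   vectors are matched by sample id).
#' For two classes the Kruskal-Wallis rank test is equivalent to the
#' two-sided Wilcoxon rank-sum test; the screen therefore uses the rank-sum
#' test directly, with its exact small-sample null (both groups at most 10
#' samples, no ties) and the tie-corrected normal approximation otherwise.
#'
#' @param alpha significance level for the screen (default 0.01).
#' @return data.frame with feature_id, kw_p and pass (kw_p < alpha).
#'   Features constant across all samples get p = 1.
#' @export
rank_screen <- function(t, classes, alpha = 0.01) {
  stopifnot(is_abundance_table(t))
  classes <- align_classes(t, classes)
  if (nlevels(classes) != 2L)
    stop_validation("exactly two classes required (got %d)", nlevels(classes))
  if (any(table(classes) < 2L))
    stop_validation("each class needs at least 2 samples")
  m <- unclass(t)
  lv <- levels(classes)
  kw_p <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    if (length(unique(v)) == 1L) return(1)
    x <- v[classes == lv[1L]]; y <- v[classes == lv[2L]]
    suppressWarnings(wilcox.test(x, y, exact = length(x) <= 10L &&
                                   length(y) <= 10L &&
                                   !anyDuplicated(v))$p.value)
  }, numeric(1L))
  data.frame(feature_id = colnames(m), kw_p = kw_p, pass = kw_p < alpha,
             stringsAsFactors = FALSE)
}

align_classes <- function(t, classes) {
  if (inherits(classes, "clustering_result"))
    classes <- setNames(classes$assignments, classes$sample_ids)
  if (!is.null(names(classes))) {
    miss <- setdiff(rownames(t), names(classes))
    if (length(miss))
      stop_validation("no class for sample(s): %s", paste(head(miss, 3L), collapse = ", "))
    classes <- classes[rownames(t)]
  } else if (length(classes) != nrow(t)) {
    stop_validation("classes length does not match the sample count")
  }
  droplevels(as.factor(classes))
}

# Regularized two-class LDA direction on scaled features.
lda_direction <- function(m, cl) {
  lv <- levels(cl)
  m1 <- colMeans(m[cl == lv[1L], , drop = FALSE])
  m2 <- colMeans(m[cl == lv[2L], , drop = FALSE])
  n1 <- sum(cl == lv[1L]); n2 <- sum(cl == lv[2L])
  c1 <- stats::cov(m[cl == lv[1L], , drop = FALSE])
  c2 <- stats::cov(m[cl == lv[2L], , drop = FALSE])
  S <- ((n1 - 1) * c1 + (n2 - 1) * c2) / (n1 + n2 - 2)
  # diagonal loading keeps the solve well-posed in the p >> n regime
  lambda <- 0.1 * mean(diag(S))
  if (!is.finite(lambda) || lambda <= 0) lambda <- 1
  Sreg <- S + diag(lambda, ncol(m))
  w <- tryCatch(solve(Sreg, m2 - m1),
                error = function(e) solve(S + diag(max(lambda, 1) * 10, ncol(m)), m2 - m1))
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) return(list(w_unit = w, sep = 0, gap = m2 - m1))
  w_unit <- w / nrm
  sep <- abs(sum(w_unit * (m2 - m1)))
  list(w_unit = w_unit, sep = sep, gap = m2 - m1)
}

#' Bootstrapped LDA effect sizes
#'
#' @param t an [abundance_table()] restricted to screened features; values
#'   are rescaled internally to a per-sample sum of 1e6 so scores land on
#'   the familiar 2-6 log10 range.
#' @param classes two-level classes as in [rank_screen()].
#' @param n_boot bootstrap iterations (default 30).
#' @param boot_fraction fraction of each class subsampled per iteration
#'   (default 2/3; at least 2 samples per class are always kept).
#' @param seed RNG seed for the bootstrap stream.
#' @return data.frame with feature_id and lda_score (signed log10 effect;
#'   negative = enriched in the first class level).
#' @export
lda_effect_size <- function(t, classes, n_boot = 30L, boot_fraction = 2 / 3,
                            seed = NULL) {
  stopifnot(is_abundance_table(t))
  classes <- align_classes(t, classes)
  if (nlevels(classes) != 2L) stop_validation("exactly two classes required")
  if (n_boot < 1L) stop_validation("n_boot must be >= 1")
  if (any(table(classes) < 2L))
    stop_validation("each class needs at least 2 samples")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  m <- unclass(t)
  m <- m / rowSums(m) * 1e6
  lv <- levels(classes)
  idx1 <- which(classes == lv[1L]); idx2 <- which(classes == lv[2L])
  take <- function(idx) {
    k <- max(2L, floor(boot_fraction * length(idx)))
    idx[sample.int(length(idx), k)]
  }
  scores <- matrix(NA_real_, n_boot, ncol(m))
  for (b in seq_len(n_boot)) {
    sub <- c(take(idx1), take(idx2))
    fit <- lda_direction(m[sub, , drop = FALSE], droplevels(classes[sub]))
    effect <- (abs(fit$gap) + abs(fit$w_unit) * fit$sep) / 2
    scores[b, ] <- log10(pmax(effect, 1))
  }
  gap_full <- colMeans(m[idx2, , drop = FALSE]) -
    colMeans(m[idx1, , drop = FALSE])
  sgn <- ifelse(gap_full > 0, 1, ifelse(gap_full < 0, -1, 0))
  data.frame(feature_id = colnames(m),
             lda_score = sgn * colMeans(scores),
             stringsAsFactors = FALSE)
}

#' LEfSe-style differential abundance
#'
#' Composition of [rank_screen()] and [lda_effect_size()]: only features
#' passing the rank screen at `alpha` are sized, and only those with
#' `|lda_score| >= lda_threshold` are reported, sorted by decreasing
#' `|lda_score|`.  The first class level is "class 1" (negative scores,
#' e.g. enterotype 1), the second "class 2" (positive scores).
#'
#' @inheritParams rank_screen
#' @inheritParams lda_effect_size
#' @param lda_threshold minimum absolute log10 effect size (default 2).
#' @return data.frame with feature_id, kw_p, lda_score, enriched_class and
#'   passes; only passing features are returned.
#' @export
lefse_run <- function(t, classes, alpha = 0.01, lda_threshold = 2,
                      n_boot = 30L, boot_fraction = 2 / 3, seed = NULL) {
  classes <- align_classes(t, classes)
  screen <- rank_screen(t, classes, alpha = alpha)
  kept <- screen$feature_id[screen$pass]
  empty <- data.frame(feature_id = character(), kw_p = numeric(),
                      lda_score = numeric(), enriched_class = character(),
                      passes = logical(), stringsAsFactors = FALSE)
  if (length(kept) == 0L) return(empty)
  sub <- abundance_table(unclass(t)[, kept, drop = FALSE],
                         level = attr(t, "level"))
  eff <- lda_effect_size(sub, classes, n_boot = n_boot,
                         boot_fraction = boot_fraction, seed = seed)
  out <- merge(screen[screen$pass, c("feature_id", "kw_p")], eff,
               by = "feature_id")
  out$enriched_class <- ifelse(out$lda_score < 0, levels(classes)[1L],
                               levels(classes)[2L])
  out$passes <- abs(out$lda_score) >= lda_threshold
  out <- out[out$passes, , drop = FALSE]
  out <- out[order(-abs(out$lda_score)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
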