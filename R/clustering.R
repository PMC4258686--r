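# Partitioning around medoids and cluster-quality indices, all operating on
# a precomputed distance matrix.  The PAM here is the classical
# Kaufman-Rousseeuw BUILD + SWAP: greedy seeding, then repeated application
# of the best strictly-improving (medoid, non-medoid) exchange.  All ties
# break toward the lowest sample index, so results are deterministic.

pam_cost <- function(D, medoids) sum(row_mins(D[, medoids, drop = FALSE]))

#' Partition samples around k medoids
#'
#' Minimizes the k-medoid objective (total distance of every sample to its
#' nearest medoid).  Two solvers share that objective:
#' \describe{
#'   \item{exhaustive}{enumerates every medoid set — the exact optimum.}
#'   \item{build_swap}{classical Kaufman-Rousseeuw PAM: greedy BUILD
#'     seeding, then the best strictly-improving (medoid, non-medoid)
#'     exchange until none exists.  A deterministic local search: on a
#'     small fraction of instances it terminates in a swap-local optimum
#'     above the true minimum.}
#' }
#' The default (`"auto"`) enumerates exactly whenever the search space is
#' small (`choose(n, k)` at most 20000, which covers every cluster-number
#' scan on cohort-sized data at small k) and falls back to BUILD+SWAP
#' otherwise.  All ties break toward the lowest sample index, so every
#' path is deterministic.
#'
#' @param D a [distance_matrix()].
#' @param k number of clusters, `1 <= k <= n`.
#' @param method `"auto"`, `"exhaustive"` or `"build_swap"`.
#' @return list with `medoids` (sample indices), `medoid_ids`, `assignments`
#'   (cluster index per sample, clusters numbered by medoid order),
#'   `total_cost` (sum of distances to the assigned medoid) and `method`
#'   (the solver actually used).
#' @export
pam_cluster <- function(D, k, method = c("auto", "exhaustive", "build_swap")) {
  method <- match.arg(method)
  stopifnot(inherits(D, "distance_matrix"))
  n <- nrow(D)
  if (k < 1L || k > n) stop_validation("k must be in 1..n (n = %d)", n)
  Dm <- unclass(D)
  if (method == "auto")
    method <- if (choose(n, k) <= 20000) "exhaustive" else "build_swap"

  medoids <- if (method == "exhaustive") {
    sets <- combn(n, k)
    costs <- vapply(seq_len(ncol(sets)),
                    function(j) pam_cost(Dm, sets[, j]), numeric(1L))
    sets[, which.min(costs)]  # which.min: lowest-index set on ties
  } else {
    pam_build_swap(Dm, k)
  }

  medoids <- sort(unname(medoids))
  assignments <- row_which_min(Dm[, medoids, drop = FALSE])
  # a medoid always belongs to its own cluster (distance 0, lowest tie wins
  # only among medoids at distance 0; force ownership for duplicated points)
  assignments[medoids] <- seq_along(medoids)
  list(medoids = medoids, medoid_ids = rownames(Dm)[medoids],
       assignments = assignments, total_cost = pam_cost(Dm, medoids),
       method = method)
}

# classical PAM: greedy BUILD seeding + steepest-descent SWAP
pam_build_swap <- function(Dm, k) {
  n <- nrow(Dm)
  # BUILD: first medoid minimizes total distance; each next maximizes the
  # decrease in cost, lowest index on ties
  medoids <- unname(which.min(colSums(Dm)))
  while (length(medoids) < k) {
    nearest <- row_mins(Dm[, medoids, drop = FALSE])
    gain <- colSums(pmax(nearest - Dm, 0))  # per candidate column
    gain[medoids] <- -Inf
    medoids <- c(medoids, unname(which.max(gain)))
  }
  # SWAP: best strictly-improving exchange until none
  cost <- pam_cost(Dm, medoids)
  repeat {
    best <- list(delta = 0)
    non_med <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      for (h in non_med) {
        cand <- medoids
        cand[mi] <- h
        delta <- pam_cost(Dm, cand) - cost
        if (delta < best$delta - 1e-12) best <- list(delta = delta, mi = mi, h = h)
      }
    }
    if (is.null(best$mi)) break
    medoids[best$mi] <- best$h
    cost <- cost + best$delta
  }
  medoids
}

#' Calinski-Harabasz pseudo F-statistic on a distance matrix
#'
#' Medoid-centrotype form with squared distances: within-cluster dispersion
#' \eqn{W = \sum_i d(x_i, medoid_{c(i)})^2}, between-cluster dispersion
#' \eqn{B = \sum_j n_j \, d(medoid_j, medoid_0)^2} where the overall medoid
#' \eqn{medoid_0} is the sample minimizing total distance to all samples,
#' and \eqn{CH = (B/(k-1)) / (W/(n-k))}.  Perfectly tight clusters
#' (\eqn{W=0}) return `Inf`.
#'
#' @param D a [distance_matrix()].
#' @param assignments integer cluster index per sample, k >= 2, no empty
#'   cluster.
#' @return the CH value.
#' @export
ch_index <- function(D, assignments) {
  Dm <- unclass(D)
  n <- nrow(Dm)
  stopifnot(length(assignments) == n)
  ks <- sort(unique(assignments))
  k <- length(ks)
  if (k < 2L) stop_validation("CH undefined for one cluster")
  overall <- which.min(colSums(Dm))
  W <- 0; B <- 0
  for (j in ks) {
    members <- which(assignments == j)
    med <- members[which.min(colSums(Dm[members, members, drop = FALSE]))]
    W <- W + sum(Dm[members, med]^2)
    B <- B + length(members) * Dm[med, overall]^2
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Silhouette widths and mean silhouette index
#'
#' Standard Rousseeuw silhouette from a distance matrix:
#' \eqn{s(i) = (b_i - a_i)/\max(a_i, b_i)} with \eqn{a_i} the mean distance
#' to the sample's own cluster (excluding itself) and \eqn{b_i} the smallest
#' mean distance to another cluster.  Singleton clusters get \eqn{s = 0}.
#' The mean width is also mapped to the Kaufman-Rousseeuw support category:
#' none (<= 0.25), weak (0.25-0.5], reasonable (0.5-0.75], strong (> 0.75).
#'
#' @inheritParams ch_index
#' @return list with `si` (mean width), `widths` (per sample) and `support`
#'   (category string).
#' @export
silhouette_index <- function(D, assignments) {
  Dm <- unclass(D)
  n <- nrow(Dm)
  stopifnot(length(assignments) == n)
  ks <- sort(unique(assignments))
  if (length(ks) < 2L) stop_validation("silhouette undefined for one cluster")
  sizes <- table(factor(assignments, levels = ks))
  if (any(sizes == 0L)) stop_validation("empty cluster")
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignments[i]
    if (sizes[as.character(own)] == 1L) { widths[i] <- 0; next }
    a <- mean(Dm[i, assignments == own & seq_len(n) != i])
    b <- min(vapply(setdiff(ks, own),
                    function(j) mean(Dm[i, assignments == j]), numeric(1L)))
    widths[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  si <- mean(widths)
  list(si = si, widths = widths, support = silhouette_support(si))
}

#' Kaufman-Rousseeuw silhouette support category
#' @param si mean silhouette width.
#' @return `"none"`, `"weak"`, `"reasonable"` or `"strong"`.
#' @export
silhouette_support <- function(si) {
  if (si <= 0.25) "none"
  else if (si <= 0.5) "weak"
  else if (si <= 0.75) "reasonable"
  else "strong"
}

#' Scan cluster numbers and select the CH-optimal partition
#'
#' Runs [pam_cluster()] for each k in `k_range`, scores each partition with
#' [ch_index()] and [silhouette_index()], and selects the k maximizing CH
#' (ties toward the smallest k — parsimony).  SI is reported as a quality
#' qualifier and never overrides the CH choice.
#'
#' @param D a [distance_matrix()].
#' @param k_range integer vector of cluster numbers to scan (each >= 2,
#'   <= n-1); default `2:min(10, n-1)`.
#' @return a `clustering_result`: list with `metric`, `sample_ids`,
#'   `scan` (data.frame k / ch / si / support), `per_k` (raw PAM fits),
#'   `selected_k`, `assignments` (for the selected k), `medoid_ids`,
#'   `silhouette_widths`, `support`.
#' @export
select_k <- function(D, k_range = NULL) {
  stopifnot(inherits(D, "distance_matrix"))
  n <- nrow(D)
  if (is.null(k_range)) k_range <- 2:min(10L, n - 1L)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop_validation("k_range must lie in 2..n-1 (n = %d)", n)
  per_k <- list()
  scan <- data.frame(k = k_range, ch = NA_real_, si = NA_real_,
                     support = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(k_range)) {
    fit <- pam_cluster(D, k_range[i])
    sil <- silhouette_index(D, fit$assignments)
    fit$silhouette_widths <- sil$widths
    per_k[[as.character(k_range[i])]] <- fit
    scan$ch[i] <- ch_index(D, fit$assignments)
    scan$si[i] <- sil$si
    scan$support[i] <- sil$support
  }
  best <- which(scan$ch == max(scan$ch))[1L]  # ties -> smallest k
  sel <- per_k[[as.character(scan$k[best])]]
  structure(list(metric = attr(D, "metric"), sample_ids = rownames(D),
                 scan = scan, per_k = per_k, selected_k = scan$k[best],
                 assignments = sel$assignments, medoid_ids = sel$medoid_ids,
                 silhouette_widths = sel$silhouette_widths,
                 support = scan$support[best]),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result (%s): selected k = %d (CH = %.2f, SI = %.3f, support: %s)\n",
              x$metric, x$selected_k,
              x$scan$ch[x$scan$k == x$selected_k],
              x$scan$si[x$scan$k == x$selected_k], x$support))
  print(table(enterotype = x$assignments))
  invisible(x)
}

#' Relabel clusters as enterotypes by marker-genus dominance
#'
#' The cluster whose samples have the highest mean abundance of the first
#' marker (default *Bacteroides*) becomes enterotype 1; the highest-mean
#' cluster for the second marker (*Prevotella*) becomes enterotype 2, and so
#' on in marker priority order.  If a cluster tops several markers the
#' earlier marker wins.  Remaining clusters are numbered by decreasing size.
#' When no marker is present in the table the relabeling falls back to
#' decreasing cluster size, with a warning.
#'
#' @param result a `clustering_result` from [select_k()].
#' @param t the [abundance_table()] the clustering was computed from.
#' @param markers ordered character vector of marker features; default
#'   `c("Bacteroides", "Prevotella")`.
#' @return the `clustering_result` with `assignments` relabeled and an
#'   `enterotype_markers` field recording the mapping.
#' @export
label_enterotypes <- function(result, t,
                              markers = c("Bacteroides", "Prevotella")) {
  stopifnot(inherits(result, "clustering_result"), is_abundance_table(t))
  m <- unclass(t)[result$sample_ids, , drop = FALSE]
  ks <- sort(unique(result$assignments))
  present <- markers[markers %in% colnames(m)]
  relabel <- rep(NA_integer_, length(ks))
  if (length(present) == 0L) {
    warning("no marker feature present; labeling enterotypes by decreasing cluster size")
    ord <- order(-tabulate(result$assignments, nbins = max(ks))[ks], ks)
    relabel[ord] <- seq_along(ks)
  } else {
    taken <- integer(0)
    for (mk in present) {
      means <- vapply(ks, function(j)
        mean(m[result$assignments == j, mk]), numeric(1L))
      means[ks %in% taken] <- -Inf
      if (all(!is.finite(means))) break
      win <- ks[which.max(means)]
      relabel[ks == win] <- match(mk, markers)
      taken <- c(taken, win)
    }
    rest <- ks[is.na(relabel)]
    if (length(rest)) {
      sizes <- vapply(rest, function(j) sum(result$assignments == j), numeric(1L))
      free <- setdiff(seq_along(ks), relabel[!is.na(relabel)])
      relabel[match(rest[order(-sizes, rest)], ks)] <- free
    }
  }
  new_assign <- relabel[match(result$assignments, ks)]
  result$assignments <- new_assign
  result$medoid_ids <- result$medoid_ids[order(relabel)]
  result$enterotype_markers <- setNames(relabel, ks)
  result
}

#' Best label-matched agreement between two partitions
#'
#' Searches all label permutations of the second partition and reports the
#' maximal fraction of samples on which the two agree, and whether they are
#' identical up to relabeling.
#'
#' @param a,b integer assignment vectors over the same samples (named
#'   vectors are matched by name).
#' @return list with `agreement` (fraction) and `exact_match` (logical).
#' @export
cross_metric_agreement <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop_validation("partitions cover different samples")
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop_validation("partitions cover different samples")
  la <- sort(unique(a)); lb <- sort(unique(b))
  k <- max(length(la), length(lb))
  if (k > 8L) stop_validation("too many clusters for exhaustive label matching")
  # confusion matrix padded to square; best one-to-one label matching
  C <- matrix(0, k, k)
  for (i in seq_along(la)) for (j in seq_along(lb))
    C[i, j] <- sum(a == la[i] & b == lb[j])
  perms <- perm_all(k)
  matched <- apply(perms, 1L, function(p) sum(C[cbind(seq_len(k), p)]))
  best <- max(matched) / length(a)
  list(agreement = best, exact_match = isTRUE(all.equal(best, 1)))
}

# all permutations of 1..n as a matrix (n small)
perm_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_all(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Cross-tabulate enterotypes against functional clusters
#'
#' Builds the 2-way contingency table of the genus-based enterotype
#' assignment versus the KEGG-based functional-cluster assignment, with each
#' cell also expressed as a percentage of all samples (1 decimal).
#'
#' @param genus_result,kegg_result `clustering_result`s over the same
#'   samples (or bare assignment vectors named by sample).
#' @return list with `counts` (matrix, functional clusters x enterotypes,
#'   with margins), `percent` (same shape, % of total).
#' @export
crosstab_enterotype_function <- function(genus_result, kegg_result) {
  ga <- if (inherits(genus_result, "clustering_result"))
    setNames(genus_result$assignments, genus_result$sample_ids) else genus_result
  ka <- if (inherits(kegg_result, "clustering_result"))
    setNames(kegg_result$assignments, kegg_result$sample_ids) else kegg_result
  if (!setequal(names(ga), names(ka)))
    stop_validation("enterotype and functional-cluster results cover different samples")
  ka <- ka[names(ga)]
  tab <- table(functional_cluster = ka, enterotype = ga)
  counts <- stats::addmargins(tab)
  dimnames(counts) <- list(
    functional_cluster = c(paste0("functional_cluster_", rownames(tab)), "total"),
    enterotype = c(paste0("enterotype_", colnames(tab)), "total"))
  percent <- round_half_up(100 * counts / sum(tab), 1)
  list(counts = counts, percent = percent)
}
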