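# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force enumeration, direct formula
# evaluation, and exhaustive search at tiny n.

# exhaustive k-medoids: best total cost over all C(n, k) medoid sets
brute_force_pam_cost <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  sets <- combn(n, k)
  for (j in seq_len(ncol(sets))) {
    med <- sets[, j]
    cost <- sum(apply(D[, med, drop = FALSE], 1L, min))
    if (cost < best) best <- cost
  }
  best
}

# direct Jensen-Shannon divergence, term-by-term KL evaluation
jsd_direct <- function(p, q, base = 2) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b, base = base), 0))
  kl(p, m) / 2 + kl(q, m) / 2
}

# exact two-sided rank-sum p by enumerating all splits of the pooled values
enum_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  splits <- combn(length(pooled), nx)
  stats <- apply(splits, 2L, function(idx) sum(r[idx]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
enum_signedrank_p <- function(d) {
  d <- d[d != 0]
  stopifnot(!anyDuplicated(abs(d)))
  r <- rank(abs(d))
  n <- length(d)
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  stats <- apply(signs, 1L, function(s) sum(r[s]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# random distance matrix from points in the plane (Euclidean, metric-valid)
random_euclidean_dist <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 2), n, 2)
  distance_matrix(as.matrix(dist(pts)), metric = "eu",
                  sample_ids = paste0("S", seq_len(n)))
}

# small abundance fixture: k well-separated blobs on the simplex
blob_abundance <- function(sizes, centers, noise = 0.01, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (b in seq_along(sizes)) {
    for (i in seq_len(sizes[b])) {
      v <- abs(centers[[b]] + rnorm(length(centers[[b]]), 0, noise))
      rows[[length(rows) + 1L]] <- v / sum(v)
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("S", seq_len(nrow(m)))
  colnames(m) <- paste0("G", seq_len(ncol(m)))
  abundance_table(m)
}

# paper-shaped design: 8 pairs at two time points + 2 pairs at one
paper_design <- function() {
  rows <- list()
  for (p in 1:10) for (s in 1:2) for (tm in if (p <= 8) 1:2 else 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("P%02d_T%d_V%d", p, s, tm),
      subject_id = sprintf("P%02d_T%d", p, s),
      pair_id = sprintf("P%02d", p), time_point = tm,
      stringsAsFactors = FALSE)
  twin_design(do.call(rbind, rows))
}
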