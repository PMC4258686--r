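#' Renormalize abundance profiles to relative abundances
#'
#' Adds a pseudocount to every entry, then divides each sample row by its
#' sum.  A strictly positive pseudocount guarantees strictly positive
#' output, which the Jensen-Shannon distance needs (KL terms with zeros are
#' undefined).  With `pseudocount = 0` this is plain closure to 1 and is
#' idempotent on already-normalized rows.
#'
#' @param t an [abundance_table()].
#' @param pseudocount small non-negative real added to every entry before
#'   closure; default `1e-6`.
#' @return an [abundance_table()] whose rows sum to 1.
#' @export
normalize_profiles <- function(t, pseudocount = 1e-6) {
  stopifnot(is_abundance_table(t), pseudocount >= 0)
  m <- unclass(t) + pseudocount
  rs <- rowSums(m)
  if (any(rs == 0))
    stop_validation("sample '%s' has an all-zero profile and pseudocount 0",
                    rownames(m)[which(rs == 0)[1L]])
  abundance_table(m / rs, level = attr(t, "level"))
}

#' Construct a labeled distance matrix
#'
#' @param D symmetric non-negative matrix with zero diagonal.
#' @param metric tag, one of `"js"`, `"bc"`, `"eu"`.
#' @param sample_ids labels; default from dimnames.
#' @return a `distance_matrix` object.
#' @export
distance_matrix <- function(D, metric, sample_ids = rownames(D)) {
  D <- as.matrix(D)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(D)))
  if (nrow(D) != ncol(D)) stop_validation("distance matrix must be square")
  if (anyNA(D) || any(!is.finite(D)))
    stop_validation("non-finite distances")
  if (max(abs(D - t(D))) > 1e-8) stop_validation("distance matrix not symmetric")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  if (any(D < 0)) stop_validation("negative distances")
  dimnames(D) <- list(sample_ids, sample_ids)
  structure(D, metric = metric,
            class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d samples, metric %s\n",
              nrow(x), attr(x, "metric")))
  invisible(x)
}

# Jensen-Shannon divergence between all row pairs of a strictly positive
# row-stochastic matrix; log base `base` (base 2 bounds the divergence by 1).
js_divergence_matrix <- function(m, base = 2) {
  n <- nrow(m)
  lg <- function(x) log(x, base = base)
  # JSD(p,q) = H(m) - (H(p)+H(q))/2 with m=(p+q)/2, H = -sum x log x
  H <- function(x) -rowSums(x * lg(x))
  h <- H(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    mid <- (m[rep(i, n - i), , drop = FALSE] + m[(i + 1L):n, , drop = FALSE]) / 2
    jsd <- H(mid) - (h[i] + h[(i + 1L):n]) / 2
    D[i, (i + 1L):n] <- D[(i + 1L):n, i] <- pmax(jsd, 0)
  }
  D
}

#' Pairwise inter-sample distances
#'
#' Three metrics:
#' \describe{
#'   \item{js}{Jensen-Shannon distance, the square root of the JS divergence
#'     \eqn{JSD(p,q) = \frac12 KL(p\|m) + \frac12 KL(q\|m)} with
#'     \eqn{m=(p+q)/2}; with base-2 logarithms (the default) it lies in
#'     \eqn{[0,1]} and is a metric.  Requires strictly positive profiles —
#'     apply [normalize_profiles()] with a pseudocount first.}
#'   \item{bc}{Bray-Curtis dissimilarity
#'     \eqn{\sum|p_i-q_i| / \sum(p_i+q_i)}, computed with
#'     \code{vegan::vegdist}.}
#'   \item{eu}{Euclidean distance on the relative abundances (no transform).}
#' }
#'
#' @param t an [abundance_table()] of relative abundances.
#' @param metric `"js"`, `"bc"` or `"eu"`.
#' @param base logarithm base for the JS divergence; 2 (default) bounds the
#'   JS distance by 1, base e by \eqn{\sqrt{\ln 2}}.
#' @return a [distance_matrix()].
#' @export
pairwise_distance <- function(t, metric = c("js", "bc", "eu"), base = 2) {
  metric <- match.arg(metric)
  stopifnot(is_abundance_table(t))
  m <- unclass(t)
  if (anyNA(m) || any(!is.finite(m))) stop_validation("non-finite abundances")
  D <- switch(metric,
    js = {
      if (any(m <= 0))
        stop_validation("js distance needs strictly positive profiles; use normalize_profiles() with a pseudocount")
      sqrt(js_divergence_matrix(m, base = base))
    },
    bc = as.matrix(vegan::vegdist(m, method = "bray")),
    eu = as.matrix(dist(m, method = "euclidean")))
  distance_matrix(D, metric = metric, sample_ids = rownames(m))
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers \eqn{-\frac12 D^2}, eigendecomposes, and returns the
#' coordinates on the top `n_axes` axes with non-negative eigenvalues.
#' Negative eigenvalues (js and bc are generally non-Euclidean) are clamped
#' to zero; their total magnitude is reported so the distortion is visible.
#'
#' @param D a [distance_matrix()].
#' @param n_axes number of axes to keep (at most n-1).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all n),
#'   `negative_magnitude` (sum of |negative eigenvalues|) and
#'   `variance_explained` (fraction per kept axis over positive eigenvalues).
#' @export
pcoa <- function(D, n_axes = 2) {
  stopifnot(inherits(D, "distance_matrix"))
  n <- nrow(D)
  if (n_axes > n - 1L) stop_validation("n_axes must be at most n-1 (= %d)", n - 1L)
  sc <- suppressWarnings(cmdscale(unclass(D), k = n - 1L, eig = TRUE))
  ev <- sc$eig
  pos <- which(ev > 1e-12)
  keep <- head(pos, n_axes)
  coords <- matrix(0, n, n_axes,
                   dimnames = list(rownames(D), paste0("PCo", seq_len(n_axes))))
  if (length(keep))
    coords[, seq_along(keep)] <- sc$points[, keep, drop = FALSE]
  list(coordinates = coords,
       eigenvalues = ev,
       negative_magnitude = sum(abs(ev[ev < 0])),
       variance_explained = if (length(keep)) ev[keep] / sum(ev[pos]) else numeric(0))
}

#' Write a distance matrix as a labeled square TSV
#' @param D a [distance_matrix()].
#' @param path output path.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(D), as.data.frame(unclass(D)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square TSV distance matrix
#' @param path file path.
#' @param metric metric tag to attach.
#' @return a [distance_matrix()].
#' @export
read_distance_matrix <- function(path, metric = "js") {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  distance_matrix(m, metric = metric, sample_ids = rownames(m))
}
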