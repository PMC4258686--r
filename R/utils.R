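# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage seed from a global seed
#'
#' A single run-level seed fans out to per-stage seeds by hashing the stage
#' name, so any stage can be re-run in isolation with the same stream.  The
#' hash is a small deterministic polynomial over the stage-name bytes, kept
#' below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(1L, "clustering")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 1987651653
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# pmin over the columns of a matrix (row-wise minimum), without apply()
row_mins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# round half away from zero: matches how clinical papers print percentages
# (base round() is half-to-even: round(81.25, 1) == 81.2)
round_half_up <- function(x, digits = 1L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# which.min over rows, first (lowest index) winner on ties
row_which_min <- function(m) {
  mins <- row_mins(m)
  out <- integer(nrow(m))
  for (j in rev(seq_len(ncol(m)))) out[m[, j] == mins] <- j
  out
}
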