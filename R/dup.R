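#' Random subsample of read pairs
#'
#' Dataset-level quality control runs on random subsets of 20,000 reads;
#' sampling is uniform without replacement and deterministic given `seed`.
#' When the input has at most `n` rows it is returned whole.
#'
#' @param pairs A pair tibble (or any data frame).
#' @param n Subsample size, default 20000.
#' @param seed Integer seed.
#' @return A tibble of at most `n` rows.
#' @export
subsample_pairs <- function(pairs, n = 20000L, seed = 1L) {
  stopifnot(n >= 1)
  if (nrow(pairs) <= n) return(pairs)
  idx <- with_seed(seed, sort(sample.int(nrow(pairs), n)))
  pairs[idx, , drop = FALSE]
}

#' Estimate duplicate-sequence rates from a sample of raw read pairs
#'
#' Duplicates are exact full-length sequence copies (bases only; qualities
#' ignored). Three rates are reported: read1 alone, read2 alone, and the
#' paired rate on the mate-sequence combination. Each rate is
#' `1 - distinct / n_sampled`. High paired duplicate rates flag
#' low-complexity libraries. Estimation is meant to run on raw (untrimmed)
#' reads; set `prefix` to compare only the first `prefix` bases.
#'
#' @param pairs A non-empty pair tibble, normally a [subsample_pairs()] of the
#'   raw input.
#' @param prefix Compare only the first `prefix` bases of each mate
#'   (0 = full length, the default).
#' @return A `dup_estimate` one-row tibble: `n_sampled`, `single_rate_r1`,
#'   `single_rate_r2`, `paired_rate`.
#' @export
estimate_duplicates <- function(pairs, prefix = 0L) {
  if (!nrow(pairs)) abort("cannot estimate duplicate rates from an empty sample")
  b1 <- pairs$bases1
  b2 <- pairs$bases2
  if (prefix > 0L) {
    b1 <- substr(b1, 1L, prefix)
    b2 <- substr(b2, 1L, prefix)
  }
  n <- length(b1)
  out <- tibble(
    n_sampled = n,
    single_rate_r1 = 1 - length(unique(b1)) / n,
    single_rate_r2 = 1 - length(unique(b2)) / n,
    paired_rate = 1 - length(unique(paste(b1, b2, sep = "|"))) / n
  )
  class(out) <- c("dup_estimate", class(out))
  out
}
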