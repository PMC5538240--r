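#' Configuration for read-pair merging
#'
#' The published thresholds: a 36-nt seed taken from read 2, a minimum
#' accepted overlap of 15 nt, fewer than 4 mismatches (so at most 3), and at
#' least 90% identity over the overlap. `max_mismatches` is an exclusive
#' bound, matching "less than 4 mismatches".
#'
#' @param seed_len Seed length in nt (default 36).
#' @param min_overlap Minimum overlap length in nt (default 15).
#' @param max_mismatches Exclusive mismatch bound (default 4).
#' @param min_identity Minimum overlap identity fraction (default 0.90).
#' @return A `merge_config` list.
#' @export
merge_config <- function(seed_len = 36L, min_overlap = 15L,
                         max_mismatches = 4L, min_identity = 0.90) {
  stopifnot(
    min_overlap >= 1, seed_len >= min_overlap,
    max_mismatches >= 1, min_identity > 0, min_identity <= 1
  )
  structure(
    list(
      seed_len = as.integer(seed_len),
      min_overlap = as.integer(min_overlap),
      max_mismatches = as.integer(max_mismatches),
      min_identity = min_identity
    ),
    class = "merge_config"
  )
}

# Evaluate candidate offsets of rc2 on r1 (raw vectors). Offsets are 0-based:
# rc2 position 1 sits on r1 position o + 1. Any position involving N counts
# as a mismatch. Returns list(offset, overlap_len, mismatches, identity) of
# the best accepted candidate, or NULL.
scan_offsets <- function(r1, rc2, offsets, cfg) {
  L1 <- length(r1)
  L2 <- length(rc2)
  nraw <- charToRaw("N")
  best <- NULL
  best_key <- c(-1, -1, Inf) # matches, overlap_len, -offset ordering
  for (o in offsets) {
    ov <- min(L1 - o, L2)
    if (ov < cfg$min_overlap) next
    a <- r1[(o + 1L):(o + ov)]
    b <- rc2[1:ov]
    mm <- sum(a != b | a == nraw | b == nraw)
    if (mm >= cfg$max_mismatches) next
    ident <- (ov - mm) / ov
    if (ident < cfg$min_identity) next
    matches <- ov - mm
    better <- matches > best_key[1] ||
      (matches == best_key[1] && ov > best_key[2]) ||
      (matches == best_key[1] && ov == best_key[2] && o < best_key[3])
    if (better) {
      best <- list(offset = o, overlap_len = ov, mismatches = mm,
                   identity = ident)
      best_key <- c(matches, ov, o)
    }
  }
  best
}

#' Find the best overlap between read 1 and the reverse-complemented read 2
#'
#' The normative semantics is an exhaustive ungapped scan over every offset
#' `o` in `0 .. len(read1) - min_overlap`, where the overlap is `rc2` laid on
#' read 1 starting at position `o` (0-based) with length
#' `min(len(read1) - o, len(rc2))`. Mismatches are counted positionally (any
#' position involving N is a mismatch); identity is
#' `(overlap - mismatches) / overlap`. Candidates failing the minimum
#' overlap, mismatch or identity threshold are rejected; among survivors the
#' one with the most matching positions wins, ties going to the longer
#' overlap and then the smaller offset.
#'
#' The default `"seed"` method reproduces this result faster: offsets whose
#' overlap contains the full `seed_len`-nt seed (the leading bases of `rc2`)
#' are pre-filtered on seed mismatches alone, which can only discard offsets
#' the full scan would also reject; shorter-overlap offsets are scanned
#' directly.
#'
#' @param bases1 Read 1 sequence (character scalar).
#' @param rc2 Reverse-complemented read 2 sequence (character scalar).
#' @param config A [merge_config()].
#' @param method `"seed"` (default) or `"exhaustive"`; both return identical
#'   results.
#' @return A list `(offset, overlap_len, mismatches, identity)` with `offset`
#'   0-based on read 1, or `NULL` when no candidate passes.
#' @export
scan_overlaps <- function(bases1, rc2, config = merge_config(),
                          method = c("seed", "exhaustive")) {
  method <- match.arg(method)
  r1 <- charToRaw(bases1)
  r2 <- charToRaw(rc2)
  L1 <- length(r1)
  L2 <- length(r2)
  max_o <- L1 - config$min_overlap
  if (max_o < 0L) return(NULL)
  offsets <- 0:max_o
  if (method == "seed" && L2 >= config$seed_len) {
    sl <- config$seed_len
    seed <- r2[1:sl]
    nraw <- charToRaw("N")
    full <- offsets[L1 - offsets >= sl] # seed fully inside the overlap
    keep <- vapply(full, function(o) {
      a <- r1[(o + 1L):(o + sl)]
      sum(a != seed | a == nraw | seed == nraw) < config$max_mismatches
    }, logical(1))
    offsets <- c(full[keep], offsets[L1 - offsets < sl])
  }
  scan_offsets(r1, r2, offsets, config)
}

# Consensus over the overlap given raw bases and integer quals.
# At agreeing positions keep the base with quality max(q1, q2); at
# disagreements keep the higher-quality read's base (ties -> read 1); an N
# defers to the non-N base.
overlap_consensus <- function(a, b, qa, qb) {
  nraw <- charToRaw("N")
  base <- a
  qual <- pmax(qa, qb)
  agree <- a == b
  an <- a == nraw
  bn <- b == nraw
  take2 <- (!agree & !an & !bn & qb > qa) | (an & !bn)
  base[take2] <- b[take2]
  disagree <- !agree & !an & !bn
  qual[disagree] <- ifelse(qb[disagree] > qa[disagree],
                           qb[disagree], qa[disagree])
  qual[an & !bn] <- qb[an & !bn]
  qual[bn & !an] <- qa[bn & !an]
  list(base = base, qual = as.integer(qual))
}

#' Merge one read pair into a consensus fragment
#'
#' Runs [scan_overlaps()] on read 1 against the reverse complement of read 2.
#' If an overlap is accepted, the merged read is read 1 up to the overlap,
#' then the per-position consensus (the higher-quality base wins; agreeing
#' bases keep the higher of the two qualities), then the remainder of the
#' reverse-complemented read 2 — or of read 1 when read 2 is contained. The
#' merged length is `max(len(read1), offset + len(read2))`. An unmerged pair
#' passes through untouched.
#'
#' @param bases1,quals1 Read 1 sequence and Phred scores.
#' @param bases2,quals2 Read 2 sequence and Phred scores (as sequenced; the
#'   reverse complement is taken internally).
#' @param config A [merge_config()].
#' @param read_id Identifier for the merged read.
#' @param method Candidate-generation method, see [scan_overlaps()].
#' @return A list: `status` ("merged"/"unmerged"); for merged pairs `bases`,
#'   `quals`, `offset` (0-based overlap start on read 1), `overlap_len`,
#'   `mismatches`, `identity`.
#' @export
merge_pair <- function(bases1, quals1, bases2, quals2,
                       config = merge_config(), read_id = "merged",
                       method = "seed") {
  rc2 <- revcomp(bases2)
  q2r <- rev(as.integer(quals2))
  cand <- scan_overlaps(bases1, rc2, config, method = method)
  if (is.null(cand)) return(list(status = "unmerged"))
  o <- cand$offset
  ov <- cand$overlap_len
  r1 <- charToRaw(bases1)
  r2 <- charToRaw(rc2)
  q1 <- as.integer(quals1)
  L1 <- length(r1)
  L2 <- length(r2)
  cons <- overlap_consensus(
    r1[(o + 1L):(o + ov)], r2[1:ov],
    q1[(o + 1L):(o + ov)], q2r[1:ov]
  )
  head_b <- if (o > 0L) r1[1:o] else raw()
  head_q <- if (o > 0L) q1[1:o] else integer()
  if (o + L2 > L1) {
    tail_b <- if (ov < L2) r2[(ov + 1L):L2] else raw()
    tail_q <- if (ov < L2) q2r[(ov + 1L):L2] else integer()
  } else {
    tail_b <- if (o + ov < L1) r1[(o + ov + 1L):L1] else raw()
    tail_q <- if (o + ov < L1) q1[(o + ov + 1L):L1] else integer()
  }
  list(
    status = "merged",
    read_id = read_id,
    bases = rawToChar(c(head_b, cons$base, tail_b)),
    quals = c(head_q, cons$qual, tail_q),
    offset = o,
    overlap_len = ov,
    mismatches = cand$mismatches,
    identity = cand$identity
  )
}

#' Merge a tibble of read pairs
#'
#' Applies [merge_pair()] to every row and splits the input into merged
#' consensus reads and untouched unmerged pairs, with summary statistics
#' (merged fraction, merged-length mean/median, a full length histogram, and
#' the median merged length as the insert-size estimate).
#'
#' @param pairs A pair tibble.
#' @param config A [merge_config()].
#' @param method Candidate-generation method, see [scan_overlaps()].
#' @return A list of class `merge_result`: `merged` (a reads tibble with
#'   overlap diagnostics columns), `unmerged` (a pair tibble), and `stats`
#'   (class `merge_stats`: `n_pairs`, `n_merged`, `merged_fraction`,
#'   `merged_len_mean`, `merged_len_median`, `insert_size_estimate`, and a
#'   `length_histogram` tibble).
#' @export
merge_pairs <- function(pairs, config = merge_config(), method = "seed") {
  outs <- purrr::pmap(
    list(pairs$bases1, pairs$quals1, pairs$bases2, pairs$quals2,
         pairs$pair_id),
    function(b1, q1, b2, q2, id) {
      merge_pair(b1, q1, b2, q2, config = config, read_id = id,
                 method = method)
    }
  )
  ok <- vapply(outs, function(x) x$status == "merged", logical(1))
  merged <- tibble(
    read_id = vapply(outs[ok], `[[`, character(1), "read_id"),
    bases = vapply(outs[ok], `[[`, character(1), "bases"),
    quals = lapply(outs[ok], `[[`, "quals"),
    offset = vapply(outs[ok], `[[`, integer(1), "offset"),
    overlap_len = vapply(outs[ok], `[[`, integer(1), "overlap_len"),
    mismatches = vapply(outs[ok], function(x) as.integer(x$mismatches),
                        integer(1)),
    identity = vapply(outs[ok], `[[`, numeric(1), "identity")
  )
  lens <- nchar(merged$bases)
  hist_tbl <- if (length(lens)) {
    dplyr::count(tibble(length = lens), .data$length, name = "count")
  } else {
    tibble(length = integer(), count = integer())
  }
  stats <- structure(
    list(
      n_pairs = nrow(pairs),
      n_merged = sum(ok),
      merged_fraction = if (nrow(pairs)) sum(ok) / nrow(pairs) else 0,
      merged_len_mean = if (length(lens)) mean(lens) else NA_real_,
      merged_len_median = if (length(lens)) median(lens) else NA_real_,
      insert_size_estimate = if (length(lens)) median(lens) else NA_real_,
      length_histogram = hist_tbl
    ),
    class = "merge_stats"
  )
  structure(
    list(merged = merged, unmerged = pairs[!ok, , drop = FALSE], stats = stats),
    class = "merge_result"
  )
}

#' @export
print.merge_stats <- function(x, ...) {
  cat(sprintf(
    "<merge_stats> %d/%d pairs merged (%.1f%%); merged length median %s, mean %s\n",
    x$n_merged, x$n_pairs, 100 * x$merged_fraction,
    format(x$merged_len_median), format(round(x$merged_len_mean, 1))
  ))
  invisible(x)
}
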