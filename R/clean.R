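#' Configuration for the read-cleaning cascade
#'
#' Defaults follow the published pipeline: terminal bases below Q20 are
#' trimmed, reads shorter than 30 nt after trimming are discarded. Adapter
#' matching is ungapped: a full-length adapter occurrence anywhere in the
#' read, or an adapter prefix of at least `adapter_min_match` nt anchored at
#' the read 3' end (read-through into the adapter), in both cases tolerating
#' up to `floor(adapter_error_rate * matched_length)` mismatches.
#'
#' @param adapters Character vector of adapter/primer sequences over {A,C,G,T}.
#' @param qual_threshold Phred score below which terminal bases are trimmed
#'   (default 20; a Q20 base is kept, Q19 is not).
#' @param min_length Minimum post-trimming read length in nt (default 30).
#' @param adapter_min_match Minimum 3'-anchored adapter prefix length (default 10).
#' @param adapter_error_rate Tolerated mismatch fraction in adapter matches
#'   (default 0.1).
#' @return A `clean_config` list.
#' @export
clean_config <- function(adapters = character(),
                         qual_threshold = 20L,
                         min_length = 30L,
                         adapter_min_match = 10L,
                         adapter_error_rate = 0.1) {
  adapters <- toupper(as.character(adapters))
  if (any(!nzchar(adapters))) abort("empty adapter sequence in config")
  if (any(grepl("[^ACGT]", adapters))) {
    abort("adapters must be sequences over {A,C,G,T}")
  }
  stopifnot(
    qual_threshold >= 0, min_length >= 1,
    adapter_error_rate >= 0, adapter_error_rate < 0.5,
    adapter_min_match >= 1
  )
  structure(
    list(
      adapters = adapters,
      qual_threshold = as.integer(qual_threshold),
      min_length = as.integer(min_length),
      adapter_min_match = as.integer(adapter_min_match),
      adapter_error_rate = adapter_error_rate
    ),
    class = "clean_config"
  )
}

# Merge sorted-by-start closed intervals, coalescing overlaps/adjacency.
merge_intervals <- function(starts, ends) {
  if (!length(starts)) {
    return(list(start = integer(), end = integer()))
  }
  o <- order(starts, ends)
  starts <- starts[o]
  ends <- ends[o]
  ms <- starts[1]
  me <- ends[1]
  out_s <- integer()
  out_e <- integer()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1L) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- starts[i]
      me <- ends[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Locate adapter occurrences in one read
#'
#' Returns the maximal intervals of the read covered by adapter occurrences,
#' 1-based inclusive coordinates, sorted and merged. An occurrence is an
#' ungapped match of the full adapter anywhere, or of an adapter prefix of
#' length >= `adapter_min_match` anchored at the 3' end, with mismatches
#' <= `floor(adapter_error_rate * matched_length)`. An N in the read never
#' matches an adapter base.
#'
#' @param bases A single read sequence (character scalar).
#' @param config A [clean_config()].
#' @return A tibble with columns `start`, `end` (possibly zero rows).
#' @export
locate_adapter_hits <- function(bases, config) {
  stopifnot(length(bases) == 1L, inherits(config, "clean_config"))
  L <- nchar(bases)
  rr <- charToRaw(bases)
  nraw <- charToRaw("N")
  hs <- integer()
  he <- integer()
  for (ad in config$adapters) {
    ar <- charToRaw(ad)
    A <- length(ar)
    # full-length internal occurrences
    if (L >= A) {
      allowed <- floor(config$adapter_error_rate * A)
      for (s in seq_len(L - A + 1L)) {
        w <- rr[s:(s + A - 1L)]
        mm <- sum(w != ar | w == nraw)
        if (mm <= allowed) {
          hs <- c(hs, s)
          he <- c(he, s + A - 1L)
        }
      }
    }
    # 3'-anchored prefix occurrences (adapter read-through)
    pmax_len <- min(A, L)
    if (pmax_len >= config$adapter_min_match) {
      # longest matching prefix wins: its interval contains all shorter ones
      for (p in pmax_len:config$adapter_min_match) {
        w <- rr[(L - p + 1L):L]
        mm <- sum(w != ar[1:p] | w == nraw)
        if (mm <= floor(config$adapter_error_rate * p)) {
          hs <- c(hs, L - p + 1L)
          he <- c(he, L)
          break
        }
      }
    }
  }
  iv <- merge_intervals(hs, he)
  tibble(start = iv$start, end = iv$end)
}

#' End-trimming interval of a quality vector
#'
#' Finds the span left after removing low-quality bases from both ends:
#' `start` is the first position with quality >= `qual_threshold` and `end`
#' the last. Interior low-quality bases are retained. Returns the empty
#' interval `c(1, 0)` when no base qualifies.
#'
#' @param quals Integer vector of Phred scores.
#' @param qual_threshold Minimum terminal quality (default 20).
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
quality_keep_interval <- function(quals, qual_threshold = 20L) {
  ok <- which(quals >= qual_threshold)
  if (!length(ok)) return(c(1L, 0L))
  c(ok[1], ok[length(ok)])
}

#' Truncation point at the second N
#'
#' Everything from the second unknown base (N) to the end of the read is
#' dropped, so a kept read retains at most one N.
#'
#' @param bases A single read sequence.
#' @return The 1-based position of the second N, or `NA_integer_` if the read
#'   has fewer than two Ns. The kept prefix is `1:(pos - 1)`.
#' @export
second_n_cut <- function(bases) {
  npos <- gregexpr("N", bases, fixed = TRUE)[[1]]
  if (npos[1] == -1L || length(npos) < 2L) return(NA_integer_)
  as.integer(npos[2])
}

# Core single-read trim. Returns list(status, reason, start, end).
clean_one <- function(bases, quals, config) {
  L <- nchar(bases)
  discarded <- list(status = "discarded", reason = "too_short",
                    start = NA_integer_, end = NA_integer_)
  if (L == 0L) return(discarded)
  # 1. mask adapter intervals; 2. complement = candidate runs
  hits <- if (length(config$adapters)) locate_adapter_hits(bases, config) else
    tibble(start = integer(), end = integer())
  run_s <- integer()
  run_e <- integer()
  pos <- 1L
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      if (hits$start[i] > pos) {
        run_s <- c(run_s, pos)
        run_e <- c(run_e, hits$start[i] - 1L)
      }
      pos <- hits$end[i] + 1L
    }
  }
  if (pos <= L) {
    run_s <- c(run_s, pos)
    run_e <- c(run_e, L)
  }
  if (!length(run_s)) return(discarded)
  # 3. per-run quality end-trim then second-N truncation
  best_s <- 0L
  best_e <- -1L
  for (i in seq_along(run_s)) {
    a <- run_s[i]
    b <- run_e[i]
    ki <- quality_keep_interval(quals[a:b], config$qual_threshold)
    if (ki[2] < ki[1]) next
    s <- a + ki[1] - 1L
    e <- a + ki[2] - 1L
    ncut <- second_n_cut(substr(bases, s, e))
    if (!is.na(ncut)) {
      e <- s + ncut - 2L
      if (e < s) next
      # the cut can expose a low-quality 3' end: re-trim it
      ki2 <- quality_keep_interval(quals[s:e], config$qual_threshold)
      if (ki2[2] < ki2[1]) next
      e <- s + ki2[2] - 1L
    }
    if (e - s > best_e - best_s) { # strict: ties keep the leftmost segment
      best_s <- s
      best_e <- e
    }
  }
  if (best_e < best_s || best_e - best_s + 1L < config$min_length) {
    return(discarded)
  }
  list(status = "kept", reason = "none", start = best_s, end = best_e)
}

#' Trim one read through the full cleaning cascade
#'
#' Applies, in order: adapter masking, per-segment end trimming of bases
#' below the quality threshold, truncation at the second N, selection of the
#' longest surviving segment (ties resolved to the 5'-most), and the minimum
#' length filter. Coordinates refer to the original read.
#'
#' @param bases A single read sequence.
#' @param quals Its integer Phred scores.
#' @param config A [clean_config()].
#' @return A list: `status` ("kept"/"discarded"), `reason` ("none"/
#'   "too_short"), `start`, `end` (1-based inclusive kept interval), and for
#'   kept reads `bases` and `quals` of the trimmed read.
#' @export
clean_record <- function(bases, quals, config = clean_config()) {
  out <- clean_one(toupper(bases), as.integer(quals), config)
  if (out$status == "kept") {
    out$bases <- substr(toupper(bases), out$start, out$end)
    out$quals <- as.integer(quals)[out$start:out$end]
  }
  out
}

#' Trim every read in a tibble
#'
#' Vectorized [clean_record()]: returns the input rows with outcome columns
#' and, for kept reads, `bases`/`quals` replaced by the trimmed read.
#'
#' @param reads A reads tibble.
#' @param config A [clean_config()].
#' @return A tibble with columns `read_id`, `status`, `reason`, `trim_start`,
#'   `trim_end`, `bases`, `quals` (trimmed; `NA`/empty for discarded reads).
#' @export
clean_reads <- function(reads, config = clean_config()) {
  validate_reads(reads)
  outs <- purrr::map2(reads$bases, reads$quals, clean_one, config = config)
  status <- vapply(outs, `[[`, character(1), "status")
  start <- vapply(outs, `[[`, integer(1), "start")
  end <- vapply(outs, `[[`, integer(1), "end")
  kept <- status == "kept"
  bases <- ifelse(kept, substr(reads$bases, start, end), NA_character_)
  quals <- vector("list", nrow(reads))
  quals[kept] <- purrr::map2(reads$quals[kept], which(kept), function(q, i) {
    q[start[i]:end[i]]
  })
  tibble(
    read_id = reads$read_id,
    status = status,
    reason = vapply(outs, `[[`, character(1), "reason"),
    trim_start = start,
    trim_end = end,
    bases = bases,
    quals = quals
  )
}

#' Clean synchronized read pairs
#'
#' Both mates are trimmed independently. A pair survives when both mates are
#' kept; when exactly one mate survives it is routed to an orphan set rather
#' than silently dropped. Counts satisfy
#' `2 * pairs_in == 2 * pairs_kept + orphans + reads_discarded`.
#'
#' @param pairs A pair tibble (see [pair_reads()]).
#' @param config A [clean_config()].
#' @return A list of class `clean_result`: `pairs` (trimmed surviving pairs),
#'   `orphans` (a reads tibble), and `stats` (a one-row tibble with
#'   `pairs_in`, `pairs_kept`, `orphans`, `reads_discarded`).
#' @export
clean_pairs <- function(pairs, config = clean_config()) {
  c1 <- clean_reads(pairs_to_reads(pairs, 1L), config)
  c2 <- clean_reads(pairs_to_reads(pairs, 2L), config)
  k1 <- c1$status == "kept"
  k2 <- c2$status == "kept"
  both <- k1 & k2
  kept_pairs <- tibble(
    pair_id = pairs$pair_id[both],
    read_id1 = c1$read_id[both], bases1 = c1$bases[both], quals1 = c1$quals[both],
    read_id2 = c2$read_id[both], bases2 = c2$bases[both], quals2 = c2$quals[both]
  )
  o1 <- k1 & !k2
  o2 <- k2 & !k1
  orphans <- tibble(
    read_id = c(c1$read_id[o1], c2$read_id[o2]),
    bases = c(c1$bases[o1], c2$bases[o2]),
    quals = c(c1$quals[o1], c2$quals[o2])
  )
  stats <- tibble(
    pairs_in = nrow(pairs),
    pairs_kept = sum(both),
    orphans = nrow(orphans),
    reads_discarded = sum(!k1) + sum(!k2)
  )
  structure(
    list(pairs = kept_pairs, orphans = orphans, stats = stats),
    class = "clean_result"
  )
}
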