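#' Canonical k-mers of a set of sequences
#'
#' A k-mer and its reverse complement are collapsed to their lexicographic
#' minimum so matching is strand-independent. Windows containing N are
#' dropped (for index building) or counted as absent (for read matching).
#'
#' @param seqs Character vector of sequences.
#' @param k Odd k-mer length.
#' @return For `canonical_kmers()`: a list (one element per sequence) of
#'   canonical k-mer character vectors, N windows removed.
#' @keywords internal
canonical_kmers <- function(seqs, k) {
  n_win <- pmax(nchar(seqs) - k + 1L, 0L)
  all_k <- unlist(purrr::map2(seqs, n_win, function(s, nw) {
    if (nw == 0L) character() else substring(s, 1:nw, k:(k + nw - 1L))
  }), use.names = FALSE)
  grp <- rep(seq_along(seqs), n_win)
  keep <- !grepl("N", all_k, fixed = TRUE)
  all_k <- all_k[keep]
  grp <- grp[keep]
  if (length(all_k)) {
    rc <- revcomp(all_k)
    all_k <- pmin(all_k, rc)
  }
  out <- rep(list(character()), length(seqs))
  if (length(all_k)) {
    split_idx <- split(all_k, factor(grp, levels = seq_along(seqs)))
    out <- unname(split_idx)
  }
  out
}

#' Build a canonical k-mer index from reference sequences
#'
#' The index stands in for read mapping against a reference set (a PhiX-like
#' sequencing control, or an rRNA database): a read "maps" when a large
#' fraction of its canonical k-mers occur in the reference. `k` must be odd so
#' no k-mer is its own reverse complement.
#'
#' @param references Named character vector of reference sequences, or a path
#'   to a FASTA file.
#' @param k Odd k-mer length, default 21.
#' @return A `kmer_index` object (fields `k`, `kmers`, `source_ids`).
#' @export
build_kmer_index <- function(references, k = 21L) {
  if (length(references) == 1L && is.character(references) &&
      is.null(names(references)) && file.exists(references)) {
    references <- read_fasta(references)
  }
  k <- as.integer(k)
  if (!length(references)) abort("reference set is empty")
  if (k %% 2L == 0L) abort("k must be odd so canonical k-mers are unambiguous")
  references <- toupper(references)
  if (all(nchar(references) < k)) {
    warn(sprintf("all references shorter than k = %d; index is empty", k))
  }
  km <- unique(unlist(canonical_kmers(unname(references), k), use.names = FALSE))
  structure(
    list(
      k = k,
      kmers = km,
      source_ids = if (is.null(names(references))) character() else names(references)
    ),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf(
    "<kmer_index> k = %d, %d canonical k-mers from %d reference(s)\n",
    x$k, length(x$kmers), max(length(x$source_ids), 1L)
  ))
  invisible(x)
}

#' Fraction of a read's k-mers found in an index
#'
#' The denominator is the number of k-mer windows of the read (length − k + 1);
#' windows containing N count as absent. Reads shorter than k score 0.
#'
#' @param bases Character vector of read sequences.
#' @param index A [build_kmer_index()] result.
#' @return Numeric vector of match fractions in \[0, 1\].
#' @export
match_fraction <- function(bases, index) {
  stopifnot(inherits(index, "kmer_index"))
  if (!length(bases)) return(numeric())
  n_win <- pmax(nchar(bases) - index$k + 1L, 0L)
  kms <- canonical_kmers(bases, index$k)
  hits <- vapply(kms, function(x) sum(x %in% index$kmers), numeric(1))
  ifelse(n_win > 0L, hits / n_win, 0)
}

pair_matches <- function(pairs, index, min_fraction) {
  match_fraction(pairs$bases1, index) >= min_fraction |
    match_fraction(pairs$bases2, index) >= min_fraction
}

#' Remove read pairs matching a contaminant reference
#'
#' A pair is removed when either mate matches the index (its canonical k-mer
#' match fraction reaches `min_fraction`) — the read and its mate go together,
#' as in paired removal of sequencing-control (PhiX) reads.
#'
#' @param pairs A pair tibble.
#' @param index A contaminant [build_kmer_index()].
#' @param min_fraction Minimum match fraction to call a mate matching
#'   (default 0.5).
#' @return A list: `kept` (pair tibble, input order preserved), `removed`
#'   (pair tibble), `n_removed`.
#' @export
remove_contaminant_pairs <- function(pairs, index, min_fraction = 0.5) {
  hit <- pair_matches(pairs, index, min_fraction)
  list(
    kept = pairs[!hit, , drop = FALSE],
    removed = pairs[hit, , drop = FALSE],
    n_removed = sum(hit)
  )
}

#' Partition read pairs into ribosomal and non-ribosomal sets
#'
#' The metatranscriptomic split: pairs with either mate matching the rRNA
#' reference index go to the `ribo` set, all others to `noribo`. The two
#' outputs partition the input exactly.
#'
#' @param pairs A pair tibble.
#' @param index An rRNA [build_kmer_index()].
#' @param min_fraction Minimum match fraction (default 0.5).
#' @return A list with pair tibbles `ribo` and `noribo`.
#' @export
split_rrna_pairs <- function(pairs, index, min_fraction = 0.5) {
  hit <- pair_matches(pairs, index, min_fraction)
  list(
    ribo = pairs[hit, , drop = FALSE],
    noribo = pairs[!hit, , drop = FALSE]
  )
}
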