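# Shared fixture builders. All randomness goes through explicit seeds.

random_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

make_reads <- function(bases, q = 40L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(bases))
  fastq_tbl(ids, bases, lapply(nchar(bases), function(L) rep(as.integer(q), L)))
}

make_pairs <- function(bases1, bases2, q = 40L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("p%03d", seq_along(bases1))
  pair_reads(
    make_reads(bases1, q, paste0(ids, "/1")),
    make_reads(bases2, q, paste0(ids, "/2"))
  )
}

# An error-free 2 x read_len pair sequenced from `frag` (no read-through
# handling: frag must be >= read_len).
pair_from_fragment <- function(frag, read_len = 101L, q = 40L, id = "p001") {
  stopifnot(nchar(frag) >= read_len)
  b1 <- substr(frag, 1L, read_len)
  b2 <- revcomp(substr(frag, nchar(frag) - read_len + 1L, nchar(frag)))
  make_pairs(b1, b2, q = q, ids = id)
}

# Plant `m` substitutions at distinct overlap positions of a pair built from
# a fragment of length 2 * read_len - overlap; mutations go into read 2 so
# the fragment stays the read-1 truth. Positions are chosen deterministically
# (evenly spaced) to avoid clustering artifacts.
pair_with_overlap_mismatches <- function(overlap, m, read_len = 101L,
                                         seed = 1L) {
  frag <- random_seq(2L * read_len - overlap, seed = seed)
  pr <- pair_from_fragment(frag, read_len)
  if (m > 0) {
    b2 <- strsplit(pr$bases2[1], "")[[1]]
    # overlap position i (1..overlap, on rc2 coordinates) is read-2
    # as-sequenced position read_len - i + 1: the 3' end of read 2
    ov_pos <- unique(round(seq(1, overlap, length.out = m)))
    stopifnot(length(ov_pos) == m)
    pos <- read_len - ov_pos + 1L
    rot <- c(A = "C", C = "G", G = "T", T = "A")
    b2[pos] <- rot[b2[pos]]
    pr$bases2[1] <- paste(b2, collapse = "")
  }
  pr
}

# Independent brute-force overlap scanner used as the merging oracle:
# a direct transcription of the exhaustive semantics on character vectors,
# sharing no code with scan_overlaps().
oracle_scan <- function(b1, rc2, min_overlap = 15L, max_mismatches = 4L,
                        min_identity = 0.90) {
  c1 <- strsplit(b1, "")[[1]]
  c2 <- strsplit(rc2, "")[[1]]
  L1 <- length(c1)
  L2 <- length(c2)
  best <- NULL
  for (o in 0:(L1 - min_overlap)) {
    ov <- min(L1 - o, L2)
    if (ov < min_overlap) next
    a <- c1[(o + 1):(o + ov)]
    b <- c2[1:ov]
    mm <- sum(a != b | a == "N" | b == "N")
    if (mm >= max_mismatches) next
    if ((ov - mm) / ov < min_identity) next
    cand <- list(offset = o, overlap_len = ov, mismatches = mm)
    if (is.null(best)) {
      best <- cand
    } else {
      bm <- best$overlap_len - best$mismatches
      cm <- ov - mm
      if (cm > bm || (cm == bm && ov > best$overlap_len)) best <- cand
    }
  }
  best
}
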