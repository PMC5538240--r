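#' Phred quality arithmetic
#'
#' A Phred score Q encodes the probability that a base call is wrong as
#' 10^(-Q/10): Q30 means 1 error in 1,000 calls (99.9% accuracy).
#'
#' @param q Integer vector of Phred scores, all >= 0.
#' @return Numeric vector of error probabilities in \[0, 1\].
#' @examples
#' phred_error_prob(c(0, 20, 30))
#' @export
phred_error_prob <- function(q) {
  if (length(q) && any(q < 0, na.rm = TRUE)) {
    abort("Phred scores must be non-negative.")
  }
  10^(-q / 10)
}

#' Decode and encode Phred quality strings
#'
#' FASTQ stores per-base qualities as printable ASCII with an offset, almost
#' always 33 (Sanger/Illumina 1.8+). Offset 64 ingest is supported for legacy
#' files but never auto-detected.
#'
#' @param qual Character vector of quality strings.
#' @param quals List of integer Phred vectors.
#' @param offset ASCII offset, 33 by default.
#' @return `decode_quals()`: a list of integer vectors; `encode_quals()`: a
#'   character vector.
#' @export
decode_quals <- function(qual, offset = 33L) {
  lapply(qual, function(s) utf8ToInt(s) - as.integer(offset))
}

#' @rdname decode_quals
#' @export
encode_quals <- function(quals, offset = 33L) {
  vapply(
    quals,
    function(q) intToUtf8(as.integer(q) + as.integer(offset)),
    character(1)
  )
}

validate_reads <- function(reads, what = "reads") {
  stopifnot(is.data.frame(reads))
  need <- c("read_id", "bases", "quals")
  missing_cols <- setdiff(need, names(reads))
  if (length(missing_cols)) {
    abort(sprintf(
      "%s must have columns %s (missing: %s)",
      what, paste(need, collapse = ", "), paste(missing_cols, collapse = ", ")
    ))
  }
  bad_alpha <- grepl("[^ACGTN]", reads$bases)
  if (any(bad_alpha)) {
    abort(sprintf(
      "record %d: bases contain characters outside {A,C,G,T,N}",
      which(bad_alpha)[1]
    ))
  }
  len_mismatch <- nchar(reads$bases) != lengths(reads$quals)
  if (any(len_mismatch)) {
    abort(sprintf(
      "record %d: sequence and quality lengths differ",
      which(len_mismatch)[1]
    ))
  }
  qrange <- range(c(0L, unlist(reads$quals)))
  if (qrange[1] < 0 || qrange[2] > 60) {
    abort("quality values must lie in [0, 60]")
  }
  invisible(reads)
}

#' Construct a tibble of reads
#'
#' The package represents FASTQ records as a tibble with one row per read:
#' `read_id` (no leading `@`), `bases` (uppercase over {A,C,G,T,N}) and
#' `quals` (list column of integer Phred scores, one per base, each in
#' \[0, 60\]).
#'
#' @param read_id Character vector of read identifiers.
#' @param bases Character vector of sequences; lowercase is uppercased.
#' @param quals List of integer Phred vectors, one per read.
#' @return A validated tibble of reads.
#' @examples
#' fastq_tbl("r1", "acgt", list(c(30L, 30L, 40L, 40L)))
#' @export
fastq_tbl <- function(read_id, bases, quals) {
  reads <- tibble(
    read_id = as.character(read_id),
    bases = toupper(as.character(bases)),
    quals = lapply(quals, as.integer)
  )
  validate_reads(reads)
}

#' Read and write FASTQ files
#'
#' Plain or gzip-compressed 4-line FASTQ. `read_fastq()` uppercases bases and
#' validates the alphabet, the base/quality length match and the quality range;
#' malformed input errors name the offending record. `write_fastq()` always
#' emits Phred+33 and gzips when `path` ends in `.gz`.
#'
#' @param path File path; `.gz` handled transparently.
#' @param offset Phred ASCII offset of the input file (default 33; pass 64
#'   explicitly for legacy encodings — never auto-detected).
#' @param reads A reads tibble (see [fastq_tbl()]).
#' @return `read_fastq()`: a reads tibble. `write_fastq()`: the number of
#'   records written, invisibly.
#' @export
read_fastq <- function(path, offset = 33L) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    abort(sprintf(
      "truncated FASTQ: %d lines is not a multiple of 4 (record %d incomplete)",
      length(lines), length(lines) %/% 4L + 1L
    ))
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(tibble(read_id = character(), bases = character(), quals = list()))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qstr <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ record %d: missing '@' or '+' line", bad[1]))
  }
  reads <- tibble(
    read_id = substring(hdr, 2L),
    bases = toupper(seqs),
    quals = decode_quals(qstr, offset)
  )
  validate_reads(reads, what = path)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  n <- nrow(reads)
  if (n > 0L) {
    lines <- character(4L * n)
    lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$read_id)
    lines[seq(2L, by = 4L, length.out = n)] <- reads$bases
    lines[seq(3L, by = 4L, length.out = n)] <- "+"
    lines[seq(4L, by = 4L, length.out = n)] <- encode_quals(reads$quals)
    writeLines(lines, con)
  }
  invisible(n)
}

#' Pair identity of a read name
#'
#' Strips a trailing `/1` or `/2` mate suffix, or anything after the first
#' whitespace (both common conventions), leaving the fragment identifier the
#' two mates share.
#'
#' @param read_id Character vector of read identifiers.
#' @return Character vector of pair identifiers.
#' @export
pair_id_of <- function(read_id) {
  sub("/[12]$", "", sub("[ \t].*$", "", read_id))
}

#' Join two synchronized read tibbles into a pair tibble
#'
#' Read pairs are a tibble with one row per fragment: `pair_id`, then
#' `read_id1`, `bases1`, `quals1` and the mate's `read_id2`, `bases2`,
#' `quals2`. Mates must arrive in the same order in both inputs;
#' desynchronization (pair ids that disagree at some row) is an error naming
#' the first offending record.
#'
#' @param reads1,reads2 Reads tibbles of the two mate files, equal length.
#' @return A pair tibble.
#' @export
pair_reads <- function(reads1, reads2) {
  validate_reads(reads1, "reads1")
  validate_reads(reads2, "reads2")
  if (nrow(reads1) != nrow(reads2)) {
    abort(sprintf(
      "mate files differ in record count: %d vs %d", nrow(reads1), nrow(reads2)
    ))
  }
  id1 <- pair_id_of(reads1$read_id)
  id2 <- pair_id_of(reads2$read_id)
  bad <- which(id1 != id2)
  if (length(bad)) {
    abort(sprintf(
      "mates desynchronized at record %d: '%s' vs '%s'",
      bad[1], reads1$read_id[bad[1]], reads2$read_id[bad[1]]
    ))
  }
  tibble(
    pair_id = id1,
    read_id1 = reads1$read_id, bases1 = reads1$bases, quals1 = reads1$quals,
    read_id2 = reads2$read_id, bases2 = reads2$bases, quals2 = reads2$quals
  )
}

#' @rdname pair_reads
#' @param path1,path2 Paths of the two mate FASTQ files.
#' @param offset Phred ASCII offset (default 33).
#' @export
read_fastq_pairs <- function(path1, path2, offset = 33L) {
  pair_reads(read_fastq(path1, offset), read_fastq(path2, offset))
}

#' Split a pair tibble back into its two mate read tibbles
#'
#' @param pairs A pair tibble.
#' @param mate 1 or 2.
#' @return A reads tibble.
#' @export
pairs_to_reads <- function(pairs, mate = 1L) {
  stopifnot(mate %in% c(1L, 2L))
  if (mate == 1L) {
    tibble(read_id = pairs$read_id1, bases = pairs$bases1, quals = pairs$quals1)
  } else {
    tibble(read_id = pairs$read_id2, bases = pairs$bases2, quals = pairs$quals2)
  }
}

#' Reverse complement sequences (and reverse their qualities)
#'
#' `revcomp()` reverse-complements a character vector of sequences over
#' {A,C,G,T,N} (N maps to N). `reverse_complement()` does the same to a reads
#' tibble, reversing each quality vector alongside its bases and keeping
#' read ids.
#'
#' @param bases Character vector of sequences.
#' @param reads A reads tibble.
#' @return A character vector, or a reads tibble.
#' @export
revcomp <- function(bases) {
  if (!length(bases)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(bases)))
}

#' @rdname revcomp
#' @export
reverse_complement <- function(reads) {
  validate_reads(reads)
  tibble(
    read_id = reads$read_id,
    bases = revcomp(reads$bases),
    quals = lapply(reads$quals, rev)
  )
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file (plain or gzipped).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# Evaluate expr with the RNG seeded to `seed`, restoring global RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
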