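#' Simulator configuration
#'
#' Defaults mirror the overlap-merging metagenomic design: 2 x 101-nt reads
#' from gel-selected fragments of about 180 bp (sd 10), which leaves ~20-bp
#' mate overlaps. Reads from fragments shorter than the read length run
#' through into the adapter (then random bases). Qualities follow a linear
#' per-cycle decay. Optional spike-ins emit exact duplicate pairs and pairs
#' drawn from separate contaminant and rRNA references, all recorded in a
#' truth table.
#'
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param n_pairs Number of read pairs to emit.
#' @param read_len Read length in nt (default 101).
#' @param insert_mean,insert_sd Fragment-length distribution in nt
#'   (Normal, rounded, truncated at 2; defaults 180 and 10).
#' @param genome_len Length of the uniform-random source genome (default 1e5).
#' @param sub_error_rate Per-base substitution probability (default 0).
#' @param q_start,q_end Per-cycle quality profile endpoints (linear decay;
#'   defaults 38 and 30).
#' @param adapter Adapter sequence appended on read-through (default: the
#'   Illumina TruSeq universal adapter start).
#' @param dup_fraction Fraction of emitted pairs that are exact copies of
#'   earlier pairs (default 0).
#' @param contaminant_fraction,contaminant_genome_len Fraction of pairs drawn
#'   from a separate contaminant (sequencing-control-like) genome and its
#'   length.
#' @param rrna_fraction,rrna_ref_len Fraction of pairs drawn from a separate
#'   rRNA-like reference and its length.
#' @param n_rate Per-base probability of an N call (default 0).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_pairs = 1000L, read_len = 101L,
                       insert_mean = 180, insert_sd = 10,
                       genome_len = 100000L, sub_error_rate = 0,
                       q_start = 38L, q_end = 30L,
                       adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       dup_fraction = 0,
                       contaminant_fraction = 0,
                       contaminant_genome_len = 5000L,
                       rrna_fraction = 0, rrna_ref_len = 2000L,
                       n_rate = 0) {
  fracs <- c(sub_error_rate, dup_fraction, contaminant_fraction,
             rrna_fraction, n_rate)
  stopifnot(
    all(fracs >= 0 & fracs <= 1), read_len >= 1, insert_mean > 0,
    insert_sd >= 0, n_pairs >= 1, genome_len >= 1,
    q_start >= 0, q_start <= 60, q_end >= 0, q_end <= 60,
    dup_fraction + contaminant_fraction + rrna_fraction <= 1
  )
  structure(
    list(
      seed = as.integer(seed), n_pairs = as.integer(n_pairs),
      read_len = as.integer(read_len), insert_mean = insert_mean,
      insert_sd = insert_sd, genome_len = as.integer(genome_len),
      sub_error_rate = sub_error_rate, q_start = as.integer(q_start),
      q_end = as.integer(q_end), adapter = toupper(adapter),
      dup_fraction = dup_fraction,
      contaminant_fraction = contaminant_fraction,
      contaminant_genome_len = as.integer(contaminant_genome_len),
      rrna_fraction = rrna_fraction, rrna_ref_len = as.integer(rrna_ref_len),
      n_rate = n_rate
    ),
    class = "sim_config"
  )
}

#' Simulate a uniform-random reference sequence
#'
#' @param length Sequence length in nt.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @return A single character string over {A,C,G,T}.
#' @export
simulate_reference <- function(length, seed = 1L) {
  stopifnot(length >= 1)
  with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE),
    collapse = ""
  ))
}

# One sequenced strand of `read_len` bases from a fragment: the fragment (or
# its start), then the adapter on read-through, then random fill.
sequence_strand <- function(template, read_len, adapter) {
  tl <- nchar(template)
  if (tl >= read_len) return(substr(template, 1L, read_len))
  out <- paste0(template, adapter)
  if (nchar(out) < read_len) {
    fill <- paste(
      sample(c("A", "C", "G", "T"), read_len - nchar(out), replace = TRUE),
      collapse = ""
    )
    out <- paste0(out, fill)
  }
  substr(out, 1L, read_len)
}

# Apply substitutions (never to/from N) and N calls to a vector of reads.
apply_errors <- function(bases, sub_rate, n_rate) {
  if (sub_rate <= 0 && n_rate <= 0) return(bases)
  alt <- list(
    A = c("C", "G", "T"), C = c("A", "G", "T"),
    G = c("A", "C", "T"), T = c("A", "C", "G")
  )
  vapply(bases, function(b) {
    ch <- strsplit(b, "")[[1]]
    if (sub_rate > 0) {
      hit <- which(stats::runif(length(ch)) < sub_rate & ch != "N")
      for (i in hit) ch[i] <- sample(alt[[ch[i]]], 1L)
    }
    if (n_rate > 0) {
      ch[stats::runif(length(ch)) < n_rate] <- "N"
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired-end reads with known truth
#'
#' Each pair derives from a fragment whose length is drawn from
#' `Normal(insert_mean, insert_sd)`, rounded and truncated at 2. Read 1 is
#' the fragment's leading `read_len` bases; read 2 is the leading `read_len`
#' bases of the reverse-complemented fragment — both running through into the
#' adapter and random fill when the fragment is shorter than the read.
#' Substitution errors and N calls are applied independently per base;
#' qualities decay linearly from `q_start` to `q_end` across cycles.
#' Spiked-in pairs come from separate contaminant and rRNA references, and a
#' `dup_fraction` of emitted pairs are exact copies of earlier pairs.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_reads`: `pairs` (a pair tibble), `truth` (a
#'   tibble: pair_id, origin in {genome, contaminant, rrna}, `is_duplicate`,
#'   `fragment`, `frag_len`, `true_overlap`), and `references` (named
#'   character vector: genome plus any contaminant/rrna references).
#' @export
simulate_pairs <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    refs <- c(genome = paste(
      sample(c("A", "C", "G", "T"), config$genome_len, replace = TRUE),
      collapse = ""
    ))
    if (config$contaminant_fraction > 0) {
      refs["contaminant"] <- paste(
        sample(c("A", "C", "G", "T"), config$contaminant_genome_len,
               replace = TRUE),
        collapse = ""
      )
    }
    if (config$rrna_fraction > 0) {
      refs["rrna"] <- paste(
        sample(c("A", "C", "G", "T"), config$rrna_ref_len, replace = TRUE),
        collapse = ""
      )
    }
    n <- config$n_pairs
    n_dup <- round(config$dup_fraction * n)
    n_fresh <- n - n_dup
    n_contam <- round(config$contaminant_fraction * n)
    n_rrna <- round(config$rrna_fraction * n)
    if (n_contam + n_rrna > n_fresh) {
      abort("spike-in fractions leave no room for fresh genome pairs")
    }
    origin <- c(
      rep("contaminant", n_contam), rep("rrna", n_rrna),
      rep("genome", n_fresh - n_contam - n_rrna)
    )
    origin <- sample(origin)
    rl <- config$read_len
    flen <- pmax(2L, as.integer(round(
      rnorm(n_fresh, config$insert_mean, config$insert_sd)
    )))
    fragment <- character(n_fresh)
    b1 <- character(n_fresh)
    b2 <- character(n_fresh)
    for (i in seq_len(n_fresh)) {
      src <- refs[[origin[i]]]
      fl <- min(flen[i], nchar(src))
      flen[i] <- fl
      pos <- sample.int(nchar(src) - fl + 1L, 1L)
      frag <- substr(src, pos, pos + fl - 1L)
      fragment[i] <- frag
      b1[i] <- sequence_strand(frag, rl, config$adapter)
      b2[i] <- sequence_strand(revcomp(frag), rl, config$adapter)
    }
    b1 <- apply_errors(b1, config$sub_error_rate, config$n_rate)
    b2 <- apply_errors(b2, config$sub_error_rate, config$n_rate)
    qual_profile <- as.integer(round(
      seq(config$q_start, config$q_end, length.out = rl)
    ))
    # duplicates are exact copies of earlier pairs: fresh pairs are emitted
    # first, copies of randomly chosen fresh pairs after them
    src_idx <- if (n_dup > 0) sample.int(n_fresh, n_dup, replace = TRUE)
               else integer()
    take <- c(seq_len(n_fresh), src_idx)
    dup_flag <- c(rep(FALSE, n_fresh), rep(TRUE, n_dup))
    pair_ids <- sprintf("pair%06d", seq_len(n))
    pairs <- tibble(
      pair_id = pair_ids,
      read_id1 = paste0(pair_ids, "/1"),
      bases1 = b1[take],
      quals1 = rep(list(qual_profile), n),
      read_id2 = paste0(pair_ids, "/2"),
      bases2 = b2[take],
      quals2 = rep(list(qual_profile), n)
    )
    truth <- tibble(
      pair_id = pair_ids,
      origin = origin[take],
      is_duplicate = dup_flag,
      fragment = fragment[take],
      frag_len = flen[take],
      true_overlap = pmin(flen[take],
                          pmax(0L, 2L * rl - flen[take]),
                          rl)
    )
    structure(
      list(pairs = pairs, truth = truth, references = refs,
           config = config),
      class = "sim_reads"
    )
  })
}

#' Write simulated reads, references and truth table to disk
#'
#' @param sim A [simulate_pairs()] result.
#' @param dir Output directory (created if needed).
#' @param gzip Compress the FASTQ files.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim <- function(sim, dir, gzip = FALSE) {
  stopifnot(inherits(sim, "sim_reads"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- file.path(dir, paste0("reads_1", ext))
  p2 <- file.path(dir, paste0("reads_2", ext))
  write_fastq(pairs_to_reads(sim$pairs, 1L), p1)
  write_fastq(pairs_to_reads(sim$pairs, 2L), p2)
  pref <- file.path(dir, "references.fasta")
  write_fasta(sim$references, pref)
  ptruth <- file.path(dir, "truth.tsv")
  utils::write.table(as.data.frame(sim$truth), ptruth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(reads_1 = p1, reads_2 = p2, references = pref,
              truth = ptruth))
}
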