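adapter33 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA" # 33 nt

test_that("adapter hits: full internal occurrences are located and merged", {
  cfg <- clean_config(adapters = adapter33)
  read <- random_seq(101, seed = 11)
  expect_equal(nrow(locate_adapter_hits(read, cfg)), 0L)
  # embed the 33-nt adapter at positions 51..83 (1-based) of a 101-nt read
  planted <- paste0(substr(read, 1, 50), adapter33, substr(read, 84, 101))
  hits <- locate_adapter_hits(planted, cfg)
  expect_equal(hits$start, 51L)
  expect_equal(hits$end, 83L)
})

test_that("adapter hits agree with Biostrings matchPattern on mismatch-tolerant search", {
  cfg <- clean_config(adapters = adapter33, adapter_min_match = 200L)
  # min_match 200 disables anchored-prefix hits: pure internal search
  for (seed in 1:5) {
    read <- random_seq(150, seed = seed)
    mid <- strsplit(adapter33, "")[[1]]
    mid[c(5, 20)] <- setdiff(c("A", "C", "G", "T"), mid[c(5, 20)])[1:2]
    planted <- paste0(substr(read, 1, 40), paste(mid, collapse = ""),
                      substr(read, 74, 150))
    ours <- locate_adapter_hits(planted, cfg)
    ref <- Biostrings::matchPattern(
      adapter33, Biostrings::DNAString(planted),
      max.mismatch = floor(0.1 * nchar(adapter33))
    )
    expect_equal(ours$start, BiocGenerics::start(ref))
    expect_equal(ours$end, BiocGenerics::end(ref))
  }
})

test_that("3'-anchored adapter prefixes follow the floor(error_rate * length) rule", {
  cfg0 <- clean_config(adapters = adapter33, adapter_error_rate = 0)
  cfg <- clean_config(adapters = adapter33) # default 10% tolerance
  pre12 <- substr(adapter33, 1, 12)
  head48 <- random_seq(48, seed = 3)
  # pin the base 5' of the planted prefix so it cannot extend the match
  substr(head48, 48, 48) <- "T" # adapter starts with A
  read <- paste0(head48, pre12)
  # exact 12-nt prefix at the 3' end covers exactly the final 12 positions
  hits <- locate_adapter_hits(read, cfg0)
  expect_equal(c(hits$start, hits$end), c(49L, 60L))
  # one mismatch: rejected at zero tolerance, accepted at 10%
  # (floor(0.1 * 12) = 1 allowed mismatch)
  mism <- pre12
  substr(mism, 6, 6) <- "A" # pre12 position 6 is 'G'
  read_m <- paste0(head48, mism)
  expect_equal(nrow(locate_adapter_hits(read_m, cfg0)), 0L)
  hm <- locate_adapter_hits(read_m, cfg)
  expect_equal(nrow(hm), 1L)
  expect_equal(hm$end, 60L)
  # two mismatches exceed the 12-nt allowance
  two <- mism
  substr(two, 9, 9) <- "T" # pre12 position 9 is 'A'
  expect_equal(nrow(locate_adapter_hits(paste0(head48, two), cfg)), 0L)
  # a 9-nt prefix is below adapter_min_match
  head51 <- random_seq(51, seed = 4)
  substr(head51, 51, 51) <- "T"
  expect_equal(nrow(locate_adapter_hits(
    paste0(head51, substr(adapter33, 1, 9)), cfg0
  )), 0L)
})

test_that("quality end-trimming keeps the span of >= threshold bases, interior lows retained", {
  expect_equal(quality_keep_interval(rep(40L, 10)), c(1L, 10L))
  # spec trace: [10,10,40,40,40,40,40,40,40,10] -> positions 3..9
  expect_equal(quality_keep_interval(c(10L, 10L, rep(40L, 7), 10L)), c(3L, 9L))
  # boundary: Q20 kept, Q19 trimmed
  expect_equal(quality_keep_interval(rep(19L, 8)), c(1L, 0L))
  expect_equal(quality_keep_interval(rep(20L, 8)), c(1L, 8L))
  # interior low-quality bases are not removed
  expect_equal(quality_keep_interval(c(30L, 5L, 30L)), c(1L, 3L))
})

test_that("second-N truncation drops everything from the second N on", {
  expect_true(is.na(second_n_cut("ACGTACGT")))
  expect_equal(second_n_cut("ACNGTNAC"), 6L) # kept prefix "ACNGT"
  expect_equal(second_n_cut("NNACGT"), 2L)   # kept prefix "N"
})

test_that("clean_record composes the cascade and enforces the 30-nt minimum", {
  cfg <- clean_config(adapters = adapter33)
  # adapter-free high-quality read is untouched
  read <- random_seq(101, seed = 21)
  out <- clean_record(read, rep(40L, 101), cfg)
  expect_equal(out$status, "kept")
  expect_equal(out$bases, read)
  expect_equal(c(out$start, out$end), c(1L, 101L))
  # 29-nt survivor discarded, 30-nt kept
  expect_equal(clean_record(random_seq(29, seed = 1), rep(40L, 29), cfg)$status,
               "discarded")
  expect_equal(clean_record(random_seq(29, seed = 1), rep(40L, 29),
                            cfg)$reason, "too_short")
  expect_equal(clean_record(random_seq(30, seed = 2), rep(40L, 30), cfg)$status,
               "kept")
  # adapter at 41..73 splits a 101-nt read into 40-nt and 28-nt runs:
  # the longer left segment is kept
  left <- random_seq(40, seed = 31)
  right <- random_seq(28, seed = 32)
  planted <- paste0(left, adapter33, right)
  out2 <- clean_record(planted, rep(40L, 101), cfg)
  expect_equal(out2$status, "kept")
  expect_equal(out2$bases, left)
  expect_equal(c(out2$start, out2$end), c(1L, 40L))
})

test_that("kept reads have clean ends, at most one N, and are substrings of the input", {
  cfg <- clean_config(adapters = adapter33)
  set.seed(42)
  for (i in 1:50) {
    L <- sample(31:120, 1)
    bases <- random_seq(L)
    ch <- strsplit(bases, "")[[1]]
    ch[sample(L, rbinom(1, 3, 0.5))] <- "N"
    bases <- paste(ch, collapse = "")
    quals <- as.integer(sample(5:45, L, replace = TRUE))
    out <- clean_record(bases, quals, cfg)
    if (out$status == "kept") {
      expect_gte(nchar(out$bases), cfg$min_length)
      expect_equal(out$bases, substr(bases, out$start, out$end))
      expect_identical(out$quals, quals[out$start:out$end])
      expect_gte(out$quals[1], cfg$qual_threshold)
      expect_gte(out$quals[length(out$quals)], cfg$qual_threshold)
      expect_lte(lengths(regmatches(out$bases,
                                    gregexpr("N", out$bases)))[[1]], 1L)
      # idempotence: cleaning the kept output changes nothing
      again <- clean_record(out$bases, out$quals, cfg)
      expect_equal(again$status, "kept")
      expect_equal(again$bases, out$bases)
    }
  }
})

test_that("pair cleaning routes orphans and conserves every read", {
  cfg <- clean_config()
  b1 <- vapply(1:6, function(i) random_seq(101, seed = 100 + i), character(1))
  b2 <- vapply(1:6, function(i) random_seq(101, seed = 200 + i), character(1))
  pairs <- make_pairs(b1, b2)
  # degrade read 2 of pairs 2 and 5 to all-Q10, and both mates of pair 3
  for (i in c(2L, 5L)) pairs$quals2[[i]] <- rep(10L, 101)
  pairs$quals1[[3]] <- rep(10L, 101)
  pairs$quals2[[3]] <- rep(10L, 101)
  res <- clean_pairs(pairs, cfg)
  expect_equal(res$stats$pairs_in, 6L)
  expect_equal(res$stats$pairs_kept, 3L)
  expect_equal(res$stats$orphans, 2L)
  expect_equal(res$orphans$read_id, c("p002/1", "p005/1"))
  expect_equal(res$stats$reads_discarded, 4L)
  # conservation: 2 * pairs_in == 2 * pairs_kept + orphans + discarded
  expect_equal(2L * res$stats$pairs_in,
               2L * res$stats$pairs_kept + res$stats$orphans +
                 res$stats$reads_discarded)
})

test_that("config validation rejects bad adapters and rates", {
  expect_error(clean_config(adapters = ""), "empty adapter")
  expect_error(clean_config(adapters = "ACNG"), "\\{A,C,G,T\\}")
  expect_error(clean_config(adapter_error_rate = 0.5))
})
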