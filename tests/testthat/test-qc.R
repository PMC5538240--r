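test_that("metrics summarize quality, composition and adapter content correctly", {
  # all bases Q30 -> mean_q 30, pct_q30 100
  reads <- make_reads(c("ACGT", "GGCC"), q = 30L)
  m <- compute_metrics(reads)
  expect_equal(m$mean_q, 30)
  expect_equal(m$pct_q30, 100)
  # half the bases Q40, half Q20 -> pct_q30 50
  half <- fastq_tbl(c("a", "b"), c("ACGTACGT", "ACGTACGT"),
                    list(rep(40L, 8), rep(20L, 8)))
  expect_equal(compute_metrics(half)$pct_q30, 50)
  expect_equal(compute_metrics(half)$mean_q, 30)
  # adapter embedded in 10 of 100 reads -> adapter_content 10%
  ad <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
  b <- vapply(1:100, function(i) random_seq(101, seed = 600 + i),
              character(1))
  b[1:10] <- paste0(substr(b[1:10], 1, 50), ad, substr(b[1:10], 84, 101))
  ma <- compute_metrics(make_reads(b), adapters = ad)
  expect_equal(ma$adapter_content$pct_reads, 10)
  # per-cycle vectors span the longest read; composition sums to 1
  mixed <- make_reads(c("ACGT", "AANNGGTTCC"))
  mc <- compute_metrics(mixed)
  expect_equal(nrow(mc$per_cycle), 10L)
  comp <- rowSums(as.matrix(
    mc$per_cycle[, c("frac_A", "frac_C", "frac_G", "frac_T", "frac_N")]
  ))
  expect_equal(comp, rep(1, 10))
  expect_equal(mc$read_length$min, 4L)
  expect_equal(mc$read_length$max, 10L)
  expect_error(compute_metrics(make_reads(character())), "empty")
})

test_that("pct_q30 equals 100 * (#bases Q>=30) / (#bases) on ragged reads", {
  reads <- fastq_tbl(
    c("a", "b", "c"),
    c("ACGTA", "ACG", "ACGTACGTAC"),
    list(c(40L, 29L, 30L, 31L, 10L), rep(30L, 3), rep(25L, 10))
  )
  m <- compute_metrics(reads)
  expect_equal(m$pct_q30, 100 * 6 / 18)
})

test_that("mean-Q rule: exactly 30 fails (must exceed), every library type", {
  for (lt in library_types) {
    expect_equal(decide_verdict(qc_metrics(30, 100),
                                library_type = lt)$status, "fail")
    expect_equal(decide_verdict(qc_metrics(30.01, 100),
                                library_type = lt)$status, "pass")
  }
})

test_that("Q30-fraction rule applies to metagenomic and SAG only; 80 exactly passes", {
  expect_equal(decide_verdict(qc_metrics(35, 80),
                              library_type = "metagenomic")$status, "pass")
  expect_equal(decide_verdict(qc_metrics(35, 79.9),
                              library_type = "metagenomic")$status, "fail")
  expect_equal(decide_verdict(qc_metrics(35, 79.9),
                              library_type = "sag")$status, "fail")
  for (lt in c("metatranscriptomic_polyA", "metatranscriptomic_random",
               "amplicon_18S", "amplicon_16S")) {
    expect_equal(decide_verdict(qc_metrics(35, 50),
                                library_type = lt)$status, "pass")
  }
})

test_that("duplicate rule (polyA metatranscriptomic): >20% fails, 20% passes", {
  met <- function(rate) {
    qc_metrics(35, 90, dup = tibble::tibble(paired_rate = rate))
  }
  v21 <- decide_verdict(met(0.21), library_type = "metatranscriptomic_polyA")
  expect_equal(v21$status, "fail")
  expect_true("duplicates" %in% v21$reasons$rule)
  v20 <- decide_verdict(met(0.20), library_type = "metatranscriptomic_polyA")
  expect_false("duplicates" %in% v20$reasons$rule)
  # other library types ignore the duplicate rule
  expect_equal(decide_verdict(met(0.9),
                              library_type = "metagenomic")$status, "pass")
})

test_that("bacteria rule: >5% fails, 5% passes; polyA metatranscriptomic only", {
  tx <- function(b) taxonomy_summary(pct_bacteria = b)
  expect_equal(decide_verdict(qc_metrics(35, 90), tx(5.1),
                              "metatranscriptomic_polyA")$status, "fail")
  expect_equal(decide_verdict(qc_metrics(35, 90), tx(5),
                              "metatranscriptomic_polyA")$status, "pass")
  expect_equal(decide_verdict(qc_metrics(35, 90), tx(50),
                              "metagenomic")$status, "pass")
})

test_that("fungi rule warns above 5% and never fails the dataset", {
  tx <- taxonomy_summary(pct_fungi = 6)
  v <- decide_verdict(qc_metrics(35, 90), tx, "metatranscriptomic_polyA")
  expect_equal(v$status, "warn")
  expect_equal(v$reasons$outcome, "warn")
  v5 <- decide_verdict(qc_metrics(35, 90), taxonomy_summary(pct_fungi = 5),
                       "metatranscriptomic_polyA")
  expect_equal(v5$status, "pass")
})

test_that("a non-marine species at exactly 2% invalidates, marine species never do", {
  sp <- function(pct, marine) {
    taxonomy_summary(tibble::tibble(
      species = "Homo sapiens", pct = pct, expected_marine = marine
    ))
  }
  expect_equal(decide_verdict(qc_metrics(35, 90), sp(2, FALSE),
                              "metagenomic")$status, "fail")
  expect_equal(decide_verdict(qc_metrics(35, 90), sp(1.9, FALSE),
                              "metagenomic")$status, "pass")
  expect_equal(decide_verdict(qc_metrics(35, 90), sp(40, TRUE),
                              "metagenomic")$status, "pass")
  # rule applies to every library type
  expect_equal(decide_verdict(qc_metrics(35, 50), sp(2, FALSE),
                              "amplicon_16S")$status, "fail")
})

test_that("verdicts are monotone: worsening one metric never turns fail into pass", {
  tx <- taxonomy_summary(pct_bacteria = 4)
  base <- decide_verdict(
    qc_metrics(31, 85, dup = tibble::tibble(paired_rate = 0.15)),
    tx, "metatranscriptomic_polyA"
  )
  expect_equal(base$status, "pass")
  worse_cases <- list(
    decide_verdict(qc_metrics(29, 85,
                              dup = tibble::tibble(paired_rate = 0.15)),
                   tx, "metatranscriptomic_polyA"),
    decide_verdict(qc_metrics(31, 85,
                              dup = tibble::tibble(paired_rate = 0.35)),
                   tx, "metatranscriptomic_polyA"),
    decide_verdict(qc_metrics(31, 85,
                              dup = tibble::tibble(paired_rate = 0.15)),
                   taxonomy_summary(pct_bacteria = 9),
                   "metatranscriptomic_polyA")
  )
  for (v in worse_cases) expect_equal(v$status, "fail")
  expect_error(decide_verdict(qc_metrics(35, 90), tx, "exome"), "library type")
})

test_that("reports serialize every metric and parse back", {
  reads <- make_reads(
    vapply(1:20, function(i) random_seq(50, seed = 700 + i), character(1)),
    q = 35
  )
  m <- compute_metrics(reads)
  v <- decide_verdict(m, library_type = "metagenomic")
  p <- withr::local_tempfile(fileext = ".json")
  render_report(m, v, provenance = list(seed = 7L, n_subsample = 20L),
                path = p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$metrics$mean_q, m$mean_q)
  expect_equal(back$metrics$pct_q30, m$pct_q30)
  expect_equal(back$verdict$status, "pass")
  expect_equal(back$provenance$seed, 7L)
  # failing verdicts list rule, observed and threshold
  vf <- decide_verdict(qc_metrics(25, 90), library_type = "metagenomic")
  render_report(qc_metrics(25, 90), vf, path = p)
  back2 <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back2$verdict$reasons$rule, "mean_q")
  expect_equal(back2$verdict$reasons$threshold, 30)
})

test_that("taxonomy TSV round-trips division rollups and species rows", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "species\tpct\texpected_marine",
    "Bacteria\t3.5\tFALSE",
    "Fungi\t1.2\tFALSE",
    "Emiliania huxleyi\t4.0\tTRUE",
    "Homo sapiens\t2.5\tFALSE"
  ), p)
  tx <- read_taxonomy_tsv(p)
  expect_equal(tx$pct_bacteria, 3.5)
  expect_equal(tx$pct_fungi, 1.2)
  expect_equal(nrow(tx$per_species), 2L)
  v <- decide_verdict(qc_metrics(35, 90), tx, "metagenomic")
  expect_equal(v$status, "fail")
  expect_match(v$reasons$rule, "Homo sapiens")
})
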