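#' Run the full preprocessing and validation pipeline
#'
#' Executes the stages in their fixed order: duplicate estimation on the RAW
#' input subsample, then cleaning, then the contaminant screen, then (for
#' metatranscriptomic libraries) the rRNA split, then (for metagenomic
#' libraries) pair merging, and finally the QC metrics, verdict and report.
#' Disabled stages (no reference supplied, wrong library type) are skipped
#' and marked as such in the report.
#'
#' @param in1,in2 Paths of the two mate FASTQ files (plain or gzipped).
#' @param out_dir Output directory for filtered FASTQ files and the report.
#' @param library_type One of [library_types].
#' @param adapters Character vector of adapter sequences (used for trimming
#'   and for adapter-content metrics).
#' @param clean A [clean_config()].
#' @param contaminant_ref Path to a contaminant (control-genome) FASTA, or a
#'   named character vector, or `NULL` to skip the screen.
#' @param rrna_ref rRNA reference FASTA path or sequences, or `NULL`.
#' @param merge A [merge_config()].
#' @param taxonomy A [taxonomy_summary()] (or path to its TSV), or `NULL`.
#' @param thresholds A [qc_thresholds()].
#' @param k,min_fraction k-mer screen parameters.
#' @param n_subsample QC subsample size (default 20000).
#' @param seed Seed for the subsamples.
#' @return A list of class `pipeline_result`: `verdict`, `metrics`,
#'   `raw_metrics`, `report`, per-stage outputs, and `exit_status` (0 for
#'   pass/warn, 2 for a failing verdict).
#' @export
run_pipeline <- function(in1, in2, out_dir,
                         library_type = "metagenomic",
                         adapters = character(),
                         clean = clean_config(adapters = adapters),
                         contaminant_ref = NULL,
                         rrna_ref = NULL,
                         merge = merge_config(),
                         taxonomy = NULL,
                         thresholds = qc_thresholds(),
                         k = 21L, min_fraction = 0.5,
                         n_subsample = 20000L, seed = 1L) {
  if (!library_type %in% library_types) {
    abort(sprintf("unknown library type '%s'", library_type))
  }
  if (is.character(taxonomy)) taxonomy <- read_taxonomy_tsv(taxonomy)
  if (is.null(taxonomy)) taxonomy <- taxonomy_summary()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log.jsonl")
  logcon <- file(log_path, "w")
  on.exit(close(logcon))
  log_stage <- function(stage, ...) {
    writeLines(jsonlite::toJSON(
      c(list(stage = stage), list(...)),
      auto_unbox = TRUE, digits = NA
    ), logcon)
  }

  pairs <- read_fastq_pairs(in1, in2)
  log_stage("input", pairs_in = nrow(pairs), in1 = in1, in2 = in2)

  # duplicate estimation always runs on the raw input
  raw_sample <- subsample_pairs(pairs, n_subsample, seed)
  dup <- estimate_duplicates(raw_sample)
  log_stage("dup_estimate", n_sampled = dup$n_sampled,
            paired_rate = dup$paired_rate, seed = seed)

  cleaned <- clean_pairs(pairs, clean)
  write_fastq(pairs_to_reads(cleaned$pairs, 1L),
              file.path(out_dir, "clean_1.fastq"))
  write_fastq(pairs_to_reads(cleaned$pairs, 2L),
              file.path(out_dir, "clean_2.fastq"))
  write_fastq(cleaned$orphans, file.path(out_dir, "orphans.fastq"))
  log_stage("clean", pairs_kept = cleaned$stats$pairs_kept,
            orphans = cleaned$stats$orphans,
            reads_discarded = cleaned$stats$reads_discarded)
  current <- cleaned$pairs

  n_contam_removed <- NA_integer_
  if (!is.null(contaminant_ref)) {
    idx <- build_kmer_index(contaminant_ref, k)
    scr <- remove_contaminant_pairs(current, idx, min_fraction)
    current <- scr$kept
    n_contam_removed <- scr$n_removed
    log_stage("contaminant_screen", removed = scr$n_removed,
              kept = nrow(current), k = k, min_fraction = min_fraction)
  } else {
    log_stage("contaminant_screen", skipped = TRUE)
  }

  pct_rrna <- NULL
  if (startsWith(library_type, "metatranscriptomic") && !is.null(rrna_ref)) {
    idx <- build_kmer_index(rrna_ref, k)
    sp <- split_rrna_pairs(current, idx, min_fraction)
    write_fastq(pairs_to_reads(sp$ribo, 1L),
                file.path(out_dir, "ribo_clean_1.fastq"))
    write_fastq(pairs_to_reads(sp$ribo, 2L),
                file.path(out_dir, "ribo_clean_2.fastq"))
    write_fastq(pairs_to_reads(sp$noribo, 1L),
                file.path(out_dir, "noribo_clean_1.fastq"))
    write_fastq(pairs_to_reads(sp$noribo, 2L),
                file.path(out_dir, "noribo_clean_2.fastq"))
    pct_rrna <- if (nrow(current)) 100 * nrow(sp$ribo) / nrow(current) else 0
    log_stage("rrna_split", ribo = nrow(sp$ribo), noribo = nrow(sp$noribo),
              pct_rrna = pct_rrna)
    current <- sp$noribo
  } else {
    log_stage("rrna_split", skipped = TRUE)
  }

  merge_stats <- NULL
  if (library_type == "metagenomic") {
    mg <- merge_pairs(current, merge)
    write_fastq(mg$merged[, c("read_id", "bases", "quals")],
                file.path(out_dir, "merged.fastq"))
    write_fastq(pairs_to_reads(mg$unmerged, 1L),
                file.path(out_dir, "unmerged_1.fastq"))
    write_fastq(pairs_to_reads(mg$unmerged, 2L),
                file.path(out_dir, "unmerged_2.fastq"))
    merge_stats <- mg$stats
    log_stage("merge", n_merged = mg$stats$n_merged,
              merged_fraction = mg$stats$merged_fraction,
              merged_len_median = mg$stats$merged_len_median)
  } else {
    log_stage("merge", skipped = TRUE)
  }

  # verdict metrics come from the cleaned reads (the data that proceeds);
  # raw-read metrics are reported alongside
  clean_sample <- subsample_pairs(current, n_subsample, seed)
  clean_reads_tbl <- dplyr::bind_rows(
    pairs_to_reads(clean_sample, 1L), pairs_to_reads(clean_sample, 2L)
  )
  raw_reads_tbl <- dplyr::bind_rows(
    pairs_to_reads(raw_sample, 1L), pairs_to_reads(raw_sample, 2L)
  )
  metrics <- compute_metrics(clean_reads_tbl, adapters = adapters,
                             dup = dup, pct_rrna = pct_rrna,
                             merge = merge_stats)
  raw_metrics <- compute_metrics(raw_reads_tbl, adapters = adapters)
  verdict <- decide_verdict(metrics, taxonomy, library_type, thresholds)
  log_stage("verdict", status = verdict$status,
            n_reasons = nrow(verdict$reasons))

  provenance <- list(
    in1 = in1, in2 = in2, library_type = library_type,
    n_subsample = n_subsample, seed = seed, k = k,
    min_fraction = min_fraction,
    contaminant_screen = !is.null(contaminant_ref),
    rrna_split = startsWith(library_type, "metatranscriptomic") &&
      !is.null(rrna_ref),
    clean = unclass(clean), merge = unclass(merge),
    thresholds = unclass(thresholds),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  report <- render_report(metrics, verdict, provenance,
                          path = file.path(out_dir, "qc_report.json"))

  structure(
    list(
      verdict = verdict, metrics = metrics, raw_metrics = raw_metrics,
      dup = dup, clean_stats = cleaned$stats,
      n_contaminant_removed = n_contam_removed,
      pct_rrna = pct_rrna, merge_stats = merge_stats,
      report = report, out_dir = out_dir,
      exit_status = if (verdict$status == "fail") 2L else 0L
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> verdict: %s (exit %d)\n",
              toupper(x$verdict$status), x$exit_status))
  print(x$clean_stats)
  if (!is.null(x$merge_stats)) print(x$merge_stats)
  invisible(x)
}
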