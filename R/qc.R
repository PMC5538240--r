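#' Library types recognized by the QC gate
#'
#' Which validation rules apply depends on the library construction:
#' the Q30-fraction rule is waived for metatranscriptomic and amplicon
#' libraries (their construction depresses Q scores), and the duplicate,
#' bacterial-contamination and fungi rules apply only to poly(A)-selected
#' metatranscriptomes from protist/metazoan-enriched filters.
#'
#' @export
library_types <- c(
  "metagenomic", "metatranscriptomic_polyA", "metatranscriptomic_random",
  "amplicon_18S", "amplicon_16S", "sag"
)

#' Dataset-acceptance thresholds
#'
#' Defaults are the published values: mean Q must exceed 30; at least 80% of
#' bases at Q >= 30 (metagenomic and SAG libraries only); more than 20%
#' paired duplicates fails; more than 5% bacterial reads fails (poly(A)
#' metatranscriptomes); more than 5% Fungi triggers inspection (a warning);
#' 2% or more of reads assigned to any single species not expected in the
#' ocean invalidates the dataset.
#'
#' @param min_mean_q Mean Q that must be exceeded (default 30).
#' @param min_pct_q30 Minimum % of bases with Q >= 30 (default 80).
#' @param max_pct_duplicates Paired duplicate % above which the dataset fails
#'   (default 20; exactly 20 passes).
#' @param max_pct_bacteria Bacterial read % above which the dataset fails
#'   (default 5; exactly 5 passes).
#' @param fungi_warn_pct Fungi % above which the dataset is flagged for
#'   inspection (default 5).
#' @param max_pct_contaminant_species Per-species % of a non-marine species
#'   at or above which the dataset fails (default 2).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_mean_q = 30, min_pct_q30 = 80,
                          max_pct_duplicates = 20, max_pct_bacteria = 5,
                          fungi_warn_pct = 5,
                          max_pct_contaminant_species = 2) {
  pcts <- c(min_pct_q30, max_pct_duplicates, max_pct_bacteria,
            fungi_warn_pct, max_pct_contaminant_species)
  stopifnot(all(pcts >= 0 & pcts <= 100), min_mean_q >= 0)
  structure(
    list(
      min_mean_q = min_mean_q,
      min_pct_q30 = min_pct_q30,
      max_pct_duplicates = max_pct_duplicates,
      max_pct_bacteria = max_pct_bacteria,
      fungi_warn_pct = fungi_warn_pct,
      max_pct_contaminant_species = max_pct_contaminant_species
    ),
    class = "qc_thresholds"
  )
}

#' Taxonomy summary consumed by the QC gate
#'
#' Taxonomic assignment of the 20,000-read subsample (BLAST against nt plus
#' a metagenome classifier) happens upstream; the gate consumes its rollup:
#' per-species percentages with a flag for species expected in the ocean,
#' plus division-level percentages for Bacteria and Fungi.
#'
#' @param per_species A tibble/data frame with columns `species` (character),
#'   `pct` (percent of subsampled reads) and `expected_marine` (logical), or
#'   `NULL` for none.
#' @param pct_bacteria,pct_fungi,pct_no_hit Division-level percentages.
#' @return A `taxonomy_summary` list.
#' @export
taxonomy_summary <- function(per_species = NULL, pct_bacteria = 0,
                             pct_fungi = 0, pct_no_hit = NA_real_) {
  if (is.null(per_species)) {
    per_species <- tibble(species = character(), pct = numeric(),
                          expected_marine = logical())
  }
  per_species <- as_tibble(per_species)
  stopifnot(
    all(c("species", "pct", "expected_marine") %in% names(per_species)),
    all(per_species$pct >= 0 & per_species$pct <= 100),
    pct_bacteria >= 0, pct_bacteria <= 100,
    pct_fungi >= 0, pct_fungi <= 100
  )
  structure(
    list(per_species = per_species, pct_bacteria = pct_bacteria,
         pct_fungi = pct_fungi, pct_no_hit = pct_no_hit),
    class = "taxonomy_summary"
  )
}

#' Read a taxonomy summary from TSV
#'
#' Expects columns `species`, `pct`, `expected_marine`; rows with species
#' `"Bacteria"` or `"Fungi"` (case-insensitive) are treated as division
#' rollups rather than species.
#'
#' @param path TSV file path.
#' @return A [taxonomy_summary()].
#' @export
read_taxonomy_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "pct", "expected_marine") %in% names(tab)))
  tab$expected_marine <- as.logical(tab$expected_marine)
  div <- tolower(tab$species)
  bac <- tab$pct[div == "bacteria"]
  fun <- tab$pct[div == "fungi"]
  taxonomy_summary(
    per_species = tab[!(div %in% c("bacteria", "fungi")), , drop = FALSE],
    pct_bacteria = if (length(bac)) bac[1] else 0,
    pct_fungi = if (length(fun)) fun[1] else 0
  )
}

#' Compute per-dataset quality metrics from a read subsample
#'
#' Read size, quality values, N positions and base composition per cycle, and
#' adapter content (percentage of reads containing each known adapter, via
#' the cleaner's matcher). `pct_q30` is 100 times the fraction of all bases
#' with Q >= 30.
#'
#' @param reads A non-empty reads tibble (normally a 20,000-read subsample).
#' @param adapters Character vector of adapter sequences to detect.
#' @param mean_q,pct_q30,dup,pct_rrna,merge Override or attach components
#'   when building metric sets directly (e.g. for threshold sweeps): `dup` a
#'   [estimate_duplicates()] row, `pct_rrna` a percentage, `merge` a
#'   `merge_stats` object.
#' @return A `qc_metrics` list: `n_reads`, `mean_q`, `pct_q30`, `per_cycle`
#'   (tibble: cycle, mean_q, frac_A..frac_N), `adapter_content` (tibble),
#'   `read_length` (min/median/mean/max), plus any attached `dup`,
#'   `pct_rrna`, `merge`.
#' @export
compute_metrics <- function(reads, adapters = character(),
                            dup = NULL, pct_rrna = NULL, merge = NULL) {
  validate_reads(reads)
  if (!nrow(reads)) abort("cannot compute metrics on an empty subsample")
  lens <- nchar(reads$bases)
  maxlen <- max(lens)
  qmat <- matrix(NA_integer_, nrow(reads), maxlen)
  bmat <- matrix(NA_character_, nrow(reads), maxlen)
  for (i in seq_len(nrow(reads))) {
    qmat[i, seq_len(lens[i])] <- reads$quals[[i]]
    bmat[i, seq_len(lens[i])] <- strsplit(reads$bases[i], "")[[1]]
  }
  allq <- unlist(reads$quals)
  per_cycle <- tibble(
    cycle = seq_len(maxlen),
    mean_q = colMeans(qmat, na.rm = TRUE),
    coverage = colSums(!is.na(qmat))
  )
  for (b in c("A", "C", "G", "T", "N")) {
    per_cycle[[paste0("frac_", b)]] <-
      colSums(bmat == b, na.rm = TRUE) / per_cycle$coverage
  }
  adapter_content <- if (length(adapters)) {
    cfg <- clean_config(adapters = adapters)
    pct <- vapply(adapters, function(ad) {
      one <- clean_config(adapters = ad,
                          adapter_min_match = cfg$adapter_min_match,
                          adapter_error_rate = cfg$adapter_error_rate)
      hit <- vapply(reads$bases,
                    function(b) nrow(locate_adapter_hits(b, one)) > 0,
                    logical(1))
      100 * mean(hit)
    }, numeric(1))
    tibble(adapter = adapters, pct_reads = unname(pct))
  } else {
    tibble(adapter = character(), pct_reads = numeric())
  }
  structure(
    list(
      n_reads = nrow(reads),
      mean_q = mean(allq),
      pct_q30 = 100 * mean(allq >= 30),
      per_cycle = per_cycle,
      adapter_content = adapter_content,
      read_length = list(min = min(lens), median = median(lens),
                         mean = mean(lens), max = max(lens)),
      dup = dup,
      pct_rrna = pct_rrna,
      merge = merge
    ),
    class = "qc_metrics"
  )
}

#' Build a metric set directly from summary values
#'
#' For rule sweeps and for datasets whose per-read detail is unavailable:
#' constructs a `qc_metrics` object from the summary quantities the verdict
#' rules consume.
#'
#' @param mean_q Mean Phred score.
#' @param pct_q30 Percent of bases with Q >= 30.
#' @param dup Optional [estimate_duplicates()] row (or a one-row data frame
#'   with a `paired_rate` column).
#' @param n_reads Nominal subsample size.
#' @param pct_rrna,merge Optional attachments as in [compute_metrics()].
#' @return A `qc_metrics` list.
#' @export
qc_metrics <- function(mean_q, pct_q30, dup = NULL, n_reads = NA_integer_,
                       pct_rrna = NULL, merge = NULL) {
  structure(
    list(
      n_reads = n_reads, mean_q = mean_q, pct_q30 = pct_q30,
      per_cycle = NULL, adapter_content = NULL, read_length = NULL,
      dup = dup, pct_rrna = pct_rrna, merge = merge
    ),
    class = "qc_metrics"
  )
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat(sprintf(
    "<qc_metrics> n_reads = %s, mean Q = %.2f, %%bases Q>=30 = %.1f\n",
    format(x$n_reads), x$mean_q, x$pct_q30
  ))
  if (!is.null(x$dup)) {
    cat(sprintf("  paired duplicate rate: %.1f%%\n", 100 * x$dup$paired_rate))
  }
  if (!is.null(x$pct_rrna)) cat(sprintf("  rRNA reads: %.1f%%\n", x$pct_rrna))
  invisible(x)
}

#' Apply the dataset-acceptance rules
#'
#' Evaluates the validation rules with their published strict/non-strict
#' senses:
#' * `mean_q` (all library types): fails unless mean Q strictly exceeds 30.
#' * `pct_q30` (metagenomic and SAG only): fails when the percentage of
#'   bases with Q >= 30 is below 80; exactly 80 passes.
#' * `contaminant_species` (all types): any species not expected in the
#'   ocean at 2% or more of reads invalidates the dataset (exactly 2% fails).
#' * `duplicates` (poly(A) metatranscriptomic only): more than 20% paired
#'   duplicates fails; exactly 20% passes.
#' * `bacteria` (poly(A) metatranscriptomic only): more than 5% bacterial
#'   reads fails; exactly 5% passes.
#' * `fungi` (poly(A) metatranscriptomic only): more than 5% Fungi reads
#'   warns (the dataset is inspected, never auto-failed).
#'
#' @param metrics A `qc_metrics` object ([compute_metrics()] or
#'   [qc_metrics()]); the duplicate rule needs `metrics$dup`.
#' @param taxonomy A [taxonomy_summary()].
#' @param library_type One of [library_types].
#' @param thresholds A [qc_thresholds()].
#' @return A `qc_verdict`: `status` ("pass"/"warn"/"fail") and `reasons`, a
#'   tibble of triggered rules (rule, observed, threshold, outcome).
#' @export
decide_verdict <- function(metrics, taxonomy = taxonomy_summary(),
                           library_type = "metagenomic",
                           thresholds = qc_thresholds()) {
  if (!library_type %in% library_types) {
    abort(sprintf(
      "unknown library type '%s' (expected one of: %s)",
      library_type, paste(library_types, collapse = ", ")
    ))
  }
  th <- thresholds
  reasons <- tibble(rule = character(), observed = numeric(),
                    threshold = numeric(), outcome = character())
  add <- function(rule, observed, threshold, outcome) {
    dplyr::bind_rows(reasons, tibble(
      rule = rule, observed = observed, threshold = threshold,
      outcome = outcome
    ))
  }
  if (!is.na(metrics$mean_q) && metrics$mean_q <= th$min_mean_q) {
    reasons <- add("mean_q", metrics$mean_q, th$min_mean_q, "fail")
  }
  if (library_type %in% c("metagenomic", "sag") &&
      !is.na(metrics$pct_q30) && metrics$pct_q30 < th$min_pct_q30) {
    reasons <- add("pct_q30", metrics$pct_q30, th$min_pct_q30, "fail")
  }
  sp <- taxonomy$per_species
  bad_sp <- which(!sp$expected_marine &
                    sp$pct >= th$max_pct_contaminant_species)
  for (i in bad_sp) {
    reasons <- add(paste0("contaminant_species:", sp$species[i]),
                   sp$pct[i], th$max_pct_contaminant_species, "fail")
  }
  if (library_type == "metatranscriptomic_polyA") {
    if (!is.null(metrics$dup)) {
      pct_dup <- 100 * metrics$dup$paired_rate
      if (pct_dup > th$max_pct_duplicates) {
        reasons <- add("duplicates", pct_dup, th$max_pct_duplicates, "fail")
      }
    }
    if (taxonomy$pct_bacteria > th$max_pct_bacteria) {
      reasons <- add("bacteria", taxonomy$pct_bacteria,
                     th$max_pct_bacteria, "fail")
    }
    if (taxonomy$pct_fungi > th$fungi_warn_pct) {
      reasons <- add("fungi", taxonomy$pct_fungi, th$fungi_warn_pct, "warn")
    }
  }
  status <- if (any(reasons$outcome == "fail")) {
    "fail"
  } else if (any(reasons$outcome == "warn")) {
    "warn"
  } else {
    "pass"
  }
  structure(list(status = status, reasons = reasons), class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("<qc_verdict> %s\n", toupper(x$status)))
  if (nrow(x$reasons)) {
    for (i in seq_len(nrow(x$reasons))) {
      cat(sprintf(
        "  [%s] %s: observed %.3g vs threshold %.3g\n",
        x$reasons$outcome[i], x$reasons$rule[i],
        x$reasons$observed[i], x$reasons$threshold[i]
      ))
    }
  }
  invisible(x)
}

#' Render a machine-readable QC report
#'
#' Serializes metrics, the verdict and run provenance (parameters, seeds,
#' package version) to a JSON-ready list, optionally written to disk.
#'
#' @param metrics A `qc_metrics` object.
#' @param verdict A `qc_verdict`.
#' @param provenance Named list of run parameters and seeds.
#' @param path Optional output path for the JSON file.
#' @return The report list, invisibly when `path` is given.
#' @export
render_report <- function(metrics, verdict, provenance = list(),
                          path = NULL) {
  report <- list(
    tool = list(
      package = "oceanqc",
      version = as.character(utils::packageVersion("oceanqc"))
    ),
    provenance = provenance,
    metrics = list(
      n_reads = metrics$n_reads,
      mean_q = metrics$mean_q,
      pct_q30 = metrics$pct_q30,
      read_length = metrics$read_length,
      per_cycle = metrics$per_cycle,
      adapter_content = metrics$adapter_content,
      duplicates = if (!is.null(metrics$dup)) as.list(metrics$dup) else NULL,
      pct_rrna = metrics$pct_rrna,
      merge = if (!is.null(metrics$merge)) {
        m <- unclass(metrics$merge)
        m$length_histogram <- as.data.frame(m$length_histogram)
        m
      } else {
        NULL
      }
    ),
    verdict = list(status = verdict$status,
                   reasons = as.data.frame(verdict$reasons))
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(report))
  }
  report
}
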