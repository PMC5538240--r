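#' Tidiers and plots for oceanqc result objects
#'
#' `tidy()` returns the per-element detail of a result as a tibble and
#' `glance()` a one-row summary, in the broom convention. `autoplot()`
#' methods draw the standard diagnostic charts.
#'
#' @param x A `qc_metrics`, `qc_verdict`, `merge_stats` or `dup_estimate`
#'   object.
#' @param object Same, for `autoplot()`.
#' @param ... Unused.
#' @name oceanqc-tidiers
NULL

#' @rdname oceanqc-tidiers
#' @export
tidy.qc_metrics <- function(x, ...) {
  if (is.null(x$per_cycle)) {
    return(tibble(cycle = integer(), mean_q = numeric()))
  }
  x$per_cycle
}

#' @rdname oceanqc-tidiers
#' @export
glance.qc_metrics <- function(x, ...) {
  tibble(
    n_reads = x$n_reads,
    mean_q = x$mean_q,
    pct_q30 = x$pct_q30,
    paired_dup_rate = if (!is.null(x$dup)) x$dup$paired_rate else NA_real_,
    pct_rrna = if (!is.null(x$pct_rrna)) x$pct_rrna else NA_real_,
    merged_fraction = if (!is.null(x$merge)) x$merge$merged_fraction
                      else NA_real_
  )
}

#' @rdname oceanqc-tidiers
#' @export
tidy.qc_verdict <- function(x, ...) {
  x$reasons
}

#' @rdname oceanqc-tidiers
#' @export
glance.qc_verdict <- function(x, ...) {
  tibble(
    status = x$status,
    n_fail = sum(x$reasons$outcome == "fail"),
    n_warn = sum(x$reasons$outcome == "warn")
  )
}

#' @rdname oceanqc-tidiers
#' @export
tidy.merge_stats <- function(x, ...) {
  x$length_histogram
}

#' @rdname oceanqc-tidiers
#' @export
glance.merge_stats <- function(x, ...) {
  tibble(
    n_pairs = x$n_pairs,
    n_merged = x$n_merged,
    merged_fraction = x$merged_fraction,
    merged_len_mean = x$merged_len_mean,
    merged_len_median = x$merged_len_median,
    insert_size_estimate = x$insert_size_estimate
  )
}

#' @rdname oceanqc-tidiers
#' @export
glance.dup_estimate <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname oceanqc-tidiers
#' @export
autoplot.qc_metrics <- function(object, ...) {
  if (is.null(object$per_cycle)) {
    abort("these metrics carry no per-cycle detail to plot")
  }
  ggplot2::ggplot(object$per_cycle,
                  ggplot2::aes(x = .data$cycle, y = .data$mean_q)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = 30, linetype = "dashed",
                        color = "grey40") +
    ggplot2::labs(x = "Cycle", y = "Mean Phred quality",
                  title = "Per-cycle mean base quality") +
    ggplot2::theme_minimal()
}

#' @rdname oceanqc-tidiers
#' @export
autoplot.merge_stats <- function(object, ...) {
  ggplot2::ggplot(object$length_histogram,
                  ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Merged read length (bp)", y = "Reads",
                  title = "Merged read length distribution") +
    ggplot2::theme_minimal()
}

#' Per-cycle base composition plot
#'
#' @param metrics A [compute_metrics()] result with per-cycle detail.
#' @return A ggplot object.
#' @export
plot_base_composition <- function(metrics) {
  stopifnot(inherits(metrics, "qc_metrics"), !is.null(metrics$per_cycle))
  long <- tidyr::pivot_longer(
    metrics$per_cycle,
    dplyr::starts_with("frac_"),
    names_to = "base", names_prefix = "frac_", values_to = "fraction"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$fraction,
                                     color = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cycle", y = "Base fraction",
                  title = "Per-cycle base composition") +
    ggplot2::theme_minimal()
}
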