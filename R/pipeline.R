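#' Run the full CNV analysis pipeline on one batch
#'
#' Orchestrates the whole analysis: load the batch, run the iterative
#' whisker-QC loop (normalization, X correction, sample removal,
#' re-normalization), call CNVs on the final matrix, annotate recurrent and
#' extreme-GC calls, render the review plots, and write the text outputs plus
#' a machine-readable JSON manifest echoing every configuration value in
#' effect.
#'
#' When fewer than `min_pass_samples` samples survive QC the batch is failed:
#' the QC summary and manifest are still written, but no call table or sample
#' plots are produced and the returned status is `"batch_failed"`.
#'
#' @param input_dir Directory of GATK DepthOfCoverage interval summary files.
#' @param interval_list Interval list path or tibble.
#' @param out_dir Output directory.
#' @param config A [cnv_config()].
#' @param gc_table Optional tibble (`label`, `gc`) or path to a two-column TSV.
#' @param exclusion_list Optional character vector of interval labels, or path
#'   to a one-label-per-line file, for exons known to fail NGS analysis.
#' @param plots Render plots (disable for speed in programmatic use).
#' @return An object of class `cnv_run`: list with `status` (`"ok"` or
#'   `"batch_failed"`), `qc` (the [iterate_qc()] result), `calls`, `manifest`
#'   and `paths`.
#' @export
run_cnv_pipeline <- function(input_dir, interval_list, out_dir,
                             config = cnv_config(), gc_table = NULL,
                             exclusion_list = NULL, plots = TRUE) {
  if (is.character(interval_list) && length(interval_list) == 1L) {
    interval_list <- parse_interval_list(interval_list, config$x_chrom_name)
  }
  if (is.character(gc_table) && length(gc_table) == 1L) {
    gc_table <- readr::read_tsv(gc_table, col_types = "cd", progress = FALSE)
  }
  if (is.character(exclusion_list) && length(exclusion_list) == 1L && file.exists(exclusion_list)) {
    exclusion_list <- readLines(exclusion_list, warn = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cov <- load_batch(input_dir, interval_list)
  qc <- iterate_qc(cov, config, out_dir = out_dir)
  paths <- character(0)

  if (qc$batch_failed) {
    paths["qc_summary"] <- file.path(out_dir, "panelcnv_qc_summary.tsv")
    readr::write_tsv(qc$qc, paths[["qc_summary"]], progress = FALSE)
    manifest <- build_manifest(config, qc, calls = NULL, paths, status = "batch_failed")
    paths["manifest"] <- write_manifest(manifest, out_dir)
    return(structure(list(status = "batch_failed", qc = qc, calls = NULL,
                          manifest = manifest, paths = paths),
                     class = "cnv_run"))
  }

  calls <- segment_calls(qc$log2, qc$summaries, config, excluded_labels = exclusion_list)
  calls <- cohort_annotate(calls, n_cases = length(sample_names(qc$log2)), config)
  calls <- flag_extreme_gc(calls, interval_meta(qc$log2), gc_table, config)
  written_calls <- if (config$drop_recurrent) calls[!calls$recurrent, , drop = FALSE] else calls

  if (plots) {
    plot_dir <- file.path(out_dir, "plots")
    dir.create(plot_dir, showWarnings = FALSE)
    for (s in sample_names(qc$log2)) {
      pd <- plot_sample_data(qc$log2, written_calls, qc$summaries, s, config)
      write_plot_sidecar(pd, file.path(plot_dir, paste0(s, "_genome")))
      save_plot(plot_sample(qc$log2, written_calls, qc$summaries, s, config),
                file.path(plot_dir, paste0(s, "_genome")))
      for (chr in unique(written_calls$chrom[written_calls$sample == s])) {
        save_plot(plot_sample(qc$log2, written_calls, qc$summaries, s, config, scope = chr),
                  file.path(plot_dir, paste0(s, "_", chr)), width = 6)
      }
    }
    save_plot(plot_x_boxplots(qc$log2_pre_x, qc$log2, config),
              file.path(plot_dir, "x_normalization_boxplots"), height = 6)
    save_plot(autoplot(qc), file.path(plot_dir, "batch_boxplots"))
  }

  paths <- c(paths, write_outputs(qc$log2, written_calls, qc$qc, out_dir))
  manifest <- build_manifest(config, qc, written_calls, paths, status = "ok")
  paths["manifest"] <- write_manifest(manifest, out_dir)

  structure(list(status = "ok", qc = qc, calls = calls,
                 manifest = manifest, paths = paths),
            class = "cnv_run")
}

build_manifest <- function(config, qc, calls, paths, status) {
  list(
    tool = "panelcnv",
    version = as.character(utils::packageVersion("panelcnv")),
    status = status,
    config = unclass(config),
    n_iterations = qc$n_iterations,
    samples_passed = sum(qc$verdicts$passed),
    samples_failed = sum(!qc$verdicts$passed),
    n_calls = if (is.null(calls)) 0L else nrow(calls),
    files = as.list(paths)
  )
}

write_manifest <- function(manifest, out_dir) {
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  p
}

#' @export
print.cnv_run <- function(x, ...) {
  cat(sprintf("<cnv_run> status: %s; %d iteration(s); %d call(s)\n",
              x$status, x$qc$n_iterations,
              if (is.null(x$calls)) 0L else nrow(x$calls)))
  invisible(x)
}

#' @rdname run_cnv_pipeline
#' @param x A `cnv_run` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cnv_run <- function(x, ...) {
  if (is.null(x$calls)) {
    return(format_call_table(NULL)[0, ])
  }
  x$calls
}

#' @rdname run_cnv_pipeline
#' @exportS3Method generics::glance
glance.cnv_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble(status = x$status,
           n_calls = if (is.null(x$calls)) 0L else nrow(x$calls)),
    glance(x$qc)
  )
}

#' Merge call tables from multiple runs and recompute cohort recurrence
#'
#' A single run computes recurrence within its own cases; at laboratory scale
#' a cohort spans many batches. This merges call tables (as written by
#' [write_outputs()] or returned by [run_cnv_pipeline()]) and re-annotates
#' recurrence against the pooled case count.
#'
#' @param calls_list List of call tibbles (or paths to call table TSVs).
#' @param n_cases Total cases in the pooled cohort; defaults to the number of
#'   distinct samples seen.
#' @param config A [cnv_config()].
#' @return The pooled, re-annotated call tibble.
#' @export
merge_cohort_calls <- function(calls_list, n_cases = NULL, config = cnv_config()) {
  calls <- purrr::map_dfr(calls_list, function(x) {
    if (is.character(x)) {
      x <- readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
      # written tables carry span, not ranks; reconstruct minimal key fields
      if (!"first_rank" %in% names(x)) {
        coords <- parse_targets(x$span, context = "call table")
        x$first_rank <- coords$start
        x$last_rank <- coords$end
      }
    }
    x
  })
  n_cases <- n_cases %||% dplyr::n_distinct(calls$sample)
  cohort_annotate(calls, n_cases, config)
}
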