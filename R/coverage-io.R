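#' Parse one GATK DepthOfCoverage interval summary file
#'
#' Reads a `sample_interval_summary` table (comma- or tab-delimited; the
#' delimiter is auto-detected) and extracts the total coverage column, whose
#' header is `{sample name}_total_cvg`. Rows are matched to `interval_list` by
#' target coordinates `(chrom, start, end)` and reordered to the list's rank
#' order, so shuffled files load identically. The sample name is taken from
#' the column header, not the filename.
#'
#' @param path Path to the interval summary file.
#' @param interval_list Interval tibble from [parse_interval_list()].
#' @return A list with `sample` (name string) and `totals` (numeric vector
#'   aligned to `interval_list` order).
#' @export
parse_interval_summary <- function(path, interval_list) {
  if (!file.exists(path)) {
    abort(paste0("interval summary not found: ", path), class = "panelcnv_input_error")
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- tryCatch(
    readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE, show_col_types = FALSE),
    error = function(e) {
      abort(paste0("cannot read interval summary ", path, ": ", conditionMessage(e)),
            class = "panelcnv_format_error")
    }
  )
  cvg_cols <- grep("_total_cvg$", names(tab), value = TRUE)
  if (length(cvg_cols) != 1L) {
    abort(
      sprintf("%s: expected exactly one '*_total_cvg' column, found %d", path, length(cvg_cols)),
      class = "panelcnv_format_error"
    )
  }
  target_col <- if ("Target" %in% names(tab)) "Target" else names(tab)[1L]
  sample <- sub("_total_cvg$", "", cvg_cols)

  coords <- parse_targets(tab[[target_col]], context = path)
  keys <- target_key(coords$chrom, coords$start, coords$end)
  want <- target_key(interval_list$chrom, interval_list$start, interval_list$end)
  if (anyDuplicated(keys)) {
    abort(sprintf("%s: duplicate target %s", path, keys[duplicated(keys)][1L]),
          class = "panelcnv_alignment_error")
  }
  missing <- setdiff(want, keys)
  extra <- setdiff(keys, want)
  if (length(missing) > 0L || length(extra) > 0L) {
    first <- c(missing, extra)[1L]
    abort(
      sprintf("%s: targets do not match the interval list (first discrepancy: %s)", path, first),
      class = "panelcnv_alignment_error"
    )
  }
  idx <- match(want, keys)
  raw <- tab[[cvg_cols]][idx]
  totals <- suppressWarnings(as.numeric(raw))
  if (anyNA(totals)) {
    row <- which(is.na(totals))[1L]
    abort(
      sprintf("%s: non-numeric coverage '%s' for target %s (row %d)", path, raw[row], want[row], idx[row]),
      class = "panelcnv_parse_error"
    )
  }
  list(sample = sample, totals = totals)
}

#' Load a capture batch from a directory of interval summary files
#'
#' Reads every regular file in `input_dir` as a GATK DepthOfCoverage interval
#' summary and assembles the batch coverage table: one row per target interval
#' (in interval-list order) and one numeric column per sample, ordered
#' lexicographically by sample name. Filenames are provenance only; sample
#' identity comes from the `_total_cvg` column header.
#'
#' @param input_dir Directory containing the per-sample files.
#' @param interval_list Interval tibble from [parse_interval_list()], or a path
#'   to an interval list file.
#' @return A coverage tibble: interval metadata columns plus one total-coverage
#'   column per sample.
#' @export
load_batch <- function(input_dir, interval_list) {
  if (is.character(interval_list) && length(interval_list) == 1L) {
    interval_list <- parse_interval_list(interval_list)
  }
  check_intervals(interval_list)
  files <- list.files(input_dir, full.names = TRUE)
  files <- files[file.exists(files) & !dir.exists(files)]
  if (length(files) == 0L) {
    abort(paste0("no interval summary files in ", input_dir), class = "panelcnv_input_error")
  }
  parsed <- purrr::map(sort(files), parse_interval_summary, interval_list = interval_list)
  samples <- purrr::map_chr(parsed, "sample")
  if (anyDuplicated(samples)) {
    abort(
      sprintf("duplicate sample name across files: %s", samples[duplicated(samples)][1L]),
      class = "panelcnv_duplicate_error"
    )
  }
  ord <- order(samples)
  cov <- interval_list
  for (k in ord) {
    totals <- parsed[[k]]$totals
    if (any(totals < 0)) {
      abort(sprintf("negative coverage for sample %s", samples[k]),
            class = "panelcnv_validation_error")
    }
    cov[[samples[k]]] <- totals
  }
  cov
}

#' Write the analysis output tables
#'
#' Writes the three tab-delimited text outputs of a run into `out_dir`: the
#' log2 ratio matrix (intervals as rows in genome order, samples as columns),
#' the CNV call table (one row per call, identifiers shared with the plot
#' annotations), and the per-sample QC summary (five-number summary, pass/fail
#' verdict and predicted sex). Re-running the writer on identical inputs
#' produces byte-identical files.
#'
#' @param log2_tbl Log2 ratio tibble from [normalize_coverage()] /
#'   [iterate_qc()].
#' @param calls Call tibble from [segment_calls()] (possibly annotated); may
#'   have zero rows.
#' @param qc QC tibble joining five-number summaries, verdicts and predicted
#'   sex (as produced by [iterate_qc()]`$qc`), or `NULL` to skip.
#' @param out_dir Output directory; created if needed.
#' @param prefix Filename prefix, default `"panelcnv"`.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_outputs <- function(log2_tbl, calls, qc, out_dir, prefix = "panelcnv") {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create output directory ", out_dir), class = "panelcnv_io_error")
  }
  paths <- character(0)

  mat <- dplyr::mutate(log2_tbl,
    Target = target_key(.data$chrom, .data$start, .data$end), .before = 1L
  )
  p <- file.path(out_dir, paste0(prefix, "_log2_matrix.tsv"))
  readr::write_tsv(mat, p, progress = FALSE)
  paths["log2_matrix"] <- p

  if (!is.null(calls)) {
    p <- file.path(out_dir, paste0(prefix, "_cnv_calls.tsv"))
    readr::write_tsv(format_call_table(calls), p, progress = FALSE)
    paths["cnv_calls"] <- p
  }
  if (!is.null(qc)) {
    p <- file.path(out_dir, paste0(prefix, "_qc_summary.tsv"))
    readr::write_tsv(qc, p, progress = FALSE)
    paths["qc_summary"] <- p
  }
  invisible(paths)
}

# call table in the documented output column order
format_call_table <- function(calls) {
  out <- tibble(
    id = integer(0), sample = character(0), chrom = character(0),
    start_label = character(0), end_label = character(0), span = character(0),
    type = character(0), n_intervals = integer(0), median_log2 = numeric(0),
    inferred_cn = numeric(0), recurrent = logical(0), gc_flag = logical(0)
  )
  if (is.null(calls) || nrow(calls) == 0L) {
    return(out)
  }
  calls <- dplyr::arrange(calls, .data$sample, .data$id)
  tibble(
    id = calls$id,
    sample = calls$sample,
    chrom = calls$chrom,
    start_label = calls$start_label,
    end_label = calls$end_label,
    span = target_key(calls$chrom, calls$start, calls$end),
    type = calls$type,
    n_intervals = calls$n_intervals,
    median_log2 = calls$median_log2,
    inferred_cn = calls$inferred_cn,
    recurrent = if ("recurrent" %in% names(calls)) calls$recurrent else rep(NA, nrow(calls)),
    gc_flag = if ("gc_flag" %in% names(calls)) calls$gc_flag else rep(NA, nrow(calls))
  )
}
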