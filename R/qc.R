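#' Five-number boxplot summary of a sample's log2 ratios
#'
#' Computes the conventional boxplot statistics used for thresholding and QC:
#' lower whisker, first quartile, median, third quartile, upper whisker.
#' Quartiles are Tukey hinges (the median of each half of the sorted data,
#' halves including the median element when n is odd). Whiskers are actual
#' data values: the most extreme observations within Q1/Q3 plus or minus
#' `iqr_multiplier` times the interquartile range. Masked intervals (`NA`)
#' and floored zero-coverage values are excluded first.
#'
#' @param values Numeric vector of log2 ratios for one sample.
#' @param iqr_multiplier Whisker multiplier of the IQR (default 3).
#' @param floor Values at or below this are treated as floored zero coverage
#'   and excluded.
#' @return A one-row tibble with columns `lower_whisker`, `q1`, `median`,
#'   `q3`, `upper_whisker`, `iqr_multiplier` and `n_used`.
#' @export
five_number_summary <- function(values, iqr_multiplier = 3, floor = -10) {
  v <- values[is.finite(values) & values > floor]
  if (length(v) < 5L) {
    abort(sprintf("five_number_summary needs at least 5 finite values, got %d", length(v)),
          class = "panelcnv_insufficient_data_error")
  }
  st <- boxplot.stats(v, coef = iqr_multiplier, do.conf = FALSE, do.out = FALSE)$stats
  tibble(
    lower_whisker = st[1L], q1 = st[2L], median = st[3L], q3 = st[4L],
    upper_whisker = st[5L], iqr_multiplier = iqr_multiplier, n_used = length(v)
  )
}

#' Five-number summaries for every sample in a batch
#'
#' @param log2_tbl Log2 ratio tibble.
#' @param config A [cnv_config()]; supplies the IQR multiplier and floor.
#' @return A tibble with one row per sample (column `sample` first).
#' @export
batch_summaries <- function(log2_tbl, config = cnv_config()) {
  samples <- sample_names(log2_tbl)
  purrr::map_dfr(samples, function(s) {
    dplyr::bind_cols(
      tibble(sample = s),
      five_number_summary(log2_tbl[[s]], config$iqr_multiplier, config$log2_floor)
    )
  })
}

#' Whisker-based sample quality control
#'
#' A sample fails QC when either boxplot whisker extends beyond the expected
#' theoretical log2 ratio of a single-copy change: upper whisker strictly
#' above `qc_gain_bound` (log2(3/2), about 0.58) or lower whisker strictly
#' below `qc_loss_bound` (-1). Such a distribution is too broad to resolve
#' single-copy changes and would skew the batch median.
#'
#' @param summaries Tibble from [batch_summaries()] (or a one-row
#'   [five_number_summary()] with a `sample` column).
#' @param config A [cnv_config()].
#' @return A tibble with columns `sample`, `passed` and `reason` (empty when
#'   passed; otherwise names the offending whisker and its value).
#' @export
sample_qc <- function(summaries, config = cnv_config()) {
  up <- summaries$upper_whisker > config$qc_gain_bound
  lo <- summaries$lower_whisker < config$qc_loss_bound
  reason <- dplyr::case_when(
    up & lo ~ sprintf("upper whisker %.3f > %.3f; lower whisker %.3f < %.3f",
                      summaries$upper_whisker, config$qc_gain_bound,
                      summaries$lower_whisker, config$qc_loss_bound),
    up ~ sprintf("upper whisker %.3f exceeds single-copy gain bound %.3f",
                 summaries$upper_whisker, config$qc_gain_bound),
    lo ~ sprintf("lower whisker %.3f below single-copy loss bound %.3f",
                 summaries$lower_whisker, config$qc_loss_bound),
    .default = ""
  )
  tibble(sample = summaries$sample, passed = !(up | lo), reason = reason)
}

#' Iterative batch quality control
#'
#' Normalizes the batch, evaluates the whisker QC rule on every sample,
#' removes failing samples, and re-normalizes the survivors as a fresh batch
#' (the batch median changes when samples are removed), repeating until an
#' iteration fails no one. If fewer than `min_pass_samples` samples survive,
#' the whole batch is failed and no call-ready matrix is returned.
#'
#' QC is evaluated on the X-corrected matrix of each iteration (configurable
#' via `qc_on_corrected`).
#'
#' @param cov Coverage tibble of the full batch.
#' @param config A [cnv_config()].
#' @param out_dir Optional directory; when given, each iteration writes its
#'   log2 matrix and QC summary into `iteration_k/` subdirectories.
#' @return An object of class `cnv_qc_run`: a list with `log2`, `log2_pre_x`,
#'   `sex`, `summaries` (final iteration), `qc` (joined per-sample QC table),
#'   `verdicts` (all samples, with the iteration at which each verdict became
#'   final), `batch_failed`, `n_iterations` and `iterations` (per-iteration
#'   records).
#' @export
iterate_qc <- function(cov, config = cnv_config(), out_dir = NULL) {
  all_samples <- sample_names(cov)
  if (length(all_samples) < 3L) {
    abort("iterate_qc needs at least 3 samples", class = "panelcnv_batch_size_error")
  }
  current <- all_samples
  verdicts <- tibble(sample = character(0), passed = logical(0),
                     reason = character(0), iteration = integer(0))
  iterations <- list()
  iter <- 0L
  norm <- NULL
  summaries <- NULL
  batch_failed <- FALSE

  repeat {
    iter <- iter + 1L
    if (length(current) < config$min_pass_samples) {
      batch_failed <- TRUE
      norm <- NULL
      break
    }
    norm <- normalize_coverage(cov[c(.meta_cols[.meta_cols %in% names(cov)], current)], config)
    qc_matrix <- if (config$qc_on_corrected) norm$log2 else norm$log2_pre_x
    summaries <- batch_summaries(qc_matrix, config)
    v <- sample_qc(summaries, config)
    failed <- v$sample[!v$passed]
    iterations[[iter]] <- list(
      samples = current, log2 = norm$log2, log2_pre_x = norm$log2_pre_x,
      sex = norm$sex, summaries = summaries, verdicts = v
    )
    if (!is.null(out_dir)) {
      write_iteration(iterations[[iter]], norm$sex, file.path(out_dir, paste0("iteration_", iter)), iter, config)
    }
    if (length(failed) == 0L) {
      verdicts <- dplyr::bind_rows(verdicts, dplyr::mutate(v, iteration = iter))
      break
    }
    verdicts <- dplyr::bind_rows(verdicts,
                                 dplyr::mutate(v[!v$passed, ], iteration = iter))
    current <- setdiff(current, failed)
  }
  if (batch_failed) {
    # survivors never reached a clean iteration; record them as passing their
    # last evaluated iteration so every sample carries a verdict
    if (length(current) > 0L && length(iterations) > 0L) {
      last <- iterations[[length(iterations)]]$verdicts
      verdicts <- dplyr::bind_rows(
        verdicts,
        dplyr::mutate(last[last$passed, , drop = FALSE], iteration = length(iterations))
      )
    }
    summaries <- if (length(iterations) > 0L) iterations[[length(iterations)]]$summaries else NULL
  }

  qc_tbl <- build_qc_table(verdicts, summaries,
                           if (!is.null(norm)) norm$sex else
                             if (length(iterations) > 0L) iterations[[length(iterations)]]$sex else NULL)
  structure(
    list(
      log2 = if (!batch_failed) norm$log2 else NULL,
      log2_pre_x = if (!batch_failed) norm$log2_pre_x else NULL,
      sex = if (!batch_failed) norm$sex else NULL,
      summaries = if (!batch_failed) summaries else NULL,
      qc = qc_tbl,
      verdicts = verdicts,
      batch_failed = batch_failed,
      n_iterations = length(iterations),
      iterations = iterations,
      config = config
    ),
    class = "cnv_qc_run"
  )
}

# join verdicts + final summaries + predicted sex into the QC summary table
build_qc_table <- function(verdicts, summaries, sex) {
  out <- verdicts
  if (!is.null(summaries)) {
    out <- dplyr::left_join(out, summaries, by = "sample")
  }
  if (!is.null(sex) && nrow(sex) > 0L) {
    out <- dplyr::left_join(out, sex[c("sample", "predicted_sex")], by = "sample")
  } else {
    out$predicted_sex <- NA_character_
  }
  dplyr::arrange(out, .data$sample)
}

write_iteration <- function(it, sex, dir, iter, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qc <- build_qc_table(dplyr::mutate(it$verdicts, iteration = iter), it$summaries, sex)
  write_outputs(it$log2, NULL, qc, dir)
  save_plot(plot_batch_boxplots(it$log2, it$verdicts, config = config),
            file.path(dir, "batch_boxplots"))
  invisible(dir)
}

#' @export
print.cnv_qc_run <- function(x, ...) {
  cat(sprintf("<cnv_qc_run> %d iteration(s); %s\n", x$n_iterations,
              if (x$batch_failed) "BATCH FAILED (too few passing samples)"
              else sprintf("%d/%d samples passed", sum(x$verdicts$passed), nrow(x$verdicts))))
  print(x$qc[c("sample", "passed", "reason", "iteration", "predicted_sex")])
  invisible(x)
}

#' @rdname iterate_qc
#' @param x A `cnv_qc_run` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cnv_qc_run <- function(x, ...) {
  x$qc
}

#' @rdname iterate_qc
#' @exportS3Method generics::glance
glance.cnv_qc_run <- function(x, ...) {
  tibble(
    n_samples = nrow(x$verdicts),
    n_passed = sum(x$verdicts$passed),
    n_iterations = x$n_iterations,
    batch_failed = x$batch_failed,
    n_intervals = if (!is.null(x$log2)) nrow(x$log2) else NA_integer_,
    n_masked = if (!is.null(x$log2)) sum(x$log2$masked) else NA_integer_
  )
}
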