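#' Segment log2 ratios into candidate CNV calls
#'
#' Applies the dual-threshold calling rule to every sample of a batch. An
#' interval is gain-eligible when its log2 ratio strictly exceeds both the
#' fixed gain threshold and the sample's upper boxplot whisker; loss-eligible
#' when it falls strictly below both the fixed loss threshold and the lower
#' whisker. Maximal runs of consecutive same-type eligible intervals on one
#' chromosome become calls; masked intervals break runs; runs shorter than
#' `min_probes_gain`/`min_probes_loss` are dropped. The estimated absolute
#' copy number of a call is `2 * 2^median_log2` (on the X chromosome this is
#' relative to the sample's sex-corrected baseline, i.e. its own expected X
#' dosage).
#'
#' Call identifiers are 1-based per sample in genome order and are shared
#' between the call table and the plot annotations.
#'
#' @param log2_tbl Log2 ratio tibble (final QC iteration).
#' @param summaries Five-number summaries from [batch_summaries()] on the same
#'   matrix.
#' @param config A [cnv_config()].
#' @param excluded_labels Optional character vector of interval labels for
#'   exons known to fail NGS analysis; single-interval calls confined to these
#'   labels are dropped.
#' @return A call tibble: `sample`, `id`, `type` (`"gain"`/`"loss"`), `chrom`,
#'   `first_rank`, `last_rank`, `start`, `end`, `start_label`, `end_label`,
#'   `n_intervals`, `median_log2`, `inferred_cn`.
#' @export
segment_calls <- function(log2_tbl, summaries, config = cnv_config(),
                          excluded_labels = NULL) {
  samples <- sample_names(log2_tbl)
  intervals <- interval_meta(log2_tbl)
  per_sample <- purrr::map(samples, function(s) {
    fns <- summaries[summaries$sample == s, , drop = FALSE]
    if (nrow(fns) != 1L) {
      abort(sprintf("no five-number summary for sample %s", s),
            class = "panelcnv_alignment_error")
    }
    segment_one(log2_tbl[[s]], intervals, fns, config, sample = s)
  })
  calls <- dplyr::bind_rows(c(list(empty_calls()), per_sample))
  if (!is.null(excluded_labels) && nrow(calls) > 0L) {
    drop <- calls$n_intervals == 1L & calls$start_label %in% excluded_labels
    calls <- calls[!drop, , drop = FALSE]
    calls <- dplyr::group_by(calls, .data$sample)
    calls <- dplyr::mutate(calls, id = dplyr::row_number())
    calls <- dplyr::ungroup(calls)
  }
  calls
}

# Calling core for one sample. `ratios` is aligned to interval rank order.
segment_one <- function(ratios, intervals, fns, config, sample = "sample") {
  n <- nrow(intervals)
  if (length(ratios) != n) {
    abort(sprintf("ratio vector length %d does not match %d intervals", length(ratios), n),
          class = "panelcnv_alignment_error")
  }
  eligible <- eligibility(ratios, intervals, fns, config)
  # encode chromosome in the run value so runs never cross chromosomes
  run_key <- ifelse(eligible == "none", "none", paste(eligible, intervals$chrom))
  r <- rle(run_key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "none"
  out <- purrr::pmap_dfr(
    list(starts[keep], ends[keep], sub(" .*", "", r$values[keep])),
    function(i, j, type) {
      min_probes <- if (type == "gain") config$min_probes_gain else config$min_probes_loss
      if (j - i + 1L < min_probes) return(NULL)
      med <- median(ratios[i:j])
      tibble(
        sample = sample, id = NA_integer_, type = type,
        chrom = intervals$chrom[i],
        first_rank = intervals$rank[i], last_rank = intervals$rank[j],
        start = intervals$start[i], end = intervals$end[j],
        start_label = intervals$label[i], end_label = intervals$label[j],
        n_intervals = j - i + 1L,
        median_log2 = med,
        inferred_cn = 2 * 2^med
      )
    }
  )
  if (nrow(out) == 0L) {
    return(empty_calls())
  }
  out <- dplyr::arrange(out, .data$first_rank)
  out$id <- seq_len(nrow(out))
  out
}

empty_calls <- function() {
  tibble(
    sample = character(0), id = integer(0), type = character(0),
    chrom = character(0), first_rank = integer(0), last_rank = integer(0),
    start = integer(0), end = integer(0),
    start_label = character(0), end_label = character(0),
    n_intervals = integer(0), median_log2 = numeric(0), inferred_cn = numeric(0)
  )
}

# per-interval eligibility under the dual (fixed threshold AND whisker) rule;
# strict comparisons throughout, masked/floored intervals ineligible
eligibility <- function(ratios, intervals, fns, config) {
  gain_thr <- max(config$gain_log2, fns$upper_whisker)
  loss_thr <- min(config$loss_log2, fns$lower_whisker)
  usable <- !intervals$masked & is.finite(ratios) & ratios > config$log2_floor
  dplyr::case_when(
    usable & ratios > gain_thr ~ "gain",
    usable & ratios < loss_thr ~ "loss",
    .default = "none"
  )
}

#' Flag recurrent calls across a cohort
#'
#' Groups calls into "unique calls" by the key (chromosome, first rank, last
#' rank, type) and flags a call as recurrent when the number of distinct cases
#' carrying it exceeds `cohort_recurrence_fraction` of the cohort. Recurrent
#' calls are likely copy-number polymorphisms or systematic capture artifacts;
#' they are flagged, never silently deleted (dropping them from the written
#' table is a separate reporting choice, `drop_recurrent`).
#'
#' @param calls Call tibble, possibly pooled over many batches.
#' @param n_cases Total number of cases in the cohort the frequency is
#'   computed over.
#' @param config A [cnv_config()].
#' @return The call tibble with a logical `recurrent` column and a
#'   `cohort_freq` column (distinct-case fraction).
#' @export
cohort_annotate <- function(calls, n_cases, config = cnv_config()) {
  stopifnot(n_cases >= 1)
  if (nrow(calls) == 0L) {
    calls$recurrent <- logical(0)
    calls$cohort_freq <- numeric(0)
    return(calls)
  }
  calls |>
    dplyr::group_by(.data$chrom, .data$first_rank, .data$last_rank, .data$type) |>
    dplyr::mutate(cohort_freq = dplyr::n_distinct(.data$sample) / n_cases) |>
    dplyr::ungroup() |>
    dplyr::mutate(recurrent = .data$cohort_freq > config$cohort_recurrence_fraction)
}

#' Flag calls in extreme-GC sequence
#'
#' Small recurrent artifact calls concentrate in exons of extreme GC content,
#' where capture efficiency is least reproducible. A call is flagged when
#' every one of its member intervals has GC fraction below `gc_low` or above
#' `gc_high`. GC content is user-supplied per interval label; it is not
#' computed from sequence.
#'
#' @param calls Call tibble.
#' @param intervals Interval tibble (for label-to-rank mapping).
#' @param gc_table Tibble with columns `label` and `gc` (fraction in 0..1), or
#'   `NULL`, in which case all flags stay `FALSE` with a notice.
#' @param config A [cnv_config()].
#' @return The call tibble with a logical `gc_flag` column.
#' @export
flag_extreme_gc <- function(calls, intervals, gc_table = NULL, config = cnv_config()) {
  if (is.null(gc_table)) {
    inform("no GC table supplied; gc_flag left FALSE for all calls")
    calls$gc_flag <- rep(FALSE, nrow(calls))
    return(calls)
  }
  stopifnot(all(c("label", "gc") %in% names(gc_table)))
  gc_by_rank <- gc_table$gc[match(intervals$label, gc_table$label)]
  flag_one <- function(first_rank, last_rank) {
    idx <- which(intervals$rank >= first_rank & intervals$rank <= last_rank)
    gc <- gc_by_rank[idx]
    if (anyNA(gc)) return(FALSE)
    all(gc < config$gc_low | gc > config$gc_high)
  }
  calls$gc_flag <- purrr::map2_lgl(calls$first_rank, calls$last_rank, flag_one)
  calls
}

#' Droplet digital PCR confirmation calculator
#'
#' Normalizes a raw ddPCR copy-number value by the sample-specific Reference
#' Correction Constant (RCC), defined as two times the AP3B1:RPP30 reference
#' gene copy-number ratio, then rescales by `rcc_scale` (default 2, restoring
#' the raw value when the reference ratio is 1). The verdict is a loss when
#' the normalized copy number is below 1.5, a gain when above 2.5, otherwise
#' copy-neutral. Samples whose RPP30:AP3B1 ratio falls outside the 0.9-1.2
#' window are flagged for manual review (`qc_ok = FALSE`), since the
#' reference genes themselves may be copy-variable.
#'
#' @param raw_cn Raw ddPCR copy-number value(s), non-negative.
#' @param ap3b1_rpp30_ratio Copy-number ratio(s) of AP3B1 to RPP30, positive.
#' @param config A [cnv_config()] (supplies `rcc_scale`).
#' @param loss_below,gain_above Verdict boundaries on the normalized copy
#'   number.
#' @param qc_window RPP30:AP3B1 window outside which the sample needs manual
#'   review.
#' @return A tibble with columns `raw_cn`, `ap3b1_rpp30_ratio`, `rcc`,
#'   `normalized_cn`, `verdict` (`"loss"`/`"neutral"`/`"gain"`) and `qc_ok`.
#' @export
ddpcr_call <- function(raw_cn, ap3b1_rpp30_ratio, config = cnv_config(),
                       loss_below = 1.5, gain_above = 2.5,
                       qc_window = c(0.9, 1.2)) {
  if (any(!is.finite(ap3b1_rpp30_ratio)) || any(ap3b1_rpp30_ratio <= 0)) {
    abort("ap3b1_rpp30_ratio must be positive", class = "panelcnv_input_error")
  }
  if (any(raw_cn < 0)) {
    abort("raw_cn must be non-negative", class = "panelcnv_input_error")
  }
  rcc <- 2 * ap3b1_rpp30_ratio
  normalized <- raw_cn / rcc * config$rcc_scale
  rpp30_ap3b1 <- 1 / ap3b1_rpp30_ratio
  tibble(
    raw_cn = raw_cn,
    ap3b1_rpp30_ratio = ap3b1_rpp30_ratio,
    rcc = rcc,
    normalized_cn = normalized,
    verdict = dplyr::case_when(
      normalized < loss_below ~ "loss",
      normalized > gain_above ~ "gain",
      .default = "neutral"
    ),
    # tiny slack absorbs float error from the reciprocal, not a policy change
    qc_ok = rpp30_ap3b1 >= qc_window[1] - 1e-9 & rpp30_ap3b1 <= qc_window[2] + 1e-9
  )
}
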