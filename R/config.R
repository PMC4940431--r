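#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with its default. Defaults
#' reproduce a clinically validated configuration for exon-level panels:
#' fixed log2 thresholds of 0.40 (gain) and -0.55 (loss), a boxplot IQR
#' multiplier of 3, whisker QC bounds at the theoretical single-copy gain
#' (log2(3/2) ~ 0.58) and single-copy loss (log2(1/2) = -1), and a minimum of
#' three passing samples per batch.
#'
#' @param gain_log2 Minimum log2 ratio for a gain call (log2 units).
#' @param loss_log2 Maximum log2 ratio for a loss call (log2 units).
#' @param iqr_multiplier Boxplot whisker multiplier of the interquartile range.
#' @param qc_gain_bound Upper-whisker QC bound; a sample fails when its upper
#'   whisker exceeds this (strictly).
#' @param qc_loss_bound Lower-whisker QC bound; a sample fails when its lower
#'   whisker falls below this (strictly).
#' @param min_pass_samples Minimum samples that must pass QC or the whole
#'   batch is failed.
#' @param min_probes_gain,min_probes_loss Minimum consecutive intervals for a
#'   gain/loss call.
#' @param cohort_recurrence_fraction Fraction of the cohort above which an
#'   identical call is flagged recurrent.
#' @param gc_low,gc_high GC-content bounds (fractions); calls whose intervals
#'   all fall outside `[gc_low, gc_high]` are flagged.
#' @param x_chrom_name Chromosome names treated as X.
#' @param x_min_separation Minimum medoid separation (log2 units) below which
#'   X clustering is declared degenerate (single-sex batch).
#' @param x_trim Fraction trimmed from each tail of a sample's X-interval
#'   ratios before computing its X summary (outlier-probe removal).
#' @param log2_floor Log2 value substituted for a zero fraction at an unmasked
#'   interval (keeps the matrix finite); floored values are excluded from
#'   boxplot statistics.
#' @param qc_on_corrected Evaluate QC whiskers on the X-corrected matrix
#'   (default) rather than the pre-correction matrix.
#' @param drop_recurrent Drop recurrent-flagged calls from the written call
#'   table instead of only flagging them.
#' @param rcc_scale Rescaling factor applied after division by the ddPCR
#'   Reference Correction Constant (see [ddpcr_call()]).
#' @return A named list of class `cnv_config`.
#' @export
cnv_config <- function(gain_log2 = 0.40,
                       loss_log2 = -0.55,
                       iqr_multiplier = 3,
                       qc_gain_bound = log2(3 / 2),
                       qc_loss_bound = -1,
                       min_pass_samples = 3,
                       min_probes_gain = 1,
                       min_probes_loss = 1,
                       cohort_recurrence_fraction = 0.01,
                       gc_low = 0.35,
                       gc_high = 0.65,
                       x_chrom_name = c("X", "chrX"),
                       x_min_separation = 0.3,
                       x_trim = 0.1,
                       log2_floor = -10,
                       qc_on_corrected = TRUE,
                       drop_recurrent = FALSE,
                       rcc_scale = 2) {
  stopifnot(gain_log2 > 0, loss_log2 < 0,
            cohort_recurrence_fraction > 0, cohort_recurrence_fraction < 1,
            iqr_multiplier > 0, gc_low < gc_high)
  structure(
    list(
      gain_log2 = gain_log2, loss_log2 = loss_log2,
      iqr_multiplier = iqr_multiplier,
      qc_gain_bound = qc_gain_bound, qc_loss_bound = qc_loss_bound,
      min_pass_samples = min_pass_samples,
      min_probes_gain = min_probes_gain, min_probes_loss = min_probes_loss,
      cohort_recurrence_fraction = cohort_recurrence_fraction,
      gc_low = gc_low, gc_high = gc_high,
      x_chrom_name = x_chrom_name,
      x_min_separation = x_min_separation, x_trim = x_trim,
      log2_floor = log2_floor,
      qc_on_corrected = qc_on_corrected,
      drop_recurrent = drop_recurrent,
      rcc_scale = rcc_scale
    ),
    class = "cnv_config"
  )
}

#' @export
print.cnv_config <- function(x, ...) {
  cat("<cnv_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
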