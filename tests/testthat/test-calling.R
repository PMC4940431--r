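one_chrom_intervals <- function(n) {
  start <- as.integer(1000L + (seq_len(n) - 1L) * 1000L)
  tibble::tibble(
    chrom = "chr1", start = start, end = start + 99L,
    label = sprintf("GENE%d_Exon%d", ceiling(seq_len(n) / 4), ((seq_len(n) - 1L) %% 4L) + 1L),
    rank = seq_len(n) - 1L, is_x = FALSE
  )
}

mk_log2 <- function(ratios, intervals = NULL) {
  iv <- if (is.null(intervals)) one_chrom_intervals(length(ratios)) else intervals
  iv$masked <- FALSE
  iv$S1 <- ratios
  iv
}

mk_fns <- function(lw, uw, sample = "S1") {
  tibble::tibble(sample = sample, lower_whisker = lw, q1 = lw / 2, median = 0,
                 q3 = uw / 2, upper_whisker = uw, iqr_multiplier = 3, n_used = 100L)
}

test_that("the dual-threshold rule produces the worked example calls", {
  cfg <- cnv_config()

  # consecutive losses become one call with inferred copy number 1
  lr <- mk_log2(c(0, -1, -1, 0))
  calls <- segment_calls(lr, mk_fns(-0.3, 0.3), cfg)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "loss")
  expect_equal(c(calls$first_rank, calls$last_rank), c(1L, 2L))
  expect_equal(calls$median_log2, -1)
  expect_equal(calls$inferred_cn, 1)

  # flat sample: no calls
  expect_equal(nrow(segment_calls(mk_log2(rep(0, 6)), mk_fns(-0.3, 0.3), cfg)), 0)

  # exceeds the fixed gain threshold but not the whisker: rejected
  lr2 <- mk_log2(c(0, 0.45, 0, 0))
  expect_equal(nrow(segment_calls(lr2, mk_fns(-0.3, 0.50), cfg)), 0)

  # exceeds both: single-interval gain, cn = 2 * 2^0.6
  lr3 <- mk_log2(c(0, 0.60, 0, 0))
  g <- segment_calls(lr3, mk_fns(-0.3, 0.30), cfg)
  expect_equal(g$type, "gain")
  expect_equal(g$n_intervals, 1L)
  expect_equal(g$inferred_cn, 2 * 2^0.6, tolerance = 1e-9)
})

test_that("comparisons at exactly the threshold are strict", {
  cfg <- cnv_config()
  lr <- mk_log2(c(cfg$gain_log2, cfg$loss_log2, 0, 0))
  expect_equal(nrow(segment_calls(lr, mk_fns(-0.2, 0.2), cfg)), 0)
})

test_that("runs break at chromosome boundaries and masked intervals", {
  iv <- tiny_intervals(8, 0)           # chr1 ranks 0-3, chr2 ranks 4-7
  lr <- mk_log2(rep(-1, 8), iv)
  calls <- segment_calls(lr, mk_fns(-0.3, 0.3), cnv_config())
  expect_equal(nrow(calls), 2)
  expect_equal(calls$chrom, c("chr1", "chr2"))
  expect_equal(calls$id, 1:2)          # per-sample ids in genome order

  lr$masked[2] <- TRUE
  lr$S1[2] <- NA
  calls2 <- segment_calls(lr, mk_fns(-0.3, 0.3), cnv_config())
  expect_equal(nrow(calls2), 3)
  expect_equal(calls2$first_rank, c(0L, 2L, 4L))
})

test_that("minimum probe counts drop short runs per type", {
  cfg <- cnv_config(min_probes_loss = 2, min_probes_gain = 1)
  lr <- mk_log2(c(-1, 0, -1, -1, 0.8, 0, 0, 0))
  calls <- segment_calls(lr, mk_fns(-0.3, 0.3), cfg)
  expect_equal(calls$type, c("loss", "gain"))
  expect_equal(calls$first_rank, c(2L, 4L))   # single-probe loss at rank 0 dropped
})

test_that("segmentation matches the brute-force run enumerator on random vectors", {
  set.seed(101)
  cfg <- cnv_config()
  for (rep in 1:200) {
    case <- random_ratio_case(n = 50)
    lr <- case$intervals
    lr$S1 <- case$ratios
    usable <- case$ratios[!lr$masked & is.finite(case$ratios)]
    fns <- cbind(tibble::tibble(sample = "S1"),
                 five_number_summary(usable, 3))
    got <- segment_calls(lr, fns, cfg)
    want <- oracle_segments(case$ratios, lr, fns, cfg)
    expect_equal(got[c("type", "first_rank", "last_rank", "median_log2")],
                 want, ignore_attr = TRUE)
    # no overlap within the sample
    if (nrow(got) > 1) {
      expect_true(all(got$first_rank[-1] > got$last_rank[-nrow(got)]))
    }
  }
})

test_that("exclusion lists drop single-interval calls in known-bad exons", {
  lr <- mk_log2(c(0, -1, 0, 0, -1, -1, 0, 0))
  fns <- mk_fns(-0.3, 0.3)
  all_calls <- segment_calls(lr, fns, cnv_config())
  expect_equal(nrow(all_calls), 2)
  bad_label <- lr$label[2]
  kept <- segment_calls(lr, fns, cnv_config(), excluded_labels = bad_label)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$n_intervals, 2L)
  expect_equal(kept$id, 1L)   # ids renumbered after the filter
})

test_that("cohort recurrence flags identical calls above the frequency threshold", {
  base <- tibble::tibble(
    sample = "X", id = 1L, type = "loss", chrom = "chr1",
    first_rank = 5L, last_rank = 5L, start = 100L, end = 200L,
    start_label = "G_Exon1", end_label = "G_Exon1", n_intervals = 1L,
    median_log2 = -1, inferred_cn = 1
  )
  calls3 <- dplyr::bind_rows(
    dplyr::mutate(base, sample = "A"),
    dplyr::mutate(base, sample = "B"),
    dplyr::mutate(base, sample = "C")
  )
  ann <- cohort_annotate(calls3, n_cases = 100)
  expect_true(all(ann$recurrent))          # 3/100 > 1%
  expect_equal(unique(ann$cohort_freq), 0.03)

  ann200 <- cohort_annotate(calls3[1, ], n_cases = 200)
  expect_false(ann200$recurrent)           # 1/200 <= 1%

  # same span, different type -> distinct unique calls
  mixed <- dplyr::bind_rows(
    dplyr::mutate(base, sample = "A"),
    dplyr::mutate(base, sample = "B", type = "gain")
  )
  annm <- cohort_annotate(mixed, n_cases = 100)
  expect_equal(annm$cohort_freq, c(0.01, 0.01))
  expect_false(any(annm$recurrent))
})

test_that("extreme-GC flags require every member interval outside the window", {
  iv <- tiny_intervals(6, 0)
  gc <- tibble::tibble(label = iv$label, gc = c(0.30, 0.40, 0.70, 0.70, 0.80, 0.50))
  mk_call <- function(fr, lr_) tibble::tibble(
    sample = "S", id = 1L, type = "loss", chrom = "chr1",
    first_rank = fr, last_rank = lr_, start = 1L, end = 2L,
    start_label = iv$label[fr + 1], end_label = iv$label[lr_ + 1],
    n_intervals = lr_ - fr + 1L, median_log2 = -1, inferred_cn = 1
  )
  cfg <- cnv_config()
  expect_true(flag_extreme_gc(mk_call(0L, 0L), iv, gc, cfg)$gc_flag)    # 0.30 < 0.35
  expect_false(flag_extreme_gc(mk_call(1L, 2L), iv, gc, cfg)$gc_flag)   # 0.40 in range
  expect_true(flag_extreme_gc(mk_call(3L, 4L), iv, gc, cfg)$gc_flag)    # 0.70, 0.80

  expect_message(out <- flag_extreme_gc(mk_call(0L, 0L), iv, NULL, cfg), "GC")
  expect_false(out$gc_flag)
})

test_that("ddPCR normalization, verdicts and reference QC behave at the boundaries", {
  # reference ratio 1 leaves a diploid value unchanged
  r <- ddpcr_call(2.0, 1.0)
  expect_equal(r$normalized_cn, 2.0)
  expect_equal(r$verdict, "neutral")
  expect_true(r$qc_ok)

  expect_equal(ddpcr_call(1.0, 1.0)$verdict, "loss")     # 1.0 < 1.5
  expect_equal(ddpcr_call(3.0, 1.0)$verdict, "gain")     # 3.0 > 2.5
  # boundary values are neutral (strict comparisons)
  expect_equal(ddpcr_call(1.5, 1.0)$verdict, "neutral")
  expect_equal(ddpcr_call(2.5, 1.0)$verdict, "neutral")

  # RPP30:AP3B1 window: supplied ratio is AP3B1:RPP30
  expect_false(ddpcr_call(2.0, 1 / 0.85)$qc_ok)   # RPP30:AP3B1 = 0.85 < 0.9
  expect_false(ddpcr_call(2.0, 1 / 1.25)$qc_ok)   # 1.25 > 1.2
  expect_true(ddpcr_call(2.0, 1 / 0.9)$qc_ok)
  expect_true(ddpcr_call(2.0, 1 / 1.2)$qc_ok)

  expect_error(ddpcr_call(2.0, 0), class = "panelcnv_input_error")
  expect_error(ddpcr_call(-1, 1), class = "panelcnv_input_error")
})
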