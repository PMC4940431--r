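#' Plot data for one sample's log2 ratio track
#'
#' Builds the machine-readable data behind a review plot: per-interval points
#' (plotted at rank order, not genomic scale), guideline positions, orange
#' call markers keyed by call identifier, and gene-label tick positions (the
#' first interval of each label group, where the group is the label prefix
#' before the final `_Exon` part).
#'
#' @param log2_tbl Log2 ratio tibble.
#' @param calls Call tibble for the batch ([segment_calls()]).
#' @param summaries Five-number summaries ([batch_summaries()]).
#' @param sample Sample name.
#' @param config A [cnv_config()].
#' @param scope `"genome"` or a chromosome name.
#' @return A list of tibbles: `points` (`rank`, `log2`, `state`), `guidelines`
#'   (`value`, `kind`, `style`), `markers` (`id`, `first_rank`, `last_rank`,
#'   `type`), `gene_labels` (`rank`, `gene`), plus `sample` and `scope`.
#' @export
plot_sample_data <- function(log2_tbl, calls, summaries, sample,
                             config = cnv_config(), scope = "genome") {
  stopifnot(sample %in% sample_names(log2_tbl))
  keep <- if (identical(scope, "genome")) rep(TRUE, nrow(log2_tbl)) else log2_tbl$chrom == scope
  iv <- interval_meta(log2_tbl)[keep, , drop = FALSE]
  ratios <- log2_tbl[[sample]][keep]

  sc <- calls[calls$sample == sample, , drop = FALSE]
  if (!identical(scope, "genome")) sc <- sc[sc$chrom == scope, , drop = FALSE]

  state <- rep("neutral", nrow(iv))
  if (nrow(sc) > 0L) {
    for (k in seq_len(nrow(sc))) {
      in_call <- iv$rank >= sc$first_rank[k] & iv$rank <= sc$last_rank[k]
      state[in_call] <- sc$type[k]
    }
  }
  state[iv$masked] <- "masked"

  fns <- summaries[summaries$sample == sample, , drop = FALSE]
  guidelines <- tibble(
    value = c(config$gain_log2, config$loss_log2,
              fns$upper_whisker, fns$lower_whisker,
              log2(3 / 2), -1),
    kind = c("gain_threshold", "loss_threshold",
             "upper_whisker", "lower_whisker",
             "theoretical_gain", "theoretical_loss"),
    style = c("solid", "solid", "dashed", "dashed", "light", "light")
  )

  gene <- sub("_Exon\\d+$", "", iv$label)
  first_of_group <- !duplicated(gene)
  gene_labels <- tibble(rank = iv$rank[first_of_group], gene = gene[first_of_group])

  list(
    sample = sample, scope = scope,
    points = tibble(rank = iv$rank, chrom = iv$chrom, log2 = ratios, state = state),
    guidelines = guidelines,
    markers = if (nrow(sc) > 0L) {
      tibble(id = sc$id, first_rank = sc$first_rank, last_rank = sc$last_rank, type = sc$type)
    } else {
      tibble(id = integer(0), first_rank = integer(0), last_rank = integer(0), type = character(0))
    },
    gene_labels = gene_labels
  )
}

.call_colors <- c(neutral = "grey25", gain = "#d7191c", loss = "#2c7bb6",
                  masked = "grey80", marker = "#ff8c00")

#' Per-sample CNV review plot
#'
#' Renders the review plot for one sample: log2 ratios by interval rank with
#' CNV-supporting points color-coded (gains red, losses blue), solid black
#' guidelines at the fixed calling thresholds, dashed guidelines at the
#' sample's boxplot whiskers, light guidelines at the theoretical single-copy
#' gain/loss ratios, an orange segment marker labeled with the call
#' identifier above each call, and gene labels under the first interval of
#' each label group.
#'
#' @inheritParams plot_sample_data
#' @return A ggplot object. The underlying data is available via
#'   [plot_sample_data()] and the sidecar TSVs written by
#'   [write_plot_sidecar()].
#' @export
plot_sample <- function(log2_tbl, calls, summaries, sample,
                        config = cnv_config(), scope = "genome") {
  pd <- plot_sample_data(log2_tbl, calls, summaries, sample, config, scope)
  marker_y <- max(pd$points$log2, pd$guidelines$value, na.rm = TRUE) + 0.25
  p <- ggplot2::ggplot(pd$points, ggplot2::aes(x = .data$rank, y = .data$log2)) +
    ggplot2::geom_hline(
      data = pd$guidelines,
      ggplot2::aes(yintercept = .data$value, linetype = .data$style),
      colour = ifelse(pd$guidelines$style == "light", "grey70", "black"),
      linewidth = 0.3, show.legend = FALSE
    ) +
    ggplot2::scale_linetype_manual(values = c(solid = "solid", dashed = "dashed", light = "solid")) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state), size = 0.6, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = .call_colors, guide = "none") +
    ggplot2::scale_x_continuous(
      breaks = pd$gene_labels$rank, labels = pd$gene_labels$gene,
      guide = ggplot2::guide_axis(angle = 90)
    ) +
    ggplot2::labs(
      x = "target interval (rank order, not to genomic scale)",
      y = "log2 ratio vs batch median",
      title = sprintf("%s (%s)", pd$sample, pd$scope)
    ) +
    ggplot2::theme_bw(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 5))
  if (nrow(pd$markers) > 0L) {
    p <- p +
      ggplot2::annotate("segment",
        x = pd$markers$first_rank - 0.4, xend = pd$markers$last_rank + 0.4,
        y = marker_y, yend = marker_y,
        colour = .call_colors[["marker"]], linewidth = 2
      ) +
      ggplot2::annotate("text",
        x = (pd$markers$first_rank + pd$markers$last_rank) / 2,
        y = marker_y + 0.15, label = pd$markers$id,
        colour = .call_colors[["marker"]], size = 3
      )
  }
  p
}

#' X-normalization review boxplots
#'
#' Two-panel figure of per-sample boxplots of X-interval log2 ratios before
#' and after the sex-composition correction. In a mixed-sex batch the "before"
#' panel shows two clusters of boxplots (males about one log2 unit below
#' females); after correction all samples center on zero.
#'
#' @param log2_pre_x Log2 tibble before X correction.
#' @param log2_post Log2 tibble after X correction.
#' @param config A [cnv_config()].
#' @return A ggplot object, or `NULL` (with a notice) when the panel has no X
#'   intervals.
#' @export
plot_x_boxplots <- function(log2_pre_x, log2_post, config = cnv_config()) {
  if (!any(log2_pre_x$is_x & !log2_pre_x$masked)) {
    inform("no X-chromosome intervals; X boxplot skipped")
    return(NULL)
  }
  long <- function(tbl, stage) {
    tbl[tbl$is_x & !tbl$masked, , drop = FALSE] |>
      tidyr::pivot_longer(dplyr::all_of(sample_names(tbl)),
                          names_to = "sample", values_to = "log2") |>
      dplyr::mutate(stage = stage)
  }
  dat <- dplyr::bind_rows(long(log2_pre_x, "before correction"),
                          long(log2_post, "after correction")) |>
    dplyr::mutate(stage = factor(.data$stage, c("before correction", "after correction"))) |>
    dplyr::filter(is.finite(.data$log2), .data$log2 > config$log2_floor)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample, y = .data$log2)) +
    ggplot2::geom_boxplot(coef = config$iqr_multiplier, outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60", linewidth = 0.3) +
    ggplot2::facet_wrap(~stage, ncol = 1) +
    ggplot2::labs(x = NULL, y = "X-interval log2 ratio") +
    ggplot2::theme_bw(base_size = 9)
}

#' Batch QC boxplots
#'
#' One boxplot per sample over all unmasked intervals, drawn from the same
#' five-number summaries used by the QC rule (whisker geometry is therefore
#' identical to [five_number_summary()]), with reference lines at the
#' theoretical single-copy gain and loss ratios. Samples that failed QC are
#' highlighted.
#'
#' @param log2_tbl Log2 ratio tibble of one iteration.
#' @param verdicts Verdict tibble from [sample_qc()] for the same iteration.
#' @param config A [cnv_config()].
#' @return A ggplot object.
#' @export
plot_batch_boxplots <- function(log2_tbl, verdicts, config = cnv_config()) {
  stats <- batch_summaries(log2_tbl, config) |>
    dplyr::left_join(verdicts[c("sample", "passed")], by = "sample")
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$sample, fill = .data$passed)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$lower_whisker, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$upper_whisker),
      stat = "identity", width = 0.6
    ) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey90", `FALSE` = "#fdae61"),
                               labels = c(`TRUE` = "pass", `FALSE` = "fail"),
                               name = "QC") +
    ggplot2::geom_hline(yintercept = c(config$qc_gain_bound, config$qc_loss_bound),
                        colour = "grey40", linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "log2 ratio") +
    ggplot2::theme_bw(base_size = 9)
}

#' @rdname iterate_qc
#' @param object A `cnv_qc_run` object.
#' @exportS3Method ggplot2::autoplot
autoplot.cnv_qc_run <- function(object, ...) {
  it <- object$iterations[[object$n_iterations]]
  plot_batch_boxplots(it$log2, it$verdicts, object$config)
}

#' Write a plot to disk
#'
#' Writes `<path>.pdf` always and attempts `<path>.png` (skipped with a notice
#' when no raster device is available on the host).
#'
#' @param plot A ggplot object (`NULL` is ignored).
#' @param path Output path without extension.
#' @param width,height Size in inches.
#' @return Invisibly, the paths written.
#' @export
save_plot <- function(plot, path, width = 10, height = 4) {
  if (is.null(plot)) return(invisible(character(0)))
  paths <- character(0)
  pdf_path <- paste0(path, ".pdf")
  ggplot2::ggsave(pdf_path, plot, width = width, height = height, device = "pdf")
  paths <- c(paths, pdf_path)
  png_path <- paste0(path, ".png")
  ok <- tryCatch({
    ggplot2::ggsave(png_path, plot, width = width, height = height, dpi = 150)
    TRUE
  }, error = function(e) FALSE)
  if (ok) paths <- c(paths, png_path)
  invisible(paths)
}

#' Write the sidecar TSVs behind a sample plot
#'
#' Emits the plot's data series as text (points, guidelines, markers, gene
#' labels) so the visual contract — guideline positions, marker identifiers,
#' point states — is machine-checkable without pixel comparisons.
#'
#' @param pd Result of [plot_sample_data()].
#' @param path Output path without extension.
#' @return Invisibly, the paths written.
#' @export
write_plot_sidecar <- function(pd, path) {
  paths <- c(points = paste0(path, "_points.tsv"),
             guidelines = paste0(path, "_guidelines.tsv"),
             markers = paste0(path, "_markers.tsv"))
  readr::write_tsv(pd$points, paths[["points"]], progress = FALSE)
  readr::write_tsv(pd$guidelines, paths[["guidelines"]], progress = FALSE)
  readr::write_tsv(pd$markers, paths[["markers"]], progress = FALSE)
  invisible(paths)
}
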