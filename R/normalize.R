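#' Fractional coverage per sample
#'
#' Divides each sample's per-interval total coverage by that sample's summed
#' coverage over all intervals, so every sample column sums to 1. Fractional
#' coverage removes overall sequencing-depth differences between samples;
#' multiplying a sample's raw totals by any positive constant leaves its
#' fractions unchanged.
#'
#' @param cov Coverage tibble from [load_batch()] or [simulate_batch()].
#' @return A tibble of the same shape with sample columns replaced by
#'   fractions.
#' @export
fractional_coverage <- function(cov) {
  samples <- sample_names(cov)
  out <- cov
  for (s in samples) {
    tot <- sum(cov[[s]])
    if (!is.finite(tot) || tot <= 0) {
      abort(sprintf("sample %s has zero total coverage", s),
            class = "panelcnv_degenerate_sample_error")
    }
    out[[s]] <- cov[[s]] / tot
  }
  out
}

#' Batch-median log2 ratios
#'
#' For each interval, divides every sample's fractional coverage by the median
#' fraction across the batch and takes log2. Under the assumption that most
#' samples are copy-neutral at any one interval, the batch median is the
#' diploid reference: a ratio of 0 means two copies, about 0.58 (log2(3/2))
#' a single-copy gain, and -1 a single-copy loss.
#'
#' Intervals whose batch-median fraction is 0 (dead baits) are masked: their
#' ratios are set to `NA` and they are excluded from all downstream
#' statistics. A zero fraction at an unmasked interval is floored at
#' `config$log2_floor` rather than -Inf.
#'
#' @param fractions Fraction tibble from [fractional_coverage()].
#' @param config A [cnv_config()].
#' @return A log2 ratio tibble: interval metadata, a `masked` logical column,
#'   and one log2 ratio column per sample.
#' @export
batch_median_log2 <- function(fractions, config = cnv_config()) {
  samples <- sample_names(fractions)
  if (length(samples) < 3L) {
    abort(sprintf("batch has %d samples; at least 3 are required for a representative median",
                  length(samples)),
          class = "panelcnv_batch_size_error")
  }
  mat <- sample_matrix(fractions)
  med <- apply(mat, 1L, median)
  masked <- med == 0
  out <- interval_meta(fractions)
  out$masked <- masked
  for (s in samples) {
    r <- log2(fractions[[s]] / med)
    r[!masked & fractions[[s]] == 0] <- config$log2_floor
    r[masked] <- NA_real_
    out[[s]] <- r
  }
  out
}

# Per-sample X summary: median of the sample's unmasked X-interval ratios
# after symmetric tail trimming (outlier-probe removal).
x_summaries <- function(log2_tbl, trim = 0.1, floor = -10) {
  samples <- sample_names(log2_tbl)
  xr <- log2_tbl[log2_tbl$is_x & !log2_tbl$masked, , drop = FALSE]
  purrr::map_dbl(setNames(samples, samples), function(s) {
    v <- xr[[s]]
    v <- v[is.finite(v) & v > floor]
    if (length(v) == 0L) return(NA_real_)
    v <- sort(v)
    k <- floor(trim * length(v))
    if (2L * k < length(v)) v <- v[(k + 1L):(length(v) - k)]
    median(v)
  })
}

# Exact 1-D 2-medoid partition: exhaustive over all medoid pairs, minimizing
# total absolute deviation to the nearer medoid. Returns assignment (1/2 by
# sorted medoid value), the medoids, and the optimal cost.
two_medoids_1d <- function(x) {
  n <- length(x)
  stopifnot(n >= 2L)
  best <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m <- c(x[i], x[j])
      d <- cbind(abs(x - m[1L]), abs(x - m[2L]))
      cost <- sum(pmin(d[, 1L], d[, 2L]))
      if (is.null(best) || cost < best$cost - 1e-12) {
        assign <- ifelse(d[, 1L] <= d[, 2L], 1L, 2L)
        best <- list(medoids = m, assign = assign, cost = cost)
      }
    }
  }
  if (best$medoids[1L] > best$medoids[2L]) {
    best$medoids <- rev(best$medoids)
    best$assign <- 3L - best$assign
  }
  best
}

#' Cluster samples by X-chromosome dosage
#'
#' Samples captured in one batch differ in X-chromosome fractional coverage by
#' sex: relative to a mixed-sex batch median, males (one X) sit about one
#' log2 unit below females. This step summarizes each sample's X-interval
#' ratios (median after trimming the `x_trim` highest and lowest fractions of
#' probes), then partitions the summaries around two medoids by exact
#' exhaustive search. The cluster with the lower medoid is predicted male.
#'
#' When the two medoids are separated by less than `x_min_separation` log2
#' units the batch is treated as single-sex: one cluster, all samples
#' `indeterminate`.
#'
#' @param log2_tbl Log2 ratio tibble (pre X correction).
#' @param config A [cnv_config()].
#' @return A tibble of class `sex_clusters` with columns `sample`,
#'   `x_summary`, `cluster`, `predicted_sex` and `shift` (the additive log2
#'   correction to apply to the sample's X intervals), carrying attributes
#'   `medoids`, `degenerate` and `skipped`.
#' @export
cluster_x_samples <- function(log2_tbl, config = cnv_config()) {
  samples <- sample_names(log2_tbl)
  empty <- tibble(sample = character(0), x_summary = numeric(0), cluster = integer(0),
                  predicted_sex = character(0), shift = numeric(0))
  if (!any(log2_tbl$is_x & !log2_tbl$masked)) {
    inform("no X-chromosome intervals in panel; X correction skipped")
    return(structure(empty, medoids = numeric(0), degenerate = NA,
                     skipped = TRUE, class = c("sex_clusters", class(empty))))
  }
  xs <- x_summaries(log2_tbl, trim = config$x_trim, floor = config$log2_floor)
  if (length(samples) < 2L || anyNA(xs)) {
    res <- tibble(sample = samples, x_summary = unname(xs), cluster = 1L,
                  predicted_sex = "indeterminate", shift = -median(xs, na.rm = TRUE))
    return(structure(res, medoids = median(xs, na.rm = TRUE), degenerate = TRUE,
                     skipped = FALSE, class = c("sex_clusters", class(res))))
  }
  fit <- two_medoids_1d(unname(xs))
  degenerate <- abs(diff(fit$medoids)) < config$x_min_separation
  if (degenerate) {
    shift <- -median(xs)
    res <- tibble(sample = samples, x_summary = unname(xs), cluster = 1L,
                  predicted_sex = "indeterminate", shift = shift)
    medoids <- median(xs)
  } else {
    cl_median <- vapply(1:2, function(k) median(xs[fit$assign == k]), numeric(1))
    res <- tibble(
      sample = samples,
      x_summary = unname(xs),
      cluster = fit$assign,
      predicted_sex = c("male", "female")[fit$assign],
      shift = -cl_median[fit$assign]
    )
    medoids <- fit$medoids
  }
  structure(res, medoids = medoids, degenerate = degenerate, skipped = FALSE,
            class = c("sex_clusters", class(res)))
}

#' Apply the X-chromosome sex correction
#'
#' Re-centers each sample's X-interval log2 ratios on zero by subtracting its
#' cluster's median X summary (equivalently, adding the per-sample `shift`
#' from [cluster_x_samples()]). Autosomal ratios are untouched. After
#' correction, both sexes' X ratios are expressed relative to the sample's own
#' expected X dosage, so X CNV calls read the same way as autosomal calls.
#'
#' @param log2_tbl Log2 ratio tibble.
#' @param clusters Result of [cluster_x_samples()] on the same matrix.
#' @return The corrected log2 ratio tibble.
#' @export
normalize_x <- function(log2_tbl, clusters) {
  if (isTRUE(attr(clusters, "skipped")) || nrow(clusters) == 0L) {
    return(log2_tbl)
  }
  out <- log2_tbl
  rows <- log2_tbl$is_x & !log2_tbl$masked
  for (k in seq_len(nrow(clusters))) {
    s <- clusters$sample[k]
    out[[s]][rows] <- log2_tbl[[s]][rows] + clusters$shift[k]
  }
  out
}

#' Full normalization of one batch
#'
#' Runs fractional coverage, batch-median log2 ratios, X-dosage clustering and
#' X correction in sequence.
#'
#' @param cov Coverage tibble.
#' @param config A [cnv_config()].
#' @return A list with `log2` (corrected ratios), `log2_pre_x` (ratios before
#'   X correction) and `sex` (the [cluster_x_samples()] result).
#' @export
normalize_coverage <- function(cov, config = cnv_config()) {
  fractions <- fractional_coverage(cov)
  pre <- batch_median_log2(fractions, config)
  sex <- cluster_x_samples(pre, config)
  list(log2 = normalize_x(pre, sex), log2_pre_x = pre, sex = sex)
}
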