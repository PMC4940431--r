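# Fixtures are built in code; no data files.

# Minimal interval tibble: n_auto autosomal intervals on chr1/chr2 plus n_x on
# chrX, constant width 100, labels GENEk_Exonj in groups of 4.
tiny_intervals <- function(n_auto = 16, n_x = 4) {
  n <- n_auto + n_x
  chrom <- c(rep(c("chr1", "chr2"), each = ceiling(n_auto / 2))[seq_len(n_auto)],
             rep("chrX", n_x))
  gene <- ceiling(seq_len(n) / 4)
  exon <- ((seq_len(n) - 1L) %% 4L) + 1L
  pos <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- as.integer(1000L + (pos - 1L) * 1000L)
  tibble::tibble(
    chrom = chrom, start = start, end = start + 99L,
    label = sprintf("GENE%d_Exon%d", gene, exon),
    rank = seq_len(n) - 1L, is_x = chrom == "chrX"
  )
}

# Deterministic coverage batch: identical baseline across samples (so all log2
# ratios are exactly 0) with optional per-sample multiplicative tweaks applied
# to specific ranks: tweaks = list(S2 = c(`3` = 0.5)) halves rank 3 in S2.
tiny_batch <- function(n_samples = 4, intervals = tiny_intervals(),
                       base = 1000, tweaks = list()) {
  n <- nrow(intervals)
  baseline <- base * (1 + (seq_len(n) %% 5))  # interval-specific efficiency
  cov <- intervals
  for (k in seq_len(n_samples)) {
    s <- paste0("S", k)
    v <- baseline
    tw <- tweaks[[s]]
    if (!is.null(tw)) {
      ranks <- as.integer(names(tw))
      v[match(ranks, intervals$rank)] <- v[match(ranks, intervals$rank)] * unname(tw)
    }
    cov[[s]] <- v
  }
  cov
}

# --- independent oracles -----------------------------------------------------

# Five-number summary by direct application of the hinge/fence definitions,
# written without boxplot.stats.
oracle_fns <- function(values, mult = 3) {
  v <- sort(values[is.finite(values)])
  n <- length(v)
  med <- if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
  half <- function(x) {
    m <- length(x)
    if (m %% 2 == 1) x[(m + 1) / 2] else mean(x[m / 2 + 0:1])
  }
  lower <- v[seq_len(ceiling(n / 2))]
  upper <- v[(floor(n / 2) + 1):n]
  q1 <- half(lower); q3 <- half(upper)
  iqr <- q3 - q1
  lw <- min(v[v >= q1 - mult * iqr])
  uw <- max(v[v <= q3 + mult * iqr])
  c(lower_whisker = lw, q1 = q1, median = med, q3 = q3, upper_whisker = uw)
}

# Brute-force CNV run enumerator: re-derives eligibility from the rule text
# and tests every contiguous (i, j) interval pair for being a maximal
# same-type run on one chromosome.
oracle_segments <- function(ratios, intervals, fns, config) {
  n <- length(ratios)
  gain_thr <- max(config$gain_log2, fns$upper_whisker)
  loss_thr <- min(config$loss_log2, fns$lower_whisker)
  ok <- !intervals$masked & is.finite(ratios) & ratios > config$log2_floor
  elig <- ifelse(ok & ratios > gain_thr, "gain",
                 ifelse(ok & ratios < loss_thr, "loss", "none"))
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      type <- elig[i]
      if (type == "none") break
      run <- i:j
      if (!all(elig[run] == type)) break
      if (!all(intervals$chrom[run] == intervals$chrom[i])) break
      left_max <- i == 1 || elig[i - 1] != type || intervals$chrom[i - 1] != intervals$chrom[i]
      right_max <- j == n || elig[j + 1] != type || intervals$chrom[j + 1] != intervals$chrom[j]
      if (left_max && right_max) {
        min_probes <- if (type == "gain") config$min_probes_gain else config$min_probes_loss
        if (length(run) >= min_probes) {
          out[[length(out) + 1L]] <- tibble::tibble(
            type = type,
            first_rank = intervals$rank[i], last_rank = intervals$rank[j],
            median_log2 = stats::median(ratios[run])
          )
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(type = character(0), first_rank = integer(0),
                          last_rank = integer(0), median_log2 = numeric(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), first_rank)
}

# Brute-force optimal 2-medoid cost: enumerate every bipartition of the
# points, pick the best in-group medoid for each side, minimize total
# absolute deviation. Returns the optimal cost.
oracle_two_medoid_cost <- function(x) {
  n <- length(x)
  group_cost <- function(idx) {
    if (length(idx) == 0L) return(Inf)
    min(vapply(idx, function(m) sum(abs(x[idx] - x[m])), numeric(1)))
  }
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g1 <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    g2 <- setdiff(seq_len(n), g1)
    best <- min(best, group_cost(g1) + group_cost(g2))
  }
  best
}

# cost of a given assignment under best in-group medoids
assignment_cost <- function(x, assign) {
  sum(vapply(unique(assign), function(k) {
    idx <- which(assign == k)
    min(vapply(idx, function(m) sum(abs(x[idx] - x[m])), numeric(1)))
  }, numeric(1)))
}

# random log2 vector with occasional masked intervals, for oracle sweeps
random_ratio_case <- function(n = 50, two_chroms = TRUE) {
  chrom <- if (two_chroms) rep(c("chr1", "chr2"), length.out = n) |> sort() else rep("chr1", n)
  intervals <- tibble::tibble(
    chrom = chrom, start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 99L,
    label = sprintf("G%d_Exon1", seq_len(n)), rank = seq_len(n) - 1L,
    is_x = FALSE, masked = stats::runif(n) < 0.05
  )
  ratios <- stats::rnorm(n, 0, 0.4)
  # sprinkle strong events so gains/losses actually occur
  k <- sample(n, 4)
  ratios[k] <- sample(c(-1.6, -1, 0.9, 1.4), 4, replace = TRUE)
  ratios[intervals$masked] <- NA_real_
  list(intervals = intervals, ratios = ratios)
}
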