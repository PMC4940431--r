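#' Configuration for a simulated capture batch
#'
#' Describes a synthetic multiplexed hybrid-capture batch: a panel of exon
#' targets with interval-specific capture efficiency, per-cell multiplicative
#' noise, X-chromosome dosage by sex, optional injected CNVs, occasional
#' high-dispersion (QC-failing) samples and a small fraction of erratic
#' baits. Defaults mirror a realistic clinical panel batch: 8 samples
#' multiplexed per capture pool, a panel of 1,016 exons, and a mean average
#' target coverage of 724x.
#'
#' Noise is multiplicative log-normal on the log2 scale: an observed total is
#' the expected total times `2^N(0, noise_sd)`. At clinical panel depths,
#' counting noise is dominated by capture-efficiency variation, so no Poisson
#' layer is applied by default (`poisson = TRUE` adds one).
#'
#' @param n_samples Number of samples in the batch.
#' @param n_intervals Number of target intervals (exons) on the panel.
#' @param x_fraction Fraction of intervals on the X chromosome.
#' @param sexes Per-sample sex labels (`"male"`/`"female"`); recycled default
#'   alternates to give a mixed-sex batch.
#' @param depth_mean Mean average coverage depth per interval (reads-bases per
#'   base).
#' @param bait_efficiency_sd SD (natural-log scale) of the per-interval
#'   log-normal capture efficiency.
#' @param noise_sd Per-cell noise SD in log2 units.
#' @param bad_bait_fraction Fraction of intervals given `bad_bait_factor`-fold
#'   inflated noise SD.
#' @param bad_bait_factor Noise inflation for bad baits.
#' @param noisy_sample_ids Sample names whose noise SD is multiplied by
#'   `dispersion_factor` (models QC-failing libraries).
#' @param dispersion_factor Noise inflation for noisy samples.
#' @param cnv_spec Tibble (or data.frame) of injected CNVs with columns
#'   `sample`, `first_rank`, `last_rank`, `cn` (true absolute copy number on
#'   the autosomal diploid scale).
#' @param poisson Add a Poisson read-sampling layer on top of the log-normal
#'   noise.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 8,
                       n_intervals = 1016,
                       x_fraction = 0.05,
                       sexes = NULL,
                       depth_mean = 724,
                       bait_efficiency_sd = 0.5,
                       noise_sd = 0.1,
                       bad_bait_fraction = 0.01,
                       bad_bait_factor = 4,
                       noisy_sample_ids = character(0),
                       dispersion_factor = 6,
                       cnv_spec = NULL,
                       poisson = FALSE,
                       seed = 1L) {
  stopifnot(n_samples >= 1, n_intervals >= 1,
            x_fraction >= 0, x_fraction <= 1,
            bad_bait_fraction >= 0, bad_bait_fraction <= 1,
            depth_mean > 0, noise_sd >= 0, bait_efficiency_sd >= 0)
  if (is.null(sexes)) {
    sexes <- rep(c("female", "male"), length.out = n_samples)
  }
  stopifnot(length(sexes) == n_samples, all(sexes %in% c("male", "female")))
  structure(
    list(
      n_samples = n_samples, n_intervals = n_intervals, x_fraction = x_fraction,
      sexes = sexes, depth_mean = depth_mean,
      bait_efficiency_sd = bait_efficiency_sd, noise_sd = noise_sd,
      bad_bait_fraction = bad_bait_fraction, bad_bait_factor = bad_bait_factor,
      noisy_sample_ids = noisy_sample_ids, dispersion_factor = dispersion_factor,
      cnv_spec = cnv_spec, poisson = poisson, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# synthetic panel: genes of ~8 exons spread over autosomes, X block at the end
sim_intervals <- function(cfg) {
  n <- cfg$n_intervals
  n_x <- round(cfg$x_fraction * n)
  n_auto <- n - n_x
  chroms <- character(n)
  if (n_auto > 0) {
    auto_chroms <- paste0("chr", 1:22)
    chroms[seq_len(n_auto)] <- auto_chroms[ceiling(seq_len(n_auto) / ceiling(n_auto / 22))]
  }
  if (n_x > 0) chroms[(n_auto + 1):n] <- "chrX"
  gene_idx <- ceiling(seq_len(n) / 8)
  exon_idx <- ((seq_len(n) - 1L) %% 8L) + 1L
  # restart exon numbering when the chromosome changes mid-gene
  label <- sprintf("%s_G%03d_Exon%d", sub("^chr", "", chroms), gene_idx, exon_idx)
  pos_in_chrom <- stats::ave(seq_len(n), chroms, FUN = seq_along)
  start <- as.integer(1e6 + (pos_in_chrom - 1L) * 5000L)
  width <- as.integer(120 + ((seq_len(n) * 37L) %% 180L))
  tibble(
    chrom = chroms, start = start, end = start + width - 1L,
    label = label, rank = seq_len(n) - 1L, is_x = chroms == "chrX"
  )
}

#' Simulate a multiplexed capture batch
#'
#' Generates a synthetic batch under `cfg`: per-interval capture efficiency
#' `e_i ~ lognormal(0, bait_efficiency_sd)`, expected total coverage
#' `depth_mean * width_i * e_i * (cn/2) * dosage` where `dosage` halves X
#' intervals for males, and observed totals
#' `round(expected * 2^N(0, sd))` with per-cell noise SD inflated for noisy
#' samples and bad baits. When `out_dir` is given, writes a GATK-dialect
#' interval list, one `sample_interval_summary` CSV per sample, and a BED-like
#' (0-based half-open) ground-truth TSV.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory for the on-disk batch.
#' @return A list with `coverage` (coverage tibble ready for the pipeline),
#'   `intervals`, `truth` (tibble: `sample`, `chrom`, `first_rank`,
#'   `last_rank`, `cn`, `type`), `sexes`, and when `out_dir` was given,
#'   `paths` (interval list, summary files, truth file).
#' @export
simulate_batch <- function(cfg = sim_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  intervals <- sim_intervals(cfg)
  n <- cfg$n_intervals
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  names(cfg$sexes) <- samples

  if (!is.null(cfg$cnv_spec)) {
    bad <- setdiff(unique(cfg$cnv_spec$sample), samples)
    if (length(bad) > 0L) {
      abort(sprintf("cnv_spec references unknown sample(s): %s", paste(bad, collapse = ", ")),
            class = "panelcnv_config_error")
    }
    if (any(cfg$cnv_spec$first_rank < 0 | cfg$cnv_spec$last_rank >= n |
            cfg$cnv_spec$first_rank > cfg$cnv_spec$last_rank)) {
      abort("cnv_spec rank range outside panel", class = "panelcnv_config_error")
    }
  }

  efficiency <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$bait_efficiency_sd)
  bad_baits <- stats::runif(n) < cfg$bad_bait_fraction

  cn <- matrix(2, nrow = n, ncol = cfg$n_samples, dimnames = list(NULL, samples))
  if (!is.null(cfg$cnv_spec)) {
    for (k in seq_len(nrow(cfg$cnv_spec))) {
      rows <- (cfg$cnv_spec$first_rank[k]:cfg$cnv_spec$last_rank[k]) + 1L
      cn[rows, cfg$cnv_spec$sample[k]] <- cfg$cnv_spec$cn[k]
    }
  }

  width <- intervals$end - intervals$start + 1L
  cov <- intervals
  for (j in seq_along(samples)) {
    s <- samples[j]
    dosage <- ifelse(intervals$is_x & cfg$sexes[s] == "male", 0.5, 1)
    expected <- cfg$depth_mean * width * efficiency * (cn[, j] / 2) * dosage
    sd_cell <- cfg$noise_sd *
      (if (s %in% cfg$noisy_sample_ids) cfg$dispersion_factor else 1) *
      ifelse(bad_baits, cfg$bad_bait_factor, 1)
    obs <- expected * 2^stats::rnorm(n, 0, sd_cell)
    if (cfg$poisson) obs <- stats::rpois(n, obs)
    cov[[s]] <- round(obs)
  }

  truth <- sim_truth(cfg, intervals, samples)
  out <- list(coverage = cov, intervals = intervals, truth = truth, sexes = cfg$sexes)
  if (!is.null(out_dir)) {
    out$paths <- write_sim_batch(out, out_dir)
  }
  out
}

sim_truth <- function(cfg, intervals, samples) {
  if (is.null(cfg$cnv_spec) || nrow(cfg$cnv_spec) == 0L) {
    return(tibble(sample = character(0), chrom = character(0),
                  first_rank = integer(0), last_rank = integer(0),
                  cn = numeric(0), type = character(0)))
  }
  spec <- as_tibble(cfg$cnv_spec)
  tibble(
    sample = spec$sample,
    chrom = intervals$chrom[spec$first_rank + 1L],
    first_rank = as.integer(spec$first_rank),
    last_rank = as.integer(spec$last_rank),
    cn = spec$cn,
    type = ifelse(spec$cn > 2, "gain", "loss")
  )
}

# GATK-dialect interval summary files + interval list + BED-like truth
write_sim_batch <- function(batch, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  iv <- batch$intervals
  list_path <- file.path(out_dir, "targets.interval_list.txt")
  writeLines(paste0(target_key(iv$chrom, iv$start, iv$end), "\t", iv$label), list_path)

  cov_dir <- file.path(out_dir, "coverage")
  dir.create(cov_dir, showWarnings = FALSE)
  width <- iv$end - iv$start + 1L
  sample_files <- purrr::map_chr(sample_names(batch$coverage), function(s) {
    totals <- batch$coverage[[s]]
    tab <- tibble(
      Target = target_key(iv$chrom, iv$start, iv$end),
      total_coverage = totals,
      average_coverage = round(totals / width, 2)
    )
    tab[[paste0(s, "_total_cvg")]] <- totals
    tab[[paste0(s, "_mean_cvg")]] <- round(totals / width, 2)
    p <- file.path(cov_dir, paste0(s, ".sample_interval_summary"))
    readr::write_csv(tab, p, progress = FALSE)
    p
  })

  truth_path <- file.path(out_dir, "truth.bed.tsv")
  truth <- batch$truth
  truth_bed <- tibble(
    chrom = truth$chrom,
    start0 = iv$start[truth$first_rank + 1L] - 1L,   # 0-based half-open
    end0 = iv$end[truth$last_rank + 1L],
    sample = truth$sample,
    cn = truth$cn,
    type = truth$type,
    first_rank = truth$first_rank,
    last_rank = truth$last_rank
  )
  readr::write_tsv(truth_bed, truth_path, progress = FALSE)
  list(interval_list = list_path, coverage_dir = cov_dir,
       coverage_files = sample_files, truth = truth_path)
}

#' Canned simulation scenarios
#'
#' Returns a ready-made batch (or cohort) exercising a named analysis path:
#' \describe{
#'   \item{`clean`}{8 mixed-sex samples, no CNVs; QC converges in one
#'     iteration.}
#'   \item{`one_failing_sample`}{as `clean` plus one high-dispersion sample
#'     that fails whisker QC at iteration 1.}
#'   \item{`mixed_sex`}{4 males / 4 females with one heterozygous deletion and
#'     one duplication injected.}
#'   \item{`single_sex`}{all-female batch; X clustering is degenerate.}
#'   \item{`recurrent_artifact`}{a 200-case cohort (25 batches of 8) where 3
#'     designated cases carry an identical single-interval deletion, above the
#'     1\% recurrence threshold.}
#' }
#'
#' @param scenario Scenario name.
#' @param seed Integer seed.
#' @param n_intervals Panel size (default 400 keeps scenario runs fast while
#'   preserving panel-like statistics).
#' @param out_dir Optional directory passed through to [simulate_batch()]
#'   (single-batch scenarios only).
#' @return For single-batch scenarios, a [simulate_batch()] result (with the
#'   config as attribute `config`). For `recurrent_artifact`, a list of batch
#'   results plus `n_cases` and `planted` (the planted call's coordinates).
#' @export
make_paperlike_batch <- function(scenario = c("clean", "one_failing_sample", "mixed_sex",
                                              "single_sex", "recurrent_artifact"),
                                 seed = 1L, n_intervals = 400, out_dir = NULL) {
  scenario <- match.arg(scenario)
  base <- function(...) sim_config(n_intervals = n_intervals, seed = seed, ...)
  if (scenario == "clean") {
    cfg <- base()
  } else if (scenario == "one_failing_sample") {
    cfg <- base(noisy_sample_ids = "S05")
  } else if (scenario == "mixed_sex") {
    del_start <- as.integer(round(n_intervals * 0.1))
    dup_start <- as.integer(round(n_intervals * 0.5))
    cfg <- base(
      sexes = rep(c("male", "female"), each = 4),
      cnv_spec = tibble(sample = c("S02", "S07"),
                        first_rank = c(del_start, dup_start),
                        last_rank = c(del_start + 4L, dup_start + 3L),
                        cn = c(1, 3))
    )
  } else if (scenario == "single_sex") {
    cfg <- base(sexes = rep("female", 8))
  } else {
    n_batches <- 25L
    planted_cases <- c("S03", "S11", "S20")  # case ids within the cohort
    batches <- purrr::map(seq_len(n_batches), function(b) {
      first <- (b - 1L) * 8L
      case_ids <- sprintf("S%02d", first + 1:8)       # cohort-wide case ids
      local_ids <- sprintf("S%02d", 1:8)              # within-batch ids
      carriers <- intersect(case_ids, planted_cases)
      spec <- if (length(carriers) > 0L) {
        tibble(sample = local_ids[match(carriers, case_ids)],
               first_rank = 25L, last_rank = 25L, cn = 1)
      } else NULL
      cfg_b <- sim_config(n_intervals = n_intervals, seed = seed + b,
                          cnv_spec = spec)
      batch <- simulate_batch(cfg_b)
      rename_map <- setNames(case_ids, local_ids)
      names(batch$coverage)[match(local_ids, names(batch$coverage))] <- case_ids
      names(batch$sexes) <- case_ids
      if (nrow(batch$truth) > 0L) {
        batch$truth$sample <- unname(rename_map[batch$truth$sample])
      }
      batch
    })
    return(list(batches = batches, n_cases = n_batches * 8L,
                planted = list(first_rank = 25L, last_rank = 25L, type = "loss",
                               cases = planted_cases)))
  }
  res <- simulate_batch(cfg, out_dir = out_dir)
  attr(res, "config") <- cfg
  res
}
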