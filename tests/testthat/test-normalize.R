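test_that("fractional coverage normalizes each sample to sum 1 and is scale invariant", {
  iv <- tiny_intervals(3, 0)
  cov <- iv
  cov$S1 <- c(100, 300, 600)
  cov$S2 <- c(100, 300, 600) * 7.3   # rescaled library
  fr <- fractional_coverage(cov)
  expect_equal(fr$S1, c(0.1, 0.3, 0.6))
  expect_equal(fr$S2, fr$S1, tolerance = 1e-12)
  expect_equal(sum(fr$S1), 1, tolerance = 1e-12)

  cov$S3 <- c(0, 0, 0)
  expect_error(fractional_coverage(cov), "S3", class = "panelcnv_degenerate_sample_error")
})

test_that("batch-median log2 ratios hit the copy-number landmarks", {
  iv <- tiny_intervals(4, 0)
  fr <- iv
  # per-interval medians are 0.25 for every interval
  fr$S1 <- c(0.25, 0.375, 0.125, 0.25)   # 1x, 1.5x, 0.5x, 1x the median
  fr$S2 <- c(0.25, 0.25, 0.25, 0.25)
  fr$S3 <- c(0.25, 0.25, 0.25, 0.25)
  fr$S4 <- c(0.25, 0.20, 0.30, 0.25)
  lr <- batch_median_log2(fr)
  expect_equal(lr$S1[1], 0)
  expect_equal(lr$S1[2], log2(3 / 2))   # single-copy gain, ~0.585
  expect_equal(lr$S1[3], -1)            # single-copy loss
  expect_false(any(lr$masked))
})

test_that("batches below three samples are refused", {
  iv <- tiny_intervals(4, 0)
  fr <- iv; fr$S1 <- rep(0.25, 4); fr$S2 <- rep(0.25, 4)
  expect_error(batch_median_log2(fr), class = "panelcnv_batch_size_error")
})

test_that("dead baits are masked and zero fractions floored", {
  iv <- tiny_intervals(4, 0)
  fr <- iv
  fr$S1 <- c(0.5, 0, 0.25, 0.25)
  fr$S2 <- c(0.5, 0, 0.25, 0.25)
  fr$S3 <- c(0.5, 0, 0, 0.5)
  lr <- batch_median_log2(fr)
  expect_equal(lr$masked, c(FALSE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(lr$S1[lr$masked])))
  expect_equal(lr$S3[3], -10)  # zero at a live bait floors, not -Inf
})

test_that("before X correction every unmasked interval has median fold change 1", {
  set.seed(42)
  for (rep in 1:5) {
    iv <- tiny_intervals(12, 4)
    cov <- iv
    for (s in paste0("S", 1:6)) cov[[s]] <- stats::rlnorm(16, log(1000), 0.4)
    lr <- batch_median_log2(fractional_coverage(cov))
    fold_med <- apply(sample_matrix(lr), 1, function(r) stats::median(2^r))
    expect_equal(fold_med[!lr$masked], rep(1, sum(!lr$masked)), tolerance = 1e-9)
  }
})

test_that("log2 ratios are invariant to rescaling one sample's raw totals", {
  sim <- simulate_batch(sim_config(n_samples = 5, n_intervals = 60, seed = 4))
  cov2 <- sim$coverage
  cov2$S03 <- cov2$S03 * 13
  lr1 <- batch_median_log2(fractional_coverage(sim$coverage))
  lr2 <- batch_median_log2(fractional_coverage(cov2))
  expect_equal(lr1$S03, lr2$S03, tolerance = 1e-12)
})

test_that("two-medoid X clustering matches the worked partition and labels sexes", {
  # X summaries engineered through the matrix: 2 male-like, 2 female-like
  iv <- tiny_intervals(8, 8)
  lr <- iv
  lr$masked <- FALSE
  x_rows <- iv$is_x
  mk <- function(x_level) c(rep(0, 8), rep(x_level, 8))
  lr$A <- mk(-0.97); lr$B <- mk(-1.02); lr$C <- mk(0.01); lr$D <- mk(0.03)
  cl <- cluster_x_samples(lr)
  expect_equal(cl$predicted_sex, c("male", "male", "female", "female"))
  expect_equal(sort(unique(cl$cluster[cl$predicted_sex == "male"])), 1L)
  expect_equal(cl$x_summary, c(-0.97, -1.02, 0.01, 0.03))
  # shift is the negative of the cluster median
  expect_equal(cl$shift[1:2], rep(-median(c(-0.97, -1.02)), 2))
  expect_equal(unique(cl$shift[3:4]), -median(c(0.01, 0.03)))
})

test_that("near-identical X summaries give a degenerate single cluster", {
  iv <- tiny_intervals(8, 8)
  lr <- iv; lr$masked <- FALSE
  mk <- function(x_level) c(rep(0, 8), rep(x_level, 8))
  lr$A <- mk(0.00); lr$B <- mk(0.01); lr$C <- mk(0.02); lr$D <- mk(0.03)
  cl <- cluster_x_samples(lr)
  expect_true(attr(cl, "degenerate"))
  expect_equal(unique(cl$predicted_sex), "indeterminate")
  expect_equal(unique(cl$cluster), 1L)
})

test_that("a two-sample batch splits into its own medoids", {
  iv <- tiny_intervals(8, 8)
  lr <- iv; lr$masked <- FALSE
  mk <- function(x_level) c(rep(0, 8), rep(x_level, 8))
  lr$M <- mk(-1.0); lr$F <- mk(0.0)
  cl <- cluster_x_samples(lr)
  expect_equal(cl$predicted_sex, c("male", "female"))
})

test_that("exhaustive medoid-pair search attains the brute-force optimal cost", {
  set.seed(7)
  for (n in c(3, 5, 8)) {
    for (rep in 1:10) {
      x <- c(stats::rnorm(ceiling(n / 2), -1, 0.1), stats::rnorm(floor(n / 2), 0, 0.1))
      fit <- panelcnv:::two_medoids_1d(x)
      expect_equal(assignment_cost(x, fit$assign), oracle_two_medoid_cost(x),
                   tolerance = 1e-9)
    }
  }
})

test_that("the exhaustive 2-medoid search agrees with PAM on separated sexes", {
  set.seed(19)
  for (rep in 1:10) {
    n_m <- sample(2:4, 1); n_f <- sample(2:4, 1)
    x <- c(stats::rnorm(n_m, -1, 0.05), stats::rnorm(n_f, 0, 0.05))
    fit <- panelcnv:::two_medoids_1d(x)
    pam <- cluster::pam(matrix(x, ncol = 1), k = 2, metric = "manhattan")
    # same partition (cluster labels may be swapped)
    same <- identical(fit$assign, as.integer(pam$clustering)) ||
      identical(3L - fit$assign, as.integer(pam$clustering))
    expect_true(same)
    # medoid identity can tie inside even-sized clusters; costs must match
    expect_equal(assignment_cost(x, fit$assign),
                 assignment_cost(x, as.integer(pam$clustering)))
  }
})

test_that("X correction recenters each cluster on zero and leaves autosomes alone", {
  sim <- simulate_batch(sim_config(
    n_samples = 8, n_intervals = 200, x_fraction = 0.2,
    sexes = rep(c("male", "female"), 4), seed = 21
  ))
  pre <- batch_median_log2(fractional_coverage(sim$coverage))
  cl <- cluster_x_samples(pre)
  post <- normalize_x(pre, cl)
  expect_false(attr(cl, "degenerate"))
  # per-cluster median of corrected X summaries is 0
  post_sum <- panelcnv:::x_summaries(post)
  for (k in unique(cl$cluster)) {
    expect_equal(median(post_sum[cl$cluster == k]), 0, tolerance = 1e-9)
  }
  auto <- !pre$is_x
  for (s in sample_names(pre)) {
    expect_identical(pre[[s]][auto], post[[s]][auto])
  }
})

test_that("panels without X intervals skip correction with a notice", {
  sim <- simulate_batch(sim_config(n_samples = 4, n_intervals = 40, x_fraction = 0, seed = 3))
  pre <- batch_median_log2(fractional_coverage(sim$coverage))
  expect_message(cl <- cluster_x_samples(pre), "skipped")
  expect_equal(nrow(cl), 0)
  expect_identical(normalize_x(pre, cl), pre)
})

test_that("an injected heterozygous deletion is recovered near -1 at realistic noise", {
  spec <- tibble::tibble(sample = "S03", first_rank = 20L, last_rank = 25L, cn = 1)
  sim <- simulate_batch(sim_config(n_samples = 8, n_intervals = 300, noise_sd = 0.1,
                                   cnv_spec = spec, seed = 17))
  norm <- normalize_coverage(sim$coverage)
  del <- norm$log2$S03[norm$log2$rank %in% 20:25]
  expect_equal(mean(del), -1, tolerance = 0.15)
})
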