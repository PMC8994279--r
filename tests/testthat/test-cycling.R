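test_that("replicates are relabelled onto a second day", {
  cfg <- simulation_config(n_genes = 5, seed = 3)
  tc <- simulate_diel_timecourse(cfg)  # 12,...,32 x 2 replicates
  split <- split_replicates_to_days(tc)
  expect_equal(sort(split$samples$time_h),
               sort(c(seq(12, 32, 4), seq(36, 56, 4))))
  expect_equal(nrow(split$samples), 12)
  expect_identical(split$expression, tc$expression)

  one <- simulate_diel_timecourse(cfg, times_h = 10, n_replicates = 2)
  expect_equal(sort(split_replicates_to_days(one)$samples$time_h),
               c(10, 34))

  # a second application finds no 2-replicate structure left
  expect_error(split_replicates_to_days(split), "time point|time\\(s\\)")
  three <- simulate_diel_timecourse(cfg, times_h = c(12, 16),
                                    n_replicates = 3)
  expect_error(split_replicates_to_days(three), "12")
})

test_that("a noiseless cosine is detected with the right period and phase", {
  truth <- make_truth(c(8, NA))
  cfg <- simulation_config(n_genes = 2, noise_sd_log2 = 0)
  tc <- split_replicates_to_days(simulate_diel_timecourse(cfg,
                                                          truth = truth))
  st <- test_cycling(tc)
  row <- st[st$gene_id == "g001", ]
  expect_lte(abs(row$period_h - 24), 0.5)
  expect_lt(abs(circular_diff(row$phase_h, 8)), 0.1)
  expect_lt(row$p_value, 1e-6)
  # the flat gene is reported as non-cycling
  expect_equal(unname(st$p_value[st$gene_id == "g002"]), 1)
  expect_equal(unname(st$amplitude[st$gene_id == "g002"]), 0)
})

test_that("grid period selection matches exhaustive SSE minimisation", {
  set.seed(21)
  cfg <- simulation_config(n_genes = 50, frac_cycling = 1,
                           noise_sd_log2 = 0.5, seed = 21)
  tc <- split_replicates_to_days(simulate_diel_timecourse(cfg))
  grid <- seq(20, 28, by = 0.5)
  st <- test_cycling(tc, period_grid = grid)

  t <- tc$samples$time_h
  Y <- tc$expression[, tc$samples$sample_id]
  for (g in rownames(Y)) {
    sse <- vapply(grid, function(T) {
      X <- cbind(1, cos(2 * pi * t / T), sin(2 * pi * t / T))
      sum(stats::lm.fit(X, Y[g, ])$residuals^2)
    }, numeric(1))
    expect_equal(st$period_h[st$gene_id == g], grid[which.min(sse)])
  }
})

test_that("BH adjustment preserves the p-value ordering", {
  set.seed(4)
  cfg <- simulation_config(n_genes = 200, frac_cycling = 0.5,
                           noise_sd_log2 = 0.6, seed = 4)
  st <- test_cycling(split_replicates_to_days(simulate_diel_timecourse(cfg)))
  expect_true(all(st$q_value >= st$p_value - 1e-12))
  # monotone: sorting by p equals sorting by q
  expect_equal(st$gene_id[order(st$p_value)],
               st$gene_id[order(st$q_value, st$p_value)])
})

test_that("true cycling genes are recovered with high power at SNR 2", {
  cfg <- simulation_config(n_genes = 2000, frac_cycling = 1,
                           amplitude_log2 = c(1, 1), noise_sd_log2 = 0.5,
                           seed = 31)
  truth <- simulate_gene_truth(cfg)
  tc <- split_replicates_to_days(simulate_diel_timecourse(cfg,
                                                          truth = truth))
  st <- test_cycling(tc)
  joined <- merge(truth, st, by = "gene_id")
  power <- mean(joined$q_value[joined$cycling] < 0.05)
  expect_gte(power, 0.95)
  # noiseless phase recovery is essentially exact
  cfg0 <- simulation_config(n_genes = 50, frac_cycling = 1,
                            noise_sd_log2 = 0, seed = 32)
  truth0 <- simulate_gene_truth(cfg0)
  st0 <- test_cycling(split_replicates_to_days(
    simulate_diel_timecourse(cfg0, truth = truth0)))
  err <- abs(circular_diff(st0$phase_h, truth0$phase_h))
  expect_lt(median(err), 0.1)
})

test_that("the filter cascade keeps exactly the compliant gene", {
  # six focal genes: q fail, period-low in A, period-high in B, amplitude
  # outlier, mean outlier, and one gene passing everything; background
  # genes define the amplitude/mean distributions but all fail the q cut
  n_bg <- 100
  set.seed(9)
  bg_amp <- rnorm(n_bg, 1, 0.2)
  bg_mean <- rnorm(n_bg, 6, 0.5)
  bg_id <- sprintf("bg%03d", seq_len(n_bg))
  focal_id <- sprintf("f%d", 1:6)

  amp_out <- 1 + 5 * sd(c(bg_amp, 1, 1, 1, 1, 1))     # far beyond 2.5 SD
  mean_out <- 6 + 5 * sd(c(bg_mean, 6, 6, 6, 6, 6))
  stats_b <- make_stats(
    gene_id = c(focal_id, bg_id),
    q_value = c(0.2, 0.01, 0.01, 0.01, 0.01, 0.01, rep(0.5, n_bg)),
    period_h = c(24, 24, 27, 24, 24, 24, rep(24, n_bg)),
    amplitude = c(1, 1, 1, amp_out, 1, 1, bg_amp),
    mean_expression = c(6, 6, 6, 6, mean_out, 6, bg_mean),
    phase_h = 10.2
  )
  stats_a <- stats_b
  stats_a$q_value <- c(rep(0.01, 6), rep(0.5, n_bg))
  stats_a$period_h <- c(24, 21, 24, 24, 24, 24, rep(24, n_bg))

  out <- filter_and_phase(stats_a, stats_b, phase_source = "b")
  expect_equal(nrow(out), 1)
  expect_equal(out$gene_id, "f6")
  expect_equal(out$phase, 10L)
})

test_that("phase bins follow the round-half-up and wrap conventions", {
  expect_equal(phase_to_bin(23.6), 0L)   # rounds to 24, wraps to 0
  expect_equal(phase_to_bin(0.4), 0L)
  expect_equal(phase_to_bin(11.5), 12L)  # .5 rounds up
  expect_equal(phase_to_bin(c(22.4, 23.49)), c(22L, 23L))
})

test_that("low-count transcripts are dropped before testing", {
  m <- matrix(c(0, 1, 2, 3,
                5, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("low", "ok"), paste0("s", 1:4)))
  kept <- filter_low_expressed(m, min_total = 10)
  expect_equal(rownames(kept), "ok")
})
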