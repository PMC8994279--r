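test_that("detrending removes polynomial drift", {
  t <- seq(0, 120, by = 0.5)
  traces <- tibble::tibble(
    seedling_id = "s1", time_h = t, position = 3 + 0.2 * t
  )
  out <- detrend_traces(traces)
  expect_true(all(abs(out$position) < 1e-9))

  # cosine survives linear detrending almost untouched
  cosine <- cos(2 * pi * (t - 4) / 25)
  traces2 <- tibble::tibble(seedling_id = "s1", time_h = t,
                            position = cosine + 1 + 0.05 * t)
  out2 <- detrend_traces(traces2)
  expect_gt(cor(out2$position, cosine), 0.99)

  # detrended traces always have mean zero
  set.seed(2)
  traces3 <- tibble::tibble(seedling_id = rep(c("a", "b"), each = 50),
                            time_h = rep(seq(0, 24.5, 0.5), 2),
                            position = rnorm(100))
  out3 <- detrend_traces(traces3, method = "cubic")
  means <- tapply(out3$position, out3$seedling_id, mean)
  expect_true(all(abs(means) < 1e-9))

  expect_error(detrend_traces(tibble::tibble(
    seedling_id = "x", time_h = 1:5, position = 1:5
  )), "fewer than 10")
})

test_that("a noiseless damped cosine is recovered precisely", {
  trace <- make_trace(tau = 26, phi = 6, amp = 1, lambda = 0.005)
  fit <- fit_rhythm(trace$time_h, trace$position)
  expect_lt(abs(fit$period_h - 26), 0.1)
  expect_lt(abs(circular_diff(fit$phase_ct_h, 6 * 24 / 26)), 0.1)
  expect_lt(fit$rae, 0.05)
  expect_lt(fit$err, 0.05)
  expect_true(fit$pass_qc)
  expect_equal(fit$damping, 0.005, tolerance = 0.002)
})

test_that("the fitted rhythm dominates a profiled grid search", {
  set.seed(15)
  trace <- make_trace(tau = 24.7, phi = 9, amp = 1, lambda = 0.004,
                      noise_sd = 0.2)
  fit <- fit_rhythm(trace$time_h, trace$position)
  t <- trace$time_h; y <- trace$position
  # oracle: for each (tau, lambda), amplitude and phase have a closed-form
  # least-squares solution via the damped cosine/sine pair
  taus <- seq(23, 27, by = 0.05)
  lams <- seq(0, 0.01, by = 0.001)
  best <- Inf
  for (lam in lams) {
    damp <- exp(-lam * t)
    for (tau in taus) {
      X <- cbind(damp * cos(2 * pi * t / tau),
                 damp * sin(2 * pi * t / tau))
      sse <- sum(stats::lm.fit(X, y)$residuals^2)
      if (sse < best) best <- sse
    }
  }
  fit_sse <- sum((y - fit$amplitude * exp(-fit$damping * t) *
                    cos(2 * pi * (t - fit$phase_h) / fit$period_h))^2)
  expect_lte(fit_sse, best * 1.001)
})

test_that("white-noise traces fail quality control", {
  set.seed(33)
  fails <- vapply(1:10, function(i) {
    trace <- make_trace(tau = 24, phi = 0, amp = 0, noise_sd = 1)
    fit <- fit_rhythm(trace$time_h, trace$position)
    !fit$pass_qc
  }, logical(1))
  expect_true(all(fails))
})

test_that("period estimates are invariant to amplitude scaling", {
  set.seed(44)
  trace <- make_trace(tau = 25, phi = 3, amp = 1, lambda = 0.003,
                      noise_sd = 0.1)
  f1 <- fit_rhythm(trace$time_h, trace$position)
  f2 <- fit_rhythm(trace$time_h, trace$position * 7)
  expect_equal(f1$period_h, f2$period_h, tolerance = 1e-6)
  expect_equal(f2$amplitude, 7 * f1$amplitude, tolerance = 1e-4)
  expect_equal(f1$err, f2$err, tolerance = 1e-6)
})

test_that("tightening the ERR threshold never enlarges the pass set", {
  set.seed(55)
  traces <- purrr::map_dfr(1:6, function(i) {
    tr <- make_trace(tau = runif(1, 23, 27), phi = runif(1, 0, 24),
                     amp = 1, noise_sd = runif(1, 0.1, 1.5))
    tr$seedling_id <- paste0("s", i)
    tr$genotype <- "MM"
    tr$experiment <- "e1"
    tr
  })
  est_loose <- fit_rhythms(traces, err_threshold = 0.6)
  est_strict <- fit_rhythms(traces, err_threshold = 0.3)
  expect_equal(est_loose$period_h, est_strict$period_h)
  pass_loose <- est_loose$seedling_id[est_loose$pass_qc]
  pass_strict <- est_strict$seedling_id[est_strict$pass_qc]
  expect_true(all(pass_strict %in% pass_loose))
})

test_that("relative phase is anchored to the reference genotype per batch", {
  est <- tibble::tibble(
    seedling_id = paste0("s", 1:8),
    genotype = c("MM", "MM", "EID1", "EID1", "MM", "MM", "EID1", "EID1"),
    experiment = rep(c("e1", "e2"), each = 4),
    phase_ct_h = c(4, 6, 7, 9, 10, 12, 15, 17)
  )
  rel <- relative_phase(est, "MM")
  # hand-computed: e1 MM mean 5, e2 MM mean 11
  expect_equal(rel$relative_phase_h,
               c(-1, 1, 2, 4, -1, 1, 4, 6))
  # reference seedlings average zero per batch
  mm <- rel[rel$genotype == "MM", ]
  expect_equal(as.numeric(tapply(mm$relative_phase_h, mm$experiment, mean)),
               c(0, 0))
  # adding a batch constant changes nothing
  est2 <- est
  est2$phase_ct_h[est2$experiment == "e1"] <-
    est2$phase_ct_h[est2$experiment == "e1"] + 5
  rel2 <- relative_phase(est2, "MM")
  expect_equal(rel2$relative_phase_h, rel$relative_phase_h)

  expect_error(relative_phase(est[est$genotype != "MM" |
                                    est$experiment != "e2", ], "MM"),
               "e2")
})

test_that("group comparison matches hand-computed one-way ANOVA", {
  set.seed(66)
  d <- tibble::tibble(
    genotype = rep(c("MM", "EID1", "LNK2"), each = 8),
    period_h = c(rnorm(8, 24, 0.1), rnorm(8, 26, 0.1), rnorm(8, 24.1, 0.1))
  )
  cmp <- group_compare(d, period_h, genotype)
  y <- d$period_h; g <- factor(d$genotype)
  grand <- mean(y)
  ss_b <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_w <- sum((y - ave(y, g))^2)
  f <- (ss_b / (nlevels(g) - 1)) / (ss_w / (length(y) - nlevels(g)))
  expect_equal(cmp$anova$statistic[1], f, tolerance = 1e-9)
  # well-separated group earns its own letter
  lt <- cmp$letters
  expect_false(lt$letter[lt$group == "EID1"] %in%
                 lt$letter[lt$group != "EID1"])

  # identical group means share a letter and give a tiny F
  d2 <- tibble::tibble(genotype = rep(c("A", "B"), each = 10),
                       period_h = rep(c(24.0, 24.4), 10))
  cmp2 <- group_compare(d2, period_h, genotype)
  expect_equal(length(unique(cmp2$letters$letter)), 1)
  expect_lt(cmp2$anova$statistic[1], 1e-9)

  expect_error(
    group_compare(tibble::tibble(g = c("A", "A", "B", "B"),
                                 v = c(1, 1, 2, 2)), v, g),
    "degenerate"
  )
})
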