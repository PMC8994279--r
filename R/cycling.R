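#' Relabel duplicate time points onto a second day
#'
#' Rhythm detection benefits from series spanning at least two full cycles.
#' When a diel time course was collected with exactly two replicates per
#' time point, the second replicate can be treated as a second consecutive
#' day by adding 24 h to its collection time, turning a 6-time-point
#' duplicate design into a single 12-sample series. Expression values are
#' untouched; only the sample times are relabelled.
#'
#' @param tc A `diel_timecourse` with exactly 2 replicates per time point.
#' @return A `diel_timecourse` with a single pseudo-replicate series.
#' @export
split_replicates_to_days <- function(tc) {
  stopifnot(inherits(tc, "diel_timecourse"))
  counts <- tc$samples |>
    dplyr::count(.data$time_h)
  bad <- counts$time_h[counts$n != 2]
  if (length(bad) > 0) {
    stop("expected exactly 2 replicates per time point; violated at time(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  samples <- tc$samples |>
    dplyr::group_by(.data$time_h) |>
    dplyr::mutate(.day2 = rank(.data$replicate, ties.method = "first") == 2) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      time_h = .data$time_h + 24 * .data$.day2,
      replicate = 1L
    ) |>
    dplyr::select(-".day2")
  tc$samples <- samples
  tc
}

#' Harmonic-regression test for ~24 h cycling transcripts
#'
#' For every gene, fits the first-harmonic regression
#' \eqn{y = m + a\cos(2\pi t/T) + b\sin(2\pi t/T)} at each candidate period
#' `T` on the grid and records the SSE-minimising period, with amplitude
#' \eqn{\sqrt{a^2+b^2}} and the acrophase of the winning fit. Significance
#' is an F-test of the harmonic terms against the intercept-only model.
#'
#' With `p_method = "fixed"` (the default) the F-test uses the harmonic fit
#' at `reference_period_h`, whose null distribution is exactly F(2, n-3)
#' under Gaussian noise, so the test is calibrated; `p_method = "best"`
#' scores the grid-selected fit instead, which is anticonservative because
#' the period is chosen to minimise the SSE. P-values are BH-adjusted across
#' genes.
#'
#' @param tc A `diel_timecourse` on a log scale (see [normalize_counts()]),
#'   typically after [split_replicates_to_days()].
#' @param period_grid Candidate periods in hours (default 20 to 28 h in
#'   0.5 h steps).
#' @param p_method `"fixed"` (calibrated F-test at `reference_period_h`) or
#'   `"best"` (F-test at the selected period).
#' @param reference_period_h Period used by the fixed-period test
#'   (default 24).
#' @return Tibble with one row per gene: `gene_id`, `p_value`, `q_value`,
#'   `period_h`, `phase_h`, `amplitude`, `mean_expression`. Constant genes
#'   get `p_value = 1` and `amplitude = 0`.
#' @export
test_cycling <- function(tc, period_grid = seq(20, 28, by = 0.5),
                         p_method = c("fixed", "best"),
                         reference_period_h = 24) {
  stopifnot(inherits(tc, "diel_timecourse"))
  p_method <- match.arg(p_method)
  if (!isTRUE(tc$log_scale)) {
    stop("`test_cycling()` expects log-scale expression; ",
         "normalize counts first", call. = FALSE)
  }
  t <- tc$samples$time_h
  n <- length(t)
  if (length(unique(t)) < 6) {
    stop("need at least 6 distinct time points (after day-splitting) ",
         "to test cycling", call. = FALSE)
  }
  if (n < 4) stop("fewer time points than model parameters", call. = FALSE)
  Y <- tc$expression[, tc$samples$sample_id, drop = FALSE]

  gene_means <- rowMeans(Y)
  sse0 <- rowSums((Y - gene_means)^2)

  fit_grid_period <- function(T) {
    X <- cbind(1, cos(2 * pi * t / T), sin(2 * pi * t / T))
    # coefficients for all genes at once: B = (X'X)^-1 X' y
    B <- solve(crossprod(X), crossprod(X, t(Y)))
    resid <- t(Y) - X %*% B
    list(sse = colSums(resid^2), a = B[2, ], b = B[3, ])
  }

  fits <- lapply(period_grid, fit_grid_period)
  sse_mat <- vapply(fits, `[[`, numeric(nrow(Y)), "sse")
  best <- max.col(-sse_mat, ties.method = "first")
  best_fit <- lapply(seq_len(nrow(Y)), function(i) {
    f <- fits[[best[i]]]
    c(a = unname(f$a[i]), b = unname(f$b[i]), sse = unname(f$sse[i]))
  })
  best_fit <- do.call(rbind, best_fit)
  best_T <- period_grid[best]
  amp <- sqrt(best_fit[, "a"]^2 + best_fit[, "b"]^2)
  phase <- (best_T / (2 * pi)) *
    atan2(best_fit[, "b"], best_fit[, "a"]) %% (2 * pi)
  phase <- phase %% best_T

  if (p_method == "fixed") {
    ref <- fit_grid_period(reference_period_h)
    sse1 <- ref$sse
  } else {
    sse1 <- best_fit[, "sse"]
  }
  df2 <- n - 3
  Fstat <- ((sse0 - sse1) / 2) / (sse1 / df2)
  p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)

  constant <- sse0 < .Machine$double.eps * n
  p[constant] <- 1
  amp[constant] <- 0
  phase[constant] <- NA_real_
  best_T[constant] <- NA_real_

  tibble::tibble(
    gene_id = rownames(Y),
    p_value = unname(p),
    q_value = unname(stats::p.adjust(p, method = "BH")),
    period_h = unname(best_T),
    phase_h = unname(phase),
    amplitude = unname(amp),
    mean_expression = unname(gene_means)
  )
}

#' Filter cycling candidates and assign integer phase bins
#'
#' Combines cycling statistics from two independent diel experiments (for
#' instance the recipient and donor species of an introgression panel) and
#' applies the filter cascade: BH-adjusted `q < q_cutoff` for the cycling
#' test, estimated period inside `period_range` in BOTH experiments, and
#' amplitude and mean expression each within `sd_multiplier` standard
#' deviations of their across-gene means (computed on the `phase_source`
#' experiment, on the scale of the input matrix). Surviving genes take
#' their phase estimate from the `phase_source` experiment, rounded
#' half-up to the nearest integer hour, with 24 subtracted when the rounded
#' value exceeds 23 so bins lie in `{0, ..., 23}`.
#'
#' @param stats_a,stats_b Per-gene tibbles from [test_cycling()] sharing a
#'   gene-id universe.
#' @param phase_source `"b"` (default) or `"a"`: which experiment provides
#'   phase, amplitude and mean-expression values for the surviving table
#'   and for the outlier filter.
#' @param q_cutoff Adjusted-p threshold (default 0.05).
#' @param q_both Require `q < q_cutoff` in both experiments (default TRUE,
#'   the conservative reading); if FALSE only `phase_source` is thresholded.
#' @param period_range Accepted period window in hours (default `c(22, 26)`).
#' @param sd_multiplier Outlier cut in SD units (default 2.5, two-sided).
#' @return Tibble with columns `gene_id`, `phase` (integer bin 0-23),
#'   `period_h`, `amplitude`, `mean_expression`, `q_value`. Empty when no
#'   gene survives.
#' @export
filter_and_phase <- function(stats_a, stats_b,
                             phase_source = c("b", "a"),
                             q_cutoff = 0.05, q_both = TRUE,
                             period_range = c(22, 26),
                             sd_multiplier = 2.5) {
  phase_source <- match.arg(phase_source)
  for (nm in c("gene_id", "q_value", "period_h", "phase_h", "amplitude",
               "mean_expression")) {
    if (!nm %in% names(stats_a) || !nm %in% names(stats_b)) {
      stop("cycling statistics tables must contain column `", nm, "`",
           call. = FALSE)
    }
  }
  src <- if (phase_source == "b") stats_b else stats_a
  oth <- if (phase_source == "b") stats_a else stats_b

  amp_ok <- abs(src$amplitude - mean(src$amplitude)) <=
    sd_multiplier * stats::sd(src$amplitude)
  mean_ok <- abs(src$mean_expression - mean(src$mean_expression)) <=
    sd_multiplier * stats::sd(src$mean_expression)
  src_keep <- src |>
    dplyr::mutate(.amp_ok = amp_ok, .mean_ok = mean_ok)

  joined <- dplyr::inner_join(
    src_keep, oth,
    by = "gene_id", suffix = c("_src", "_oth")
  )
  ok <- joined$q_value_src < q_cutoff &
    (!q_both | joined$q_value_oth < q_cutoff) &
    !is.na(joined$period_h_src) & !is.na(joined$period_h_oth) &
    joined$period_h_src >= period_range[1] &
    joined$period_h_src <= period_range[2] &
    joined$period_h_oth >= period_range[1] &
    joined$period_h_oth <= period_range[2] &
    joined$.amp_ok & joined$.mean_ok

  surv <- joined[ok, , drop = FALSE]
  tibble::tibble(
    gene_id = surv$gene_id,
    phase = phase_to_bin(surv$phase_h_src),
    period_h = surv$period_h_src,
    amplitude = surv$amplitude_src,
    mean_expression = surv$mean_expression_src,
    q_value = surv$q_value_src
  ) |>
    dplyr::arrange(.data$gene_id)
}

#' Map a continuous phase (hours) to an integer bin in 0-23
#'
#' Round-half-up to the nearest integer hour; 24 is subtracted when the
#' rounded value exceeds 23, so 23.6 h lands in bin 0.
#'
#' @param phase_h Continuous phase estimates in hours.
#' @return Integer vector of phase bins in `{0, ..., 23}`.
#' @export
phase_to_bin <- function(phase_h) {
  bin <- as.integer(floor(phase_h + 0.5))
  bin[!is.na(bin) & bin > 23L] <- bin[!is.na(bin) & bin > 23L] - 24L
  bin
}

#' Drop transcripts with too few reads to test
#'
#' Removes genes whose summed raw counts across all samples fall below
#' `min_total` (default 10), the standard low-expression prefilter applied
#' before cycling detection.
#'
#' @param counts Gene x sample count matrix.
#' @param min_total Minimum total reads across samples (default 10).
#' @return The filtered matrix.
#' @export
filter_low_expressed <- function(counts, min_total = 10) {
  stopifnot(is.matrix(counts))
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}
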