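#' Remove baseline drift from leaf-movement traces
#'
#' Fits and subtracts a least-squares polynomial trend (degree 1 for
#' `"linear"`, 3 for `"cubic"`) per seedling, leaving mean-zero residuals
#' ready for rhythm fitting. Free-running leaf traces typically drift as
#' the seedling grows; the drift is not part of the circadian signal.
#'
#' @param traces Tibble with columns `seedling_id`, `time_h`, `position`
#'   (plus any metadata, preserved). Each seedling needs >= 10 points.
#' @param method `"linear"` (default) or `"cubic"`.
#' @return The input tibble with `position` replaced by detrended values.
#' @export
detrend_traces <- function(traces, method = c("linear", "cubic")) {
  method <- match.arg(method)
  degree <- if (method == "linear") 1 else 3
  need <- c("seedling_id", "time_h", "position")
  if (!all(need %in% names(traces))) {
    stop("`traces` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  traces |>
    dplyr::group_by(.data$seedling_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 10) {
        stop("seedling ", key$seedling_id, " has fewer than 10 points",
             call. = FALSE)
      }
      fit <- stats::lm(position ~ stats::poly(time_h, degree), data = df)
      df$position <- stats::residuals(fit)
      df
    }) |>
    dplyr::ungroup()
}

#' Fit a damped cosine to one free-running trace
#'
#' Nonlinear least squares of
#' \eqn{y = A e^{-\lambda t} \cos(2\pi (t-\phi)/\tau)} on a detrended
#' position series. The period \eqn{\tau} is initialised at the peak of a
#' least-squares periodogram (harmonic-regression \eqn{R^2} over a period
#' grid) and the phase from the best grid cosine; when the periodogram
#' peak falls outside `period_bounds` the trace is flagged arrhythmic.
#'
#' Quality metrics: the relative amplitude error `rae = SE(A)/A`, and the
#' fit error `err` = residual SD / signal SD (clipped to `[0, 1]`). Traces
#' pass QC when `err < err_threshold` (default 0.4) and a period was found.
#' The phase is also expressed in circadian hours,
#' `phase_ct_h = (phi mod tau) * 24 / tau`, so that phases of seedlings
#' with different endogenous periods are comparable.
#'
#' @param time_h,position Numeric vectors: sampling times (hours) and
#'   detrended positions.
#' @param period_bounds Length-2 period search window within `[18, 34]` h
#'   (default `c(18, 34)`).
#' @param err_threshold QC cut on `err` (default 0.4).
#' @return Object of class `rhythm_fit`: list with `period_h`, `phase_h`,
#'   `phase_ct_h`, `amplitude`, `damping`, `rae`, `err`, `pass_qc`,
#'   `arrhythmic`, `n_points` and the data.
#' @export
fit_rhythm <- function(time_h, position, period_bounds = c(18, 34),
                       err_threshold = 0.4) {
  stopifnot(is.numeric(time_h), is.numeric(position),
            length(time_h) == length(position))
  if (length(period_bounds) != 2 || period_bounds[1] >= period_bounds[2] ||
      period_bounds[1] < 18 || period_bounds[2] > 34) {
    stop("`period_bounds` must be an increasing pair within [18, 34]",
         call. = FALSE)
  }
  o <- order(time_h)
  t <- time_h[o]
  y <- position[o]
  n <- length(y)
  if (n < 20 || diff(range(t)) < 2 * period_bounds[1]) {
    stop("trace too short: need >= 2 expected periods of data",
         call. = FALSE)
  }
  sig_sd <- stats::sd(y)
  if (sig_sd == 0) {
    return(new_rhythm_fit(NA, NA, NA, 0, NA, NA, 1, FALSE, TRUE, n, t, y,
                          err_threshold))
  }

  # least-squares periodogram over an extended grid; a peak landing outside
  # the requested bounds marks the dominant variation as non-circadian
  grid_lo <- max(16, period_bounds[1] - 4)
  grid_hi <- min(40, period_bounds[2] + 4)
  grid <- seq(grid_lo, grid_hi, by = 0.1)
  pgram <- vapply(grid, function(T) {
    f <- stats::lm(y ~ cos(2 * pi * t / T) + sin(2 * pi * t / T))
    summary(f)$r.squared
  }, numeric(1))
  peak_T <- grid[which.max(pgram)]
  if (peak_T < period_bounds[1] || peak_T > period_bounds[2]) {
    return(new_rhythm_fit(NA, NA, NA, NA, NA, NA, 1, FALSE, TRUE, n, t, y,
                          err_threshold))
  }

  start_fit <- fit_cosinor(t, y, period_h = peak_T)
  start <- list(A = max(start_fit$amplitude, 1e-6), lam = 0.001,
                tau = peak_T, phi = start_fit$acrophase_h)

  nls_fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-lam * t) * cos(2 * pi * (t - phi) / tau),
      start = start,
      lower = c(A = 0, lam = -0.05, tau = period_bounds[1],
                phi = start$phi - peak_T / 2),
      upper = c(A = Inf, lam = 0.5, tau = period_bounds[2],
                phi = start$phi + peak_T / 2),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )

  if (is.null(nls_fit)) {
    # fall back to the undamped cosinor at the periodogram peak
    A <- start_fit$amplitude
    rae <- start_fit$se[["amplitude"]] / A
    res_sd <- start_fit$residual_sd
    err <- min(1, res_sd / sig_sd)
    return(new_rhythm_fit(peak_T, start_fit$acrophase_h %% peak_T,
                          (start_fit$acrophase_h %% peak_T) * 24 / peak_T,
                          A, 0, rae, err, err < err_threshold, FALSE,
                          n, t, y, err_threshold))
  }

  cf <- summary(nls_fit)$coefficients
  A <- cf["A", "Estimate"]
  lam <- cf["lam", "Estimate"]
  tau <- cf["tau", "Estimate"]
  phi <- cf["phi", "Estimate"] %% tau
  rae <- if (A > 0) cf["A", "Std. Error"] / A else Inf
  err <- min(1, stats::sd(stats::residuals(nls_fit)) / sig_sd)
  new_rhythm_fit(tau, phi, phi * 24 / tau, A, lam, rae, err,
                 err < err_threshold, FALSE, n, t, y, err_threshold)
}

new_rhythm_fit <- function(period_h, phase_h, phase_ct_h, amplitude,
                           damping, rae, err, pass_qc, arrhythmic, n, t, y,
                           err_threshold) {
  structure(
    list(
      period_h = period_h, phase_h = phase_h, phase_ct_h = phase_ct_h,
      amplitude = amplitude, damping = damping, rae = rae, err = err,
      pass_qc = pass_qc && !arrhythmic, arrhythmic = arrhythmic,
      n_points = n, err_threshold = err_threshold,
      data = tibble::tibble(time_h = t, position = y)
    ),
    class = "rhythm_fit"
  )
}

#' @exportS3Method base::print
print.rhythm_fit <- function(x, ...) {
  if (x$arrhythmic) {
    cat("Rhythm fit: arrhythmic (no circadian periodogram peak)\n")
  } else {
    cat(sprintf(
      "Rhythm fit: period %.2f h, phase %.2f h (CT %.2f), amplitude %.3g\n",
      x$period_h, x$phase_h, x$phase_ct_h, x$amplitude))
    cat(sprintf("  RAE %.3f, ERR %.3f (QC %s at ERR < %.2f)\n",
                x$rae, x$err, if (x$pass_qc) "pass" else "fail",
                x$err_threshold))
  }
  invisible(x)
}

#' Tidy a rhythm fit
#' @param x A `rhythm_fit`.
#' @param ... Unused.
#' @export
tidy.rhythm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("period_h", "phase_h", "phase_ct_h", "amplitude", "damping"),
    estimate = c(x$period_h, x$phase_h, x$phase_ct_h, x$amplitude,
                 x$damping)
  )
}

#' Glance at a rhythm fit
#' @param x A `rhythm_fit`.
#' @param ... Unused.
#' @export
glance.rhythm_fit <- function(x, ...) {
  tibble::tibble(
    rae = x$rae, err = x$err, pass_qc = x$pass_qc,
    arrhythmic = x$arrhythmic, nobs = x$n_points
  )
}

#' Fit rhythms for every seedling in a trace table
#'
#' Applies [fit_rhythm()] per seedling and returns one row of estimates per
#' trace, carrying genotype and experiment labels along.
#'
#' @param traces Tibble with columns `seedling_id`, `genotype`,
#'   `experiment`, `time_h`, `position` (detrended; see
#'   [detrend_traces()]).
#' @inheritParams fit_rhythm
#' @return Tibble with per-seedling `period_h`, `phase_h`, `phase_ct_h`,
#'   `amplitude`, `damping`, `rae`, `err`, `pass_qc`, `arrhythmic`.
#' @export
fit_rhythms <- function(traces, period_bounds = c(18, 34),
                        err_threshold = 0.4) {
  need <- c("seedling_id", "genotype", "experiment", "time_h", "position")
  if (!all(need %in% names(traces))) {
    stop("`traces` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  traces |>
    dplyr::group_by(.data$seedling_id, .data$genotype, .data$experiment) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_rhythm(df$time_h, df$position, period_bounds, err_threshold)
      tibble::tibble(
        period_h = f$period_h, phase_h = f$phase_h,
        phase_ct_h = f$phase_ct_h, amplitude = f$amplitude,
        damping = f$damping, rae = f$rae, err = f$err,
        pass_qc = f$pass_qc, arrhythmic = f$arrhythmic
      )
    }) |>
    dplyr::ungroup()
}

#' Phase relative to a reference genotype, per experiment
#'
#' Circadian phases are only comparable within an experiment batch, so the
#' reference genotype's mean circadian-time phase is subtracted from every
#' seedling of the same experiment.
#'
#' @param estimates Tibble from [fit_rhythms()] (columns `experiment`,
#'   `genotype`, `phase_ct_h`; QC-failing rows should be filtered first).
#' @param reference_genotype Label of the reference line, present in every
#'   experiment.
#' @return The input with an added `relative_phase_h` column.
#' @export
relative_phase <- function(estimates, reference_genotype) {
  need <- c("experiment", "genotype", "phase_ct_h")
  if (!all(need %in% names(estimates))) {
    stop("`estimates` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  estimates |>
    dplyr::group_by(.data$experiment) |>
    dplyr::group_modify(function(df, key) {
      ref <- df$phase_ct_h[df$genotype == reference_genotype]
      if (length(ref) == 0) {
        stop("reference genotype ", reference_genotype,
             " missing from experiment ", key$experiment, call. = FALSE)
      }
      df$relative_phase_h <- df$phase_ct_h - mean(ref, na.rm = TRUE)
      df
    }) |>
    dplyr::ungroup()
}

#' One-way ANOVA with Tukey HSD letters across genotypes
#'
#' Compares a per-seedling statistic (period, phase, amplitude, RAE, ...)
#' between genotype groups: one-way ANOVA, all-pairs Tukey HSD, and a
#' compact letter display at level `alpha` (groups sharing a letter are not
#' significantly different).
#'
#' @param data Tibble holding the values and group labels.
#' @param value,group Column names (unquoted) of the statistic and the
#'   grouping factor.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `group_comparison`: list with `anova` (tidied
#'   table), `tukey` (pairwise contrasts), `letters` (per-group mean and
#'   letter).
#' @export
group_compare <- function(data, value, group, alpha = 0.05) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]
  g <- factor(g[keep])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  d <- data.frame(v = v, g = g)
  m <- stats::aov(v ~ g, data = d)
  if (stats::sigma(m) < .Machine$double.eps^0.5 * max(1, diff(range(v)))) {
    stop("degenerate within-group variance; ANOVA undefined", call. = FALSE)
  }
  glht <- multcomp::glht(m, linfct = multcomp::mcp(g = "Tukey"))
  tk <- summary(glht)
  tukey_tbl <- tibble::tibble(
    contrast = names(tk$test$coefficients),
    estimate = unname(tk$test$coefficients),
    se = unname(tk$test$sigma),
    statistic = unname(tk$test$tstat),
    p_value = unname(as.numeric(tk$test$pvalues))
  )
  lt <- multcomp::cld(glht, level = alpha)$mcletters$Letters
  letters_tbl <- tibble::tibble(
    group = names(lt),
    mean = as.numeric(tapply(v, g, mean)[names(lt)]),
    n = as.integer(table(g)[names(lt)]),
    letter = unname(lt)
  )
  structure(
    list(anova = tidy_aov(m), tukey = tukey_tbl, letters = letters_tbl,
         alpha = alpha),
    class = "group_comparison"
  )
}

#' @exportS3Method base::print
print.group_comparison <- function(x, ...) {
  cat("One-way ANOVA: F =",
      format(x$anova$statistic[1], digits = 4),
      ", p =", format(x$anova$p_value[1], digits = 3), "\n")
  print(x$letters)
  invisible(x)
}
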