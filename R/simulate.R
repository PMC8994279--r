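#' Configuration for the synthetic diel-expression generator
#'
#' Bundles and validates the parameters of the rhythm model used by
#' [simulate_diel_timecourse()] and [simulate_snapshot()]. On the log2 scale
#' a cycling gene follows
#' \deqn{x_g(t) = m_g + A_g \cos(2\pi (t - \phi_g)/\tau) + \epsilon,}
#' with gene-level mesor \eqn{m_g}, amplitude \eqn{A_g}, acrophase
#' \eqn{\phi_g} and Gaussian noise \eqn{\epsilon}. Acrophases are drawn from
#' a circular mixture with two wrapped-normal components centred shortly
#' before dawn and before dusk plus a uniform background, matching the
#' bimodal pre-dawn / pre-dusk phase distribution typical of plant diel
#' transcriptomes. Non-cycling genes have \eqn{A_g = 0}.
#'
#' The defaults describe the emulated study design: sampling 2 h after
#' lights-on (ZT2), three biological replicates, four genotypes (a recipient
#' background plus near-isogenic lines), and an internal-phase delay of
#' 0.8 h in long days relative to short days.
#'
#' @param n_genes Number of genes.
#' @param frac_cycling Fraction of genes that cycle, in `[0, 1]`. The number
#'   of cycling genes is `round(frac_cycling * n_genes)`. Default 0.25,
#'   roughly the fraction of expressed transcripts that pass diel-cycling
#'   filters in tomato seedlings.
#' @param phase_centers_h Centres of the two clustered acrophase components,
#'   hours (default `c(23, 11)`: just before dawn at ZT0 and dusk at ZT12).
#' @param phase_sd_h Spread (hours) of each wrapped-normal component
#'   (default 2).
#' @param phase_uniform_weight Weight of the uniform background component
#'   (default 0.2); the remainder is split equally between the two centres.
#' @param amplitude_log2 Length-2 range; per-gene amplitudes are drawn
#'   uniformly from it (log2 units, default `c(0.5, 2)`).
#' @param mean_expression_log2 Centre of the per-gene mesor distribution
#'   (log2 units, default 6).
#' @param mesor_sd_log2 Between-gene spread of mesors (default 1).
#' @param noise_sd_log2 SD of the additive log2-scale noise (default 0.2).
#' @param period_h Oscillation period in hours (default 24). All hour-valued
#'   fields are interpreted modulo this period.
#' @param genotype_offsets_h Named numeric vector mapping genotype label to
#'   its internal phase offset in hours. Default: recipient background `MM`
#'   and three introgression lines, all offset 0.
#' @param photoperiod_shift_h Hours added to the internal phase of long-day
#'   samples (default 0.8, the average long-day phase delay this design is
#'   built to detect).
#' @param sampling_zt_h Snapshot collection time, hours after lights-on
#'   (default 2, i.e. ZT2).
#' @param n_replicates Biological replicates per genotype x photoperiod cell
#'   in snapshot experiments (default 3).
#' @param seed Optional integer seed; identical seed and configuration give
#'   bit-identical simulated matrices.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              frac_cycling = 0.25,
                              phase_centers_h = c(23, 11),
                              phase_sd_h = 2,
                              phase_uniform_weight = 0.2,
                              amplitude_log2 = c(0.5, 2),
                              mean_expression_log2 = 6,
                              mesor_sd_log2 = 1,
                              noise_sd_log2 = 0.2,
                              period_h = 24,
                              genotype_offsets_h = c(
                                MM = 0, EID1 = 0, LNK2 = 0, EID1.LNK2 = 0
                              ),
                              photoperiod_shift_h = 0.8,
                              sampling_zt_h = 2,
                              n_replicates = 3,
                              seed = NULL) {
  check_scalar <- function(x, nm, positive = FALSE, nonneg = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
    if (positive && x <= 0) {
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
    }
    if (nonneg && x < 0) {
      stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
    }
  }
  check_scalar(n_genes, "n_genes", positive = TRUE)
  check_scalar(frac_cycling, "frac_cycling")
  if (frac_cycling < 0 || frac_cycling > 1) {
    stop("`frac_cycling` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(phase_centers_h) || length(phase_centers_h) != 2) {
    stop("`phase_centers_h` must be two hour values", call. = FALSE)
  }
  check_scalar(phase_sd_h, "phase_sd_h", positive = TRUE)
  check_scalar(phase_uniform_weight, "phase_uniform_weight")
  if (phase_uniform_weight < 0 || phase_uniform_weight > 1) {
    stop("`phase_uniform_weight` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(amplitude_log2) || length(amplitude_log2) != 2 ||
      any(amplitude_log2 <= 0) || diff(amplitude_log2) < 0) {
    stop("`amplitude_log2` must be an increasing positive range",
         call. = FALSE)
  }
  check_scalar(mean_expression_log2, "mean_expression_log2")
  check_scalar(mesor_sd_log2, "mesor_sd_log2", nonneg = TRUE)
  check_scalar(noise_sd_log2, "noise_sd_log2", nonneg = TRUE)
  check_scalar(period_h, "period_h", positive = TRUE)
  if (length(genotype_offsets_h) == 0 ||
      is.null(names(genotype_offsets_h)) ||
      any(!nzchar(names(genotype_offsets_h))) ||
      !is.numeric(genotype_offsets_h)) {
    stop("`genotype_offsets_h` must be a non-empty named numeric vector",
         call. = FALSE)
  }
  check_scalar(photoperiod_shift_h, "photoperiod_shift_h")
  check_scalar(sampling_zt_h, "sampling_zt_h")
  check_scalar(n_replicates, "n_replicates", positive = TRUE)
  if (!is.null(seed)) check_scalar(seed, "seed")

  structure(
    list(
      n_genes = as.integer(n_genes), frac_cycling = frac_cycling,
      phase_centers_h = phase_centers_h %% period_h,
      phase_sd_h = phase_sd_h,
      phase_uniform_weight = phase_uniform_weight,
      amplitude_log2 = amplitude_log2,
      mean_expression_log2 = mean_expression_log2,
      mesor_sd_log2 = mesor_sd_log2,
      noise_sd_log2 = noise_sd_log2,
      period_h = period_h,
      genotype_offsets_h = genotype_offsets_h,
      photoperiod_shift_h = photoperiod_shift_h,
      sampling_zt_h = sampling_zt_h %% period_h,
      n_replicates = as.integer(n_replicates),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Draw per-gene ground-truth rhythm parameters
#'
#' Samples gene-level cycling flags, acrophases, amplitudes and mesors from
#' the configured mixture. Exposed so that several simulated experiments
#' (e.g. two diel time courses and a snapshot) can share one truth table.
#'
#' @param config A [simulation_config()].
#' @return Tibble with columns `gene_id`, `cycling`, `phase_h`,
#'   `amplitude_log2`, `mesor_log2`.
#' @export
simulate_gene_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_genes
  n_cyc <- round(config$frac_cycling * n)
  cycling <- c(rep(TRUE, n_cyc), rep(FALSE, n - n_cyc))
  phase <- rep(NA_real_, n)
  if (n_cyc > 0) {
    phase[seq_len(n_cyc)] <- sample_phase_mixture(n_cyc, config)
  }
  amp <- ifelse(
    cycling,
    stats::runif(n, config$amplitude_log2[1], config$amplitude_log2[2]),
    0
  )
  mesor <- stats::rnorm(n, config$mean_expression_log2, config$mesor_sd_log2)
  tibble::tibble(
    gene_id = sprintf("gene_%05d", seq_len(n)),
    cycling = cycling,
    phase_h = phase,
    amplitude_log2 = amp,
    mesor_log2 = mesor
  )
}

# Two wrapped-normal components plus uniform background on [0, period).
sample_phase_mixture <- function(n, config) {
  w_bg <- config$phase_uniform_weight
  comp <- sample.int(3L, n, replace = TRUE,
                     prob = c((1 - w_bg) / 2, (1 - w_bg) / 2, w_bg))
  out <- numeric(n)
  for (k in 1:2) {
    idx <- comp == k
    out[idx] <- stats::rnorm(sum(idx), config$phase_centers_h[k],
                             config$phase_sd_h)
  }
  idx <- comp == 3L
  out[idx] <- stats::runif(sum(idx), 0, config$period_h)
  out %% config$period_h
}

# Noise-free log2 expression of all genes at internal times `t_h`.
expected_log2_expression <- function(truth, t_h, period_h) {
  ph <- ifelse(truth$cycling, truth$phase_h, 0)
  outer_cos <- cos(2 * pi * outer(-ph, t_h, "+") / period_h)
  truth$mesor_log2 + truth$amplitude_log2 * outer_cos
}

finalize_expression <- function(mu_log2, noise_sd, counts, gene_ids,
                                sample_ids) {
  x <- mu_log2
  if (noise_sd > 0) {
    x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow = nrow(x))
  }
  if (counts) {
    x <- matrix(stats::rpois(length(x), lambda = 2^x), nrow = nrow(x))
  }
  dimnames(x) <- list(gene_ids, sample_ids)
  x
}

#' Simulate a diel expression time course
#'
#' Generates a gene x sample matrix following the cosine rhythm model of
#' [simulation_config()] at the given collection times, with independent
#' replicates at every time point. The default design mirrors a diel cycle
#' sampled every 4 h at time points 12, 16, 20, 24, 28 and 32 h with
#' duplicate samples, the layout consumed by [split_replicates_to_days()].
#'
#' @param config A [simulation_config()].
#' @param times_h Collection times in hours (non-empty).
#' @param n_replicates Replicates per time point (default 2).
#' @param counts If `TRUE`, exponentiate the log2 model and draw Poisson
#'   counts; otherwise return log2-scale values (default).
#' @param truth Optional truth table from [simulate_gene_truth()]; drawn
#'   from `config` when missing.
#' @return A `diel_timecourse`: list with `expression` (gene x sample
#'   matrix), `samples` (tibble: `sample_id`, `time_h`, `replicate`),
#'   `truth`, and `log_scale` flag.
#' @export
simulate_diel_timecourse <- function(config,
                                     times_h = seq(12, 32, by = 4),
                                     n_replicates = 2,
                                     counts = FALSE,
                                     truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(times_h) == 0 || !is.numeric(times_h)) {
    stop("`times_h` must be a non-empty numeric vector", call. = FALSE)
  }
  if (is.null(truth)) {
    truth <- simulate_gene_truth(config)
  } else if (!is.null(config$seed)) {
    set.seed(config$seed + 1L)
  }
  samples <- tidyr::expand_grid(
    time_h = times_h,
    replicate = seq_len(n_replicates)
  ) |>
    dplyr::mutate(sample_id = sprintf("T%02g_r%d", .data$time_h,
                                      .data$replicate)) |>
    dplyr::select("sample_id", "time_h", "replicate")

  mu <- expected_log2_expression(truth, samples$time_h, config$period_h)
  expr <- finalize_expression(mu, config$noise_sd_log2, counts,
                              truth$gene_id, samples$sample_id)
  structure(
    list(expression = expr, samples = samples, truth = truth,
         log_scale = !counts, period_h = config$period_h),
    class = "diel_timecourse"
  )
}

#' Simulate a single-time-point snapshot experiment
#'
#' Every sample is collected at the same Zeitgeber time but genotype and
#' photoperiod move the plants' internal clock: a sample of genotype g under
#' photoperiod p is the diel model evaluated at internal time
#' `sampling_zt_h + genotype_offsets_h[g] + photoperiod_shift_h * (p == "LD")`,
#' plus noise. The per-cell internal times are recorded as ground truth, so
#' downstream phase inference can be scored by parameter recovery.
#'
#' @inheritParams simulate_diel_timecourse
#' @return A `snapshot_experiment`: list with `expression` (gene x sample
#'   matrix), `samples` (tibble: `sample_id`, `genotype`, `photoperiod`,
#'   `replicate`, `zt_h`), `truth` (gene table), `truth_cells` (tibble:
#'   `genotype`, `photoperiod`, `internal_time_h`) and `log_scale`.
#' @export
simulate_snapshot <- function(config, counts = FALSE, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(config$genotype_offsets_h) == 0) {
    stop("`genotype_offsets_h` must be non-empty", call. = FALSE)
  }
  if (is.null(truth)) {
    truth <- simulate_gene_truth(config)
  } else if (!is.null(config$seed)) {
    set.seed(config$seed + 2L)
  }
  genotypes <- names(config$genotype_offsets_h)
  samples <- tidyr::expand_grid(
    genotype = genotypes,
    photoperiod = c("SD", "LD"),
    replicate = seq_len(config$n_replicates)
  ) |>
    dplyr::mutate(
      sample_id = sprintf("%s_%s_r%d", .data$genotype, .data$photoperiod,
                          .data$replicate),
      zt_h = config$sampling_zt_h
    ) |>
    dplyr::select("sample_id", "genotype", "photoperiod", "replicate",
                  "zt_h")

  internal <- config$sampling_zt_h +
    config$genotype_offsets_h[samples$genotype] +
    config$photoperiod_shift_h * (samples$photoperiod == "LD")
  internal <- unname(internal) %% config$period_h

  mu <- expected_log2_expression(truth, internal, config$period_h)
  expr <- finalize_expression(mu, config$noise_sd_log2, counts,
                              truth$gene_id, samples$sample_id)

  truth_cells <- samples |>
    dplyr::mutate(internal_time_h = internal) |>
    dplyr::distinct(.data$genotype, .data$photoperiod,
                    .data$internal_time_h)

  structure(
    list(expression = expr, samples = samples, truth = truth,
         truth_cells = truth_cells, log_scale = !counts,
         period_h = config$period_h),
    class = "snapshot_experiment"
  )
}

#' @exportS3Method base::print
print.diel_timecourse <- function(x, ...) {
  cat("Diel time course:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples\n")
  cat("  times (h):", paste(sort(unique(x$samples$time_h)), collapse = ", "),
      "\n")
  cat("  scale:", if (x$log_scale) "log2" else "counts", "\n")
  invisible(x)
}

#' @exportS3Method base::print
print.snapshot_experiment <- function(x, ...) {
  cat("Snapshot experiment:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples\n")
  cat("  genotypes:", paste(unique(x$samples$genotype), collapse = ", "),
      "\n")
  cat("  photoperiods:", paste(unique(x$samples$photoperiod),
                               collapse = ", "),
      "| collection ZT", unique(x$samples$zt_h), "h\n")
  invisible(x)
}
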