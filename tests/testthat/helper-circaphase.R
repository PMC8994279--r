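# shared builders for the test suite

# truth table for hand-constructed genes; phases NA for non-cycling
make_truth <- function(phase_h, amplitude = 1, mesor = 6) {
  n <- length(phase_h)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    cycling = !is.na(phase_h),
    phase_h = phase_h,
    amplitude_log2 = ifelse(is.na(phase_h), 0, rep_len(amplitude, n)),
    mesor_log2 = rep_len(mesor, n)
  )
}

# cycling-gene table straight from a truth table (reference stats included)
genes_from_truth <- function(truth) {
  cyc <- truth[truth$cycling, ]
  tibble::tibble(
    gene_id = cyc$gene_id,
    phase = phase_to_bin(cyc$phase_h),
    period_h = 24,
    amplitude = cyc$amplitude_log2,
    mean_expression = cyc$mesor_log2,
    q_value = 0
  )
}

# minimal valid cycling-stats row set for filter tests
make_stats <- function(gene_id, q_value, period_h, amplitude,
                       mean_expression, phase_h = 10) {
  tibble::tibble(
    gene_id = gene_id,
    p_value = q_value,
    q_value = q_value,
    period_h = period_h,
    phase_h = rep_len(phase_h, length(gene_id)),
    amplitude = amplitude,
    mean_expression = mean_expression
  )
}

# random genotype table for introgression oracle tests
random_variants <- function(n_sites, chroms = c("ch01", "ch02"),
                            p_het = 0.3, p_missing = 0.05) {
  purrr::map_dfr(chroms, function(ch) {
    states <- sample(
      c("hom_ref", "het", "hom_alt", "missing"), n_sites, replace = TRUE,
      prob = c(1 - p_het - p_missing - 0.05, p_het, 0.05, p_missing)
    )
    tibble::tibble(
      chrom = ch,
      pos = sort(sample.int(n_sites * 50, n_sites)),
      genotype = factor(states,
                        levels = c("hom_ref", "het", "hom_alt", "missing"))
    )
  })
}

# damped cosine movement trace sampled every 0.5 h for `days` days
make_trace <- function(tau, phi, amp = 1, lambda = 0, noise_sd = 0,
                       days = 5) {
  t <- seq(0, days * 24, by = 0.5)
  y <- amp * exp(-lambda * t) * cos(2 * pi * (t - phi) / tau) +
    stats::rnorm(length(t), 0, noise_sd)
  tibble::tibble(time_h = t, position = y)
}
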