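test_that("within-experiment z-scores follow the sample-sd definition", {
  m <- matrix(c(4, 6, 8,
                1, 1, 1,
                2, 5, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("g001", "g002", "g003"), paste0("s", 1:3)))
  genes <- tibble::tibble(gene_id = rownames(m), phase = c(0L, 6L, 12L))
  expect_message(z <- zscore_genes(m, genes, scope = "all"), "zero variance")
  # hand-computed with the sample (n-1) sd: (4,6,8) -> (-1, 0, 1)
  expect_equal(unname(z["g001", ]), c(-1, 0, 1), tolerance = 1e-9)
  expect_false("g002" %in% rownames(z))
  expect_equal(attr(z, "dropped"), "g002")
  # every retained row has mean 0 and sd 1
  expect_equal(unname(rowMeans(z)), rep(0, 2), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 2), tolerance = 1e-9)
})

test_that("reference z-scores rescale by the diel cycle statistics", {
  truth <- make_truth(c(2, 20), amplitude = 1.5, mesor = 6)
  cfg <- simulation_config(n_genes = 2, noise_sd_log2 = 0,
                           photoperiod_shift_h = 0,
                           genotype_offsets_h = c(A = 0), n_replicates = 2)
  snap <- simulate_snapshot(cfg, truth = truth)
  genes <- genes_from_truth(truth)
  z <- zscore_genes(snap, genes, scope = "reference")
  # z = (m + A cos(w(2 - phi)) - m) / (A/sqrt(2)) = sqrt(2) cos(w(2 - phi))
  expect_equal(unname(z["g001", 1]), sqrt(2), tolerance = 1e-9)
  expect_equal(unname(z["g002", 1]),
               sqrt(2) * cos(2 * pi * (2 - 20) / 24), tolerance = 1e-9)
})

test_that("timetable curves aggregate z by phase bin and group", {
  # zero z matrix: all defined bins average zero
  z <- matrix(0, nrow = 3, ncol = 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  genes <- tibble::tibble(gene_id = paste0("g", 1:3), phase = c(0L, 0L, 5L))
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    genotype = c("A", "A", "B", "B"),
    photoperiod = c("SD", "LD", "SD", "LD")
  )
  cur <- timetable_curve(z, genes, samples)
  expect_s3_class(cur, "timetable_curve")
  expect_true(all(cur$mean_z[cur$n_genes > 0] == 0))
  # empty bins carry NA, not zero
  expect_true(all(is.na(cur$mean_z[cur$n_genes == 0])))
  # per group, gene counts over bins sum to the number of cycling genes
  tot <- tapply(cur$n_genes, paste(cur$genotype, cur$photoperiod), sum)
  expect_true(all(tot == 3))
  expect_error(timetable_curve(z, genes, samples, group_by = "nope"),
               "unknown grouping")
})

test_that("curve means equal an independent group-by recomputation", {
  set.seed(12)
  n_genes <- 20
  z <- matrix(rnorm(n_genes * 6), nrow = n_genes,
              dimnames = list(sprintf("g%02d", 1:n_genes), paste0("s", 1:6)))
  genes <- tibble::tibble(gene_id = rownames(z),
                          phase = sample(0:23, n_genes, replace = TRUE))
  samples <- tibble::tibble(
    sample_id = colnames(z),
    genotype = rep(c("A", "B"), each = 3),
    photoperiod = rep(c("SD", "LD", "SD"), 2)
  )
  cur <- timetable_curve(z, genes, samples)
  # brute-force recomputation with base R loops
  for (i in sample(which(cur$n_genes > 0), 10)) {
    rows <- genes$gene_id[genes$phase == cur$phase[i]]
    cols <- samples$sample_id[samples$genotype == cur$genotype[i] &
                                samples$photoperiod == cur$photoperiod[i]]
    vals <- as.vector(z[rows, cols, drop = FALSE])
    expect_equal(cur$mean_z[i], mean(vals), tolerance = 1e-12)
    expect_equal(cur$se[i], sd(vals) / sqrt(length(vals)),
                 tolerance = 1e-12)
  }
  # permutation invariance to sample order
  perm <- sample(ncol(z))
  cur2 <- timetable_curve(z[, perm], genes, samples[perm, ])
  expect_equal(as.data.frame(cur2), as.data.frame(cur))
})

test_that("a noiseless ZT2 snapshot peaks at bin 2 and dips near bin 14", {
  cfg <- simulation_config(n_genes = 600, frac_cycling = 1,
                           noise_sd_log2 = 0, photoperiod_shift_h = 0,
                           genotype_offsets_h = c(MM = 0), seed = 8)
  truth <- simulate_gene_truth(cfg)
  snap <- simulate_snapshot(cfg, truth = truth)
  genes <- genes_from_truth(truth)
  z <- zscore_genes(snap, genes, scope = "reference")
  cur <- timetable_curve(z, genes, snap$samples)
  one <- cur[cur$photoperiod == "SD" & !is.na(cur$mean_z), ]
  expect_equal(one$phase[which.max(one$mean_z)], 2)
  expect_lte(abs(circular_diff(one$phase[which.min(one$mean_z)], 14)), 1)
})

test_that("phase-binned fold changes match the closed form", {
  truth <- make_truth(seq(0.3, 23.3, by = 1), amplitude = 1.2)
  cfg0 <- simulation_config(n_genes = 24, noise_sd_log2 = 0,
                            photoperiod_shift_h = 0,
                            genotype_offsets_h = c(A = 0), n_replicates = 2)
  snap0 <- simulate_snapshot(cfg0, truth = truth)
  genes <- genes_from_truth(truth)
  fc0 <- foldchange_by_phase(snap0, genes)
  expect_true(all(abs(fc0$mean_lfc[fc0$n_genes > 0]) < 1e-12))

  cfg1 <- simulation_config(n_genes = 24, noise_sd_log2 = 0,
                            photoperiod_shift_h = 0.8,
                            genotype_offsets_h = c(A = 0), n_replicates = 2)
  snap1 <- simulate_snapshot(cfg1, truth = truth)
  fc1 <- foldchange_by_phase(snap1, genes)
  # per-bin mean LFC equals the cosine difference evaluated at the truth
  lfc_true <- function(phi) {
    1.2 * (cos(2 * pi * (2.8 - phi) / 24) - cos(2 * pi * (2 - phi) / 24))
  }
  filled <- fc1[fc1$n_genes > 0, ]
  per_gene <- tibble::tibble(phase = phase_to_bin(truth$phase_h),
                             lfc = lfc_true(truth$phase_h))
  for (i in seq_len(nrow(filled))) {
    expect_equal(
      filled$mean_lfc[i],
      mean(per_gene$lfc[per_gene$phase == filled$phase[i]]),
      tolerance = 1e-9
    )
  }
  # delayed LD clock: genes peaking after collection are up-regulated,
  # genes peaking ~12 h away are down-regulated
  expect_gt(filled$mean_lfc[filled$phase == 8], 0)
  expect_lt(filled$mean_lfc[filled$phase == 20], 0)

  # genotype missing a photoperiod is reported by name
  snap_bad <- snap1
  keep <- snap_bad$samples$photoperiod == "SD"
  snap_bad$samples <- snap_bad$samples[keep, ]
  snap_bad$expression <- snap_bad$expression[, keep]
  expect_error(foldchange_by_phase(snap_bad, genes), "A")
})

test_that("the DE stand-in is calibrated and finds a spiked gene", {
  # identical photoperiod groups: no signal at all
  truth <- make_truth(rep(NA_real_, 20))
  cfg <- simulation_config(n_genes = 20, noise_sd_log2 = 0,
                           photoperiod_shift_h = 0,
                           genotype_offsets_h = c(A = 0), n_replicates = 3)
  snap <- simulate_snapshot(cfg, truth = truth)
  de <- de_stand_in(snap)
  expect_true(all(de$q_value > 0.99))
  expect_true(all(abs(de$lfc) < 1e-12))

  # null simulation with noise: BH keeps the q<0.05 fraction at bay
  cfg_n <- simulation_config(n_genes = 500, frac_cycling = 0,
                             noise_sd_log2 = 0.3, photoperiod_shift_h = 0,
                             genotype_offsets_h = c(A = 0),
                             n_replicates = 3, seed = 14)
  de_n <- de_stand_in(simulate_snapshot(cfg_n))
  expect_lte(mean(de_n$q_value < 0.05), 0.05)

  # a strongly shifted gene gets the smallest q
  snap_sp <- simulate_snapshot(cfg_n)
  ld_cols <- snap_sp$samples$photoperiod == "LD"
  snap_sp$expression["gene_00007", ld_cols] <-
    snap_sp$expression["gene_00007", ld_cols] + 2
  de_sp <- de_stand_in(snap_sp)
  expect_equal(de_sp$gene_id[which.min(de_sp$q_value)], "gene_00007")
})
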