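#' Read a gene x sample expression matrix
#'
#' `format = "tsv"` expects a header row of sample ids and a first column
#' of gene ids; `format = "mtx"` reads a MatrixMarket file plus sibling
#' `<path>.rows` / `<path>.cols` index files (one id per line). Duplicate
#' gene or sample ids and ragged rows are rejected with the offending line
#' named.
#'
#' @param path Path to the matrix file.
#' @param format `"tsv"` (default) or `"mtx"`.
#' @return Dense numeric matrix with gene ids as rownames and sample ids
#'   as colnames.
#' @export
read_expression <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    lines <- readLines(path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    width <- lengths(fields)
    bad <- which(width != width[1])
    if (length(bad) > 0) {
      stop("malformed row at line ", bad[1], ": expected ", width[1],
           " fields, found ", width[bad[1]], call. = FALSE)
    }
    header <- fields[[1]][-1]
    ids <- vapply(fields[-1], `[[`, character(1), 1)
    if (anyDuplicated(ids)) {
      stop("duplicate gene id: ", ids[duplicated(ids)][1], call. = FALSE)
    }
    if (anyDuplicated(header)) {
      stop("duplicate sample id: ", header[duplicated(header)][1],
           call. = FALSE)
    }
    vals <- vapply(fields[-1], function(f) as.numeric(f[-1]),
                   numeric(length(header)))
    m <- if (length(header) == 1) matrix(vals, ncol = 1) else t(vals)
    dimnames(m) <- list(ids, header)
    m
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rows <- readLines(paste0(path, ".rows"))
    cols <- readLines(paste0(path, ".cols"))
    if (length(rows) != nrow(m) || length(cols) != ncol(m)) {
      stop("index files do not match matrix dimensions", call. = FALSE)
    }
    if (anyDuplicated(rows) || anyDuplicated(cols)) {
      stop("duplicate ids in MTX index files", call. = FALSE)
    }
    dimnames(m) <- list(rows, cols)
    m
  }
}

#' Write a gene x sample expression matrix
#'
#' Round-trips with [read_expression()]: TSV with a `gene_id` header
#' column, or MatrixMarket plus `.rows` / `.cols` index files.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
    writeLines(rownames(mat), paste0(path, ".rows"))
    writeLines(colnames(mat), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read sample metadata
#'
#' CSV with at least `sample_id`; typical snapshot metadata also carries
#' `genotype`, `photoperiod`, `replicate`, `zt_h`.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(meta)) {
    stop("metadata must contain a `sample_id` column", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  meta
}

#' Analysis thresholds and modes for a pipeline run
#'
#' Collects every tunable of the snapshot phase-inference pipeline, each
#' defaulting to the value used throughout the package: `q_cutoff = 0.05`
#' for the cycling test, accepted period window 22-26 h, 2.5-SD
#' amplitude/mean outlier cut, ERR threshold 0.4 for movement traces,
#' `alpha = 0.05`, CPM normalisation and experiment-wide z-score scope.
#' The full configuration is serialised into each run's provenance record.
#'
#' @param q_cutoff,period_range,sd_multiplier Cycling filter settings.
#' @param err_threshold Leaf-movement QC cut.
#' @param alpha Significance level for contrasts and letters.
#' @param normalization `"cpm"` or `"mor"` (see [normalize_counts()]).
#' @param zscore_scope `"reference"` (default; the molecular-timetable
#'   normalisation required for absolute phase inference), `"all"` or
#'   `"genotype"` (see [zscore_genes()]).
#' @param period_grid Candidate periods for [test_cycling()].
#' @param seed Integer seed for simulation-backed runs.
#' @return List of class `run_config`.
#' @export
run_config <- function(q_cutoff = 0.05,
                       period_range = c(22, 26),
                       sd_multiplier = 2.5,
                       err_threshold = 0.4,
                       alpha = 0.05,
                       normalization = c("cpm", "mor"),
                       zscore_scope = c("reference", "all", "genotype"),
                       period_grid = seq(20, 28, by = 0.5),
                       seed = 1L) {
  structure(
    list(
      q_cutoff = q_cutoff,
      period_range = period_range,
      sd_multiplier = sd_multiplier,
      err_threshold = err_threshold,
      alpha = alpha,
      normalization = match.arg(normalization),
      zscore_scope = match.arg(zscore_scope),
      period_grid = period_grid,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Run the synthetic snapshot phase-inference pipeline end to end
#'
#' Simulates two diel time courses (sharing one gene truth table, emulating
#' recipient- and donor-species experiments) and a snapshot experiment,
#' then runs day-splitting, cycling detection, the filter cascade,
#' z-scoring, timetable curves, the DE stand-in, phase-binned fold changes,
#' per-replicate phase estimation and the photoperiod ANOVA. All
#' intermediate tables are written as TSV under `out_dir` together with a
#' JSON summary (per-genotype phase shift, ANOVA table, provenance:
#' configuration, seed, versions). Identical seeds give byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param sim_config A [simulation_config()]; its `seed` is overridden by
#'   `config$seed`.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return Invisibly, a list with the pipeline objects: `timecourse_a`,
#'   `timecourse_b`, `snapshot`, `cycling`, `z`, `curves`, `de`,
#'   `foldchange`, `sample_phases`, `shift`, `summary`.
#' @export
run_pipeline <- function(config = run_config(),
                         sim_config = simulation_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"),
            inherits(sim_config, "simulation_config"))
  sim_config$seed <- config$seed

  set.seed(config$seed)
  truth <- simulate_gene_truth(sim_config)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", what, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  tc_a <- stage("simulate", {
    cfg <- sim_config; cfg$seed <- NULL
    simulate_diel_timecourse(cfg, truth = truth)
  })
  tc_b <- stage("simulate", {
    cfg <- sim_config; cfg$seed <- NULL
    simulate_diel_timecourse(cfg, truth = truth)
  })
  snap <- stage("simulate", {
    cfg <- sim_config; cfg$seed <- NULL
    simulate_snapshot(cfg, truth = truth)
  })

  stats_a <- stage("cycling", test_cycling(
    split_replicates_to_days(tc_a), period_grid = config$period_grid))
  stats_b <- stage("cycling", test_cycling(
    split_replicates_to_days(tc_b), period_grid = config$period_grid))
  cycling <- stage("cycling", filter_and_phase(
    stats_a, stats_b, phase_source = "b",
    q_cutoff = config$q_cutoff, period_range = config$period_range,
    sd_multiplier = config$sd_multiplier))
  if (nrow(cycling) == 0) {
    stop("pipeline stage `cycling` failed: no gene passed the filter ",
         "cascade", call. = FALSE)
  }

  z <- stage("timetable", zscore_genes(snap, cycling,
                                       scope = config$zscore_scope))
  curves <- stage("timetable", timetable_curve(z, cycling, snap$samples))
  de <- stage("timetable", de_stand_in(snap, alpha = config$alpha))
  fc <- stage("timetable", foldchange_by_phase(snap, cycling, de))

  phases <- stage("phase-shift", estimate_sample_phase(z, cycling,
                                                       snap$samples))
  shift <- stage("phase-shift", phase_shift_anova(
    phases, alpha = config$alpha))

  summary_list <- list(
    shifts = shift$shifts,
    mean_shift_h = shift$mean_shift_h,
    main_effect = shift$main_effect,
    anova = shift$anova,
    n_cycling_genes = nrow(cycling),
    provenance = list(
      config = unclass(config),
      sim_config = unclass(sim_config),
      seed = config$seed,
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      package_version = as.character(utils::packageVersion("circaphase"))
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression(snap$expression,
                     file.path(out_dir, "snapshot_expression.tsv"))
    readr::write_csv(snap$samples,
                     file.path(out_dir, "snapshot_metadata.csv"))
    readr::write_tsv(cycling, file.path(out_dir, "cycling_genes.tsv"))
    readr::write_tsv(phases, file.path(out_dir, "sample_phases.tsv"))
    readr::write_tsv(curves, file.path(out_dir, "timetable_curves.tsv"))
    readr::write_tsv(fc, file.path(out_dir, "foldchange_by_phase.tsv"))
    jsonlite::write_json(summary_list,
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(
    timecourse_a = tc_a, timecourse_b = tc_b, snapshot = snap,
    cycling_stats_a = stats_a, cycling_stats_b = stats_b,
    cycling = cycling, z = z, curves = curves, de = de, foldchange = fc,
    sample_phases = phases, shift = shift, summary = summary_list
  ))
}
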