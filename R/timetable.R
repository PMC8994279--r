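#' Library-size normalisation of a count matrix to a log2 scale
#'
#' `method = "cpm"` (default) computes `log2(counts-per-million + 1)`;
#' `method = "mor"` divides each sample by a median-of-ratios size factor
#' (the geometric-mean reference construction) before the log transform.
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @param method `"cpm"` or `"mor"`.
#' @return Log2-scale matrix with the same dimnames.
#' @export
normalize_counts <- function(counts, method = c("cpm", "mor")) {
  method <- match.arg(method)
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (method == "cpm") {
    lib <- colSums(counts)
    if (any(lib == 0)) stop("sample with zero total counts", call. = FALSE)
    log2(t(t(counts) / lib) * 1e6 + 1)
  } else {
    # median-of-ratios size factors on genes expressed in every sample
    log_geo <- rowMeans(log(counts))
    use <- is.finite(log_geo)
    if (!any(use)) {
      stop("no gene expressed in all samples; cannot compute size factors",
           call. = FALSE)
    }
    sf <- apply(counts[use, , drop = FALSE], 2, function(cnt) {
      exp(stats::median(log(cnt) - log_geo[use]))
    })
    log2(t(t(counts) / sf) + 1)
  }
}

#' Z-score cycling genes
#'
#' Standardises each cycling gene's (log-scale) expression. Three scopes
#' are available, and the choice matters because all snapshot samples are
#' collected at (almost) the same internal time:
#'
#' * `"reference"` (recommended for phase inference): each gene is
#'   standardised with its mean expression and cycle standard deviation
#'   (amplitude / sqrt(2)) from the reference diel time course carried in
#'   the cycling-gene table — the classic molecular-timetable
#'   normalisation. Each sample's z-profile then traces
#'   \eqn{\sqrt 2 \cos(2\pi(t^*-\phi_g)/\tau)} around the sample's
#'   internal time \eqn{t^*}, so the absolute phase is recoverable from a
#'   single sample.
#' * `"all"`: per gene across all snapshot samples (sample sd,
#'   \eqn{n-1}). Useful for visualising relative differences, but because
#'   the samples share one collection time the centering removes the
#'   absolute cosine component, so per-sample acrophases are not
#'   interpretable in this scope.
#' * `"genotype"`: as `"all"` but within each genotype.
#'
#' Genes with zero variance (or zero reference amplitude) are dropped and
#' reported via the `"dropped"` attribute and a message.
#'
#' @param snap A `snapshot_experiment` (log-scale expression) or a plain
#'   gene x sample matrix.
#' @param genes A cycling-gene table from [filter_and_phase()] (needs
#'   columns `gene_id`, `phase`; `scope = "reference"` also needs
#'   `mean_expression` and `amplitude`).
#' @param scope `"reference"`, `"all"` (default, the within-experiment
#'   convention) or `"genotype"`.
#' @param samples Sample metadata tibble; required only when `snap` is a
#'   bare matrix and `scope = "genotype"`.
#' @return Gene x sample z-score matrix with attribute `dropped` (character
#'   vector of excluded gene ids).
#' @export
zscore_genes <- function(snap, genes, scope = c("all", "genotype",
                                                "reference"),
                         samples = NULL) {
  scope <- match.arg(scope)
  if (inherits(snap, "snapshot_experiment")) {
    expr <- snap$expression
    samples <- snap$samples
    if (!isTRUE(snap$log_scale)) {
      stop("z-scoring expects log-scale expression; normalize counts first",
           call. = FALSE)
    }
  } else {
    expr <- snap
    stopifnot(is.matrix(expr))
  }
  if (ncol(expr) < 2) stop("need at least 2 samples", call. = FALSE)
  present <- intersect(genes$gene_id, rownames(expr))
  if (length(present) == 0) {
    stop("none of the cycling genes are present in the expression matrix",
         call. = FALSE)
  }
  x <- expr[present, , drop = FALSE]

  scale_rows <- function(m) {
    mu <- rowMeans(m)
    sd <- apply(m, 1, stats::sd)
    list(z = (m - mu) / sd, sd = sd)
  }

  if (scope == "reference") {
    need <- c("mean_expression", "amplitude")
    if (!all(need %in% names(genes))) {
      stop("`scope = \"reference\"` needs `mean_expression` and ",
           "`amplitude` columns in the cycling-gene table", call. = FALSE)
    }
    ref <- genes[match(present, genes$gene_id), ]
    ref_sd <- ref$amplitude / sqrt(2)
    z <- (x - ref$mean_expression) / ref_sd
    bad <- !is.finite(ref_sd) | ref_sd == 0
  } else if (scope == "all") {
    sc <- scale_rows(x)
    z <- sc$z
    bad <- sc$sd == 0
  } else {
    if (is.null(samples)) {
      stop("`samples` metadata required for genotype-scoped z-scores",
           call. = FALSE)
    }
    z <- x
    bad <- rep(FALSE, nrow(x))
    for (g in unique(samples$genotype)) {
      cols <- samples$sample_id[samples$genotype == g]
      sc <- scale_rows(x[, cols, drop = FALSE])
      z[, cols] <- sc$z
      bad <- bad | sc$sd == 0
    }
  }
  if (any(bad)) {
    message("dropping ", sum(bad), " gene(s) with zero variance")
  }
  out <- z[!bad, , drop = FALSE]
  attr(out, "dropped") <- rownames(x)[bad]
  out
}

#' Molecular-timetable curve: mean z by phase bin and group
#'
#' Averages the z-scored expression of cycling genes within each phase bin
#' for every combination of the grouping variables (genotype and
#' photoperiod by default). In a sample collected at internal time
#' \eqn{t^*}, genes whose acrophase bin is near \eqn{t^*} have positive
#' z-scores and genes peaking half a period away have negative ones, so the
#' curve traces a cosine whose peak estimates the sample group's internal
#' time.
#'
#' @param z Gene x sample z matrix from [zscore_genes()].
#' @param genes Cycling-gene table (`gene_id`, `phase`).
#' @param samples Sample metadata tibble (must contain `sample_id` and the
#'   `group_by` fields).
#' @param group_by Character vector of metadata fields to group by
#'   (default `c("genotype", "photoperiod")`).
#' @return Tibble of class `timetable_curve` with the grouping columns plus
#'   `phase`, `mean_z`, `se`, `n_genes` for every bin 0-23; bins with no
#'   genes carry `NA` means (not zeros) and `n_genes = 0`.
#' @export
timetable_curve <- function(z, genes, samples,
                            group_by = c("genotype", "photoperiod")) {
  stopifnot(is.matrix(z))
  missing_fields <- setdiff(group_by, names(samples))
  if (length(missing_fields) > 0) {
    stop("unknown grouping field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(rownames(z), genes$gene_id)
  if (length(unknown) > 0) {
    stop(length(unknown), " gene(s) in the z matrix have no phase bin",
         call. = FALSE)
  }
  long <- tibble::as_tibble(z, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "z") |>
    dplyr::inner_join(genes[, c("gene_id", "phase")], by = "gene_id") |>
    dplyr::inner_join(samples, by = "sample_id")

  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_by, "phase")))) |>
    dplyr::summarise(
      mean_z = mean(.data$z),
      se = stats::sd(.data$z) / sqrt(dplyr::n()),
      n_genes = dplyr::n_distinct(.data$gene_id),
      .groups = "drop"
    ) |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(group_by)),
      phase = 0:23,
      fill = list(n_genes = 0L)
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(group_by, "phase"))))
  class(out) <- c("timetable_curve", class(out))
  out
}

#' Photoperiod log2 fold change summarised by phase bin
#'
#' For each genotype, computes the per-gene log2 fold change between long
#' and short days (`mean log2 LD - mean log2 SD` over replicates) and
#' summarises it per acrophase bin. When the clock is delayed in long days,
#' genes peaking shortly after the collection time are up-regulated and
#' genes peaking half a period away are down-regulated, producing a
#' cosine-shaped bin profile. If a differential-expression table is
#' supplied, per-bin counts of significantly up/down genes are added.
#'
#' @param snap A `snapshot_experiment` with log-scale expression and both
#'   photoperiods for every genotype.
#' @param genes Cycling-gene table (`gene_id`, `phase`).
#' @param de_table Optional tibble from [de_stand_in()] (columns `gene_id`,
#'   `genotype`, `lfc`, `significant`).
#' @return Tibble of class `phase_binned_foldchange` with `genotype`,
#'   `phase`, `mean_lfc`, `se`, `n_genes` (and `n_up`, `n_down` when
#'   `de_table` is given) for bins 0-23.
#' @export
foldchange_by_phase <- function(snap, genes, de_table = NULL) {
  stopifnot(inherits(snap, "snapshot_experiment"))
  if (!isTRUE(snap$log_scale)) {
    stop("fold changes expect log-scale expression", call. = FALSE)
  }
  meta <- snap$samples
  lfc_tbl <- purrr::map_dfr(unique(meta$genotype), function(g) {
    ld <- meta$sample_id[meta$genotype == g & meta$photoperiod == "LD"]
    sd_ <- meta$sample_id[meta$genotype == g & meta$photoperiod == "SD"]
    if (length(ld) == 0 || length(sd_) == 0) {
      stop("genotype ", g, " is missing one photoperiod", call. = FALSE)
    }
    present <- intersect(genes$gene_id, rownames(snap$expression))
    x <- snap$expression[present, , drop = FALSE]
    tibble::tibble(
      genotype = g,
      gene_id = present,
      lfc = rowMeans(x[, ld, drop = FALSE]) -
        rowMeans(x[, sd_, drop = FALSE])
    )
  })
  lfc_tbl <- dplyr::inner_join(lfc_tbl, genes[, c("gene_id", "phase")],
                               by = "gene_id")
  if (!is.null(de_table)) {
    lfc_tbl <- dplyr::left_join(
      lfc_tbl,
      de_table[, c("gene_id", "genotype", "significant")],
      by = c("gene_id", "genotype")
    ) |>
      dplyr::mutate(significant = dplyr::coalesce(.data$significant, FALSE))
  }
  out <- lfc_tbl |>
    dplyr::group_by(.data$genotype, .data$phase) |>
    dplyr::summarise(
      mean_lfc = mean(.data$lfc),
      se = stats::sd(.data$lfc) / sqrt(dplyr::n()),
      n_genes = dplyr::n(),
      n_up = if (!is.null(de_table))
        sum(.data$significant & .data$lfc > 0) else NA_integer_,
      n_down = if (!is.null(de_table))
        sum(.data$significant & .data$lfc < 0) else NA_integer_,
      .groups = "drop"
    ) |>
    tidyr::complete(
      genotype = unique(lfc_tbl$genotype), phase = 0:23,
      fill = list(n_genes = 0L)
    ) |>
    dplyr::arrange(.data$genotype, .data$phase)
  if (is.null(de_table)) out$n_up <- out$n_down <- NULL
  class(out) <- c("phase_binned_foldchange", class(out))
  out
}

#' Per-gene photoperiod differential-expression stand-in
#'
#' A simple two-group contrast for synthetic runs: per gene and genotype, a
#' two-sided Welch t-test of long-day versus short-day log-scale values,
#' BH-adjusted across genes within each genotype. The log2 fold change is
#' `mean LD - mean SD`.
#'
#' @param snap A `snapshot_experiment` with log-scale expression and at
#'   least 2 replicates per photoperiod.
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @return Tibble with `gene_id`, `genotype`, `lfc`, `statistic`, `df`,
#'   `p_value`, `q_value`, `significant`.
#' @export
de_stand_in <- function(snap, alpha = 0.05) {
  stopifnot(inherits(snap, "snapshot_experiment"))
  if (!isTRUE(snap$log_scale)) {
    stop("the DE stand-in expects log-scale expression", call. = FALSE)
  }
  meta <- snap$samples
  purrr::map_dfr(unique(meta$genotype), function(g) {
    ld <- meta$sample_id[meta$genotype == g & meta$photoperiod == "LD"]
    sd_ <- meta$sample_id[meta$genotype == g & meta$photoperiod == "SD"]
    if (length(ld) < 2 || length(sd_) < 2) {
      stop("genotype ", g, " has fewer than 2 replicates per photoperiod",
           call. = FALSE)
    }
    x1 <- snap$expression[, ld, drop = FALSE]
    x2 <- snap$expression[, sd_, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
    n1 <- ncol(x1); n2 <- ncol(x2)
    se2 <- v1 / n1 + v2 / n2
    stat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(stat), df)
    # degenerate rows: no within-group variance
    zero <- se2 == 0
    p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
    stat[zero & m1 == m2] <- 0
    q <- stats::p.adjust(p, method = "BH")
    tibble::tibble(
      gene_id = rownames(snap$expression),
      genotype = g,
      lfc = m1 - m2,
      statistic = stat,
      df = df,
      p_value = p,
      q_value = q,
      significant = q < alpha
    )
  })
}
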