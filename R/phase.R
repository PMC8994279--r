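#' Estimate each sample's internal circadian phase from one time point
#'
#' The molecular-timetable estimator: for a single sample, the z-scored
#' expression of phase-annotated cycling genes, viewed as a function of the
#' genes' acrophase bins, traces a cosine peaking at the sample's internal
#' time. Each sample (biological replicate) is therefore summarised by a
#' fixed-period cosinor fit with `t` = gene phase bin (hours) and `y` =
#' gene z-score; the fitted acrophase is the sample's internal-phase
#' estimate.
#'
#' @param z Gene x sample z matrix from [zscore_genes()].
#' @param genes Cycling-gene table (`gene_id`, `phase`) covering at least
#'   3 distinct phase bins among the genes present in `z`.
#' @param samples Sample metadata tibble (`sample_id`, `genotype`,
#'   `photoperiod`, `replicate`).
#' @param period_h Assumed period in hours (default 24).
#' @return Tibble with one row per sample: identifiers plus `acrophase_h`
#'   (in `[0, period_h)`), `amplitude`, `phase_se`, `r_squared`, `n_genes`
#'   and a `flagged` column marking samples whose z-profile is flat
#'   (acrophase undefined).
#' @export
estimate_sample_phase <- function(z, genes, samples, period_h = 24) {
  stopifnot(is.matrix(z))
  phase_of <- genes$phase[match(rownames(z), genes$gene_id)]
  if (any(is.na(phase_of))) {
    stop("z matrix contains genes without a phase bin", call. = FALSE)
  }
  if (length(unique(phase_of)) < 3) {
    stop("need cycling genes in at least 3 distinct phase bins",
         call. = FALSE)
  }
  res <- purrr::map_dfr(seq_len(ncol(z)), function(j) {
    fit <- fit_cosinor(phase_of, z[, j], period_h = period_h)
    tibble::tibble(
      sample_id = colnames(z)[j],
      acrophase_h = fit$acrophase_h,
      amplitude = fit$amplitude,
      phase_se = fit$se[["acrophase"]],
      r_squared = fit$r_squared,
      n_genes = fit$n_points,
      flagged = fit$flat || is.na(fit$acrophase_h)
    )
  })
  dplyr::left_join(samples, res, by = "sample_id")
}

#' Photoperiod phase-shift analysis by two-way ANOVA
#'
#' Tests how photoperiod and genotype move the internal circadian phase
#' estimated per replicate by [estimate_sample_phase()]. Acrophases are
#' first unwrapped around their grand circular mean (each value shifted by
#' a multiple of the period to lie within half a period of the mean), so
#' ordinary linear modelling applies; the model is
#' `phase ~ genotype * photoperiod`. Per-genotype long-day minus short-day
#' contrasts come from estimated marginal means with multiplicity
#' adjustment across genotypes, and a compact letter display over all
#' genotype x photoperiod cells is built from Tukey all-pairs comparisons.
#'
#' @param phases Tibble from [estimate_sample_phase()]; flagged samples are
#'   dropped. Needs >= 2 replicates in every genotype x photoperiod cell.
#' @param period_h Period used for unwrapping (default 24).
#' @param alpha Significance level for the letter display (default 0.05).
#' @param adjust Multiplicity adjustment for the per-genotype contrasts
#'   (default `"sidak"`; any method accepted by `emmeans`).
#' @return Object of class `phase_shift_result`: a list with `shifts`
#'   (tibble: per-genotype `dphi_h` = LD - SD, `se`, `df`, `conf_low`,
#'   `conf_high`, `t`, `p_value`), `anova` (tidied two-way ANOVA table),
#'   `letters` (per-cell marginal mean and letter), `mean_shift_h` (the
#'   average of the per-genotype shifts), `main_effect` (the overall
#'   photoperiod contrast: estimate, SE, p), and the fitted `model`.
#' @export
phase_shift_anova <- function(phases, period_h = 24, alpha = 0.05,
                              adjust = "sidak") {
  need <- c("genotype", "photoperiod", "acrophase_h")
  if (!all(need %in% names(phases))) {
    stop("`phases` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d <- phases
  if ("flagged" %in% names(d)) d <- d[!d$flagged, , drop = FALSE]
  d <- d[is.finite(d$acrophase_h), , drop = FALSE]

  cells <- tidyr::expand_grid(
    genotype = unique(d$genotype),
    photoperiod = c("SD", "LD")
  )
  counts <- d |>
    dplyr::count(.data$genotype, .data$photoperiod)
  cells <- dplyr::left_join(cells, counts,
                            by = c("genotype", "photoperiod")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  bad <- cells[cells$n < 2, , drop = FALSE]
  if (nrow(bad) > 0) {
    stop("fewer than 2 usable replicates in cell(s): ",
         paste(paste(bad$genotype, bad$photoperiod, sep = ":"),
               collapse = ", "),
         call. = FALSE)
  }

  centre <- circular_mean(d$acrophase_h, period_h)
  d$phase_unwrapped <- centre + circular_diff(d$acrophase_h, centre,
                                              period_h)
  d$genotype <- factor(d$genotype)
  d$photoperiod <- factor(d$photoperiod, levels = c("SD", "LD"))

  model <- stats::aov(phase_unwrapped ~ genotype * photoperiod, data = d)
  anova_tbl <- tidy_aov(model)

  emm <- emmeans::emmeans(model, ~ photoperiod | genotype)
  ct <- summary(
    emmeans::contrast(emm, method = "revpairwise"),
    adjust = adjust, by = NULL, infer = c(TRUE, TRUE), level = 1 - alpha
  )
  shifts <- tibble::tibble(
    genotype = as.character(ct$genotype),
    dphi_h = circular_diff(ct$estimate, 0, period_h),
    se = ct$SE,
    df = ct$df,
    conf_low = ct$lower.CL,
    conf_high = ct$upper.CL,
    t = ct$t.ratio,
    p_value = ct$p.value
  )

  # averaging over the genotype x photoperiod interaction is intentional:
  # the overall photoperiod contrast is the design's headline quantity
  emm_main <- suppressMessages(emmeans::emmeans(model, ~ photoperiod))
  mc <- summary(emmeans::contrast(emm_main, method = "revpairwise"))
  main_effect <- tibble::tibble(
    estimate = mc$estimate, se = mc$SE, df = mc$df,
    t = mc$t.ratio, p_value = mc$p.value
  )

  letters_tbl <- cell_letters(d, alpha)

  structure(
    list(
      shifts = shifts,
      anova = anova_tbl,
      letters = letters_tbl,
      mean_shift_h = mean(shifts$dphi_h),
      main_effect = main_effect,
      model = model,
      period_h = period_h,
      alpha = alpha
    ),
    class = "phase_shift_result"
  )
}

# Tukey all-pairs compact letter display over genotype x photoperiod cells.
cell_letters <- function(d, alpha) {
  d$cell <- interaction(d$genotype, d$photoperiod, drop = TRUE, sep = "\r")
  lookup <- dplyr::distinct(d, .data$cell, .data$genotype,
                            .data$photoperiod)
  m <- stats::aov(phase_unwrapped ~ cell, data = d)
  glht <- multcomp::glht(m, linfct = multcomp::mcp(cell = "Tukey"))
  cld <- multcomp::cld(glht, level = alpha)
  lt <- cld$mcletters$Letters
  means <- tapply(d$phase_unwrapped, d$cell, mean)
  tibble::tibble(
    cell = names(lt),
    mean_phase_h = as.numeric(means[names(lt)]),
    letter = unname(lt)
  ) |>
    dplyr::left_join(
      dplyr::mutate(lookup, cell = as.character(.data$cell)),
      by = "cell"
    ) |>
    dplyr::mutate(genotype = as.character(.data$genotype),
                  photoperiod = as.character(.data$photoperiod)) |>
    dplyr::select("genotype", "photoperiod", "mean_phase_h", "letter")
}

tidy_aov <- function(model) {
  s <- summary(model)[[1]]
  tibble::tibble(
    term = trimws(rownames(s)),
    df = s$Df,
    sumsq = s$`Sum Sq`,
    meansq = s$`Mean Sq`,
    statistic = s$`F value`,
    p_value = s$`Pr(>F)`
  )
}

#' @exportS3Method base::print
print.phase_shift_result <- function(x, ...) {
  cat("Photoperiod phase shift (LD - SD), period", x$period_h, "h\n")
  cat(sprintf("  mean shift over genotypes: %.3f h\n", x$mean_shift_h))
  cat(sprintf("  photoperiod main effect: %.3f h (p = %.3g)\n",
              x$main_effect$estimate, x$main_effect$p_value))
  print(x$shifts)
  invisible(x)
}

#' Tidy a phase-shift result
#'
#' Per-genotype long-day minus short-day phase contrasts.
#'
#' @param x A `phase_shift_result`.
#' @param ... Unused.
#' @export
tidy.phase_shift_result <- function(x, ...) x$shifts

#' Glance at a phase-shift result
#'
#' One-row summary: mean shift, photoperiod main effect, and the ANOVA
#' p-values for photoperiod, genotype and their interaction.
#'
#' @param x A `phase_shift_result`.
#' @param ... Unused.
#' @export
glance.phase_shift_result <- function(x, ...) {
  p_of <- function(term) {
    i <- match(term, x$anova$term)
    if (is.na(i)) NA_real_ else x$anova$p_value[i]
  }
  tibble::tibble(
    mean_shift_h = x$mean_shift_h,
    main_effect_h = x$main_effect$estimate,
    p_photoperiod = p_of("photoperiod"),
    p_genotype = p_of("genotype"),
    p_interaction = p_of("genotype:photoperiod")
  )
}
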