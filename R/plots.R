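#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot molecular-timetable curves
#'
#' Mean z-score of cycling genes per phase bin, one line per photoperiod,
#' facetted by genotype, with standard-error ribbons. The peak of each
#' curve sits near the group's internal circadian time.
#'
#' @param object A `timetable_curve` tibble from [timetable_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.timetable_curve <- function(object, ...) {
  if (!"photoperiod" %in% names(object)) object$photoperiod <- "all"
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$phase, y = .data$mean_z,
                 colour = .data$photoperiod, group = .data$photoperiod)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_z - .data$se,
                   ymax = .data$mean_z + .data$se,
                   fill = .data$photoperiod),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 1, na.rm = TRUE) +
    ggplot2::labs(x = "acrophase bin (ZT, h)", y = "mean z-score",
                  colour = "photoperiod", fill = "photoperiod") +
    ggplot2::theme_minimal()
  if ("genotype" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~genotype)
  }
  p
}

#' Plot phase-binned photoperiod fold changes
#'
#' Mean long-day vs short-day log2 fold change per acrophase bin,
#' facetted by genotype.
#'
#' @param object A `phase_binned_foldchange` tibble from
#'   [foldchange_by_phase()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_binned_foldchange <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$phase, y = .data$mean_lfc)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_lfc - .data$se,
                   ymax = .data$mean_lfc + .data$se),
      alpha = 0.2
    ) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::labs(x = "acrophase bin (ZT, h)",
                  y = "mean log2 fold change (LD vs SD)") +
    ggplot2::theme_minimal()
}

#' Plot a cosinor fit
#'
#' Observed points with the fitted cosine overlaid.
#'
#' @param object A `cosinor_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cosinor_fit <- function(object, ...) {
  grid <- tibble::tibble(
    t = seq(min(object$data$t), max(object$data$t), length.out = 200)
  )
  grid$y <- predict(object, grid$t)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "time (h)", y = "value") +
    ggplot2::theme_minimal()
}

#' Plot a leaf-movement rhythm fit
#'
#' Detrended trace with the fitted damped cosine.
#'
#' @param object A `rhythm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rhythm_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_h,
                                    y = .data$position)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::labs(x = "time in constant light (h)",
                  y = "leaf position (detrended)") +
    ggplot2::theme_minimal()
  if (!object$arrhythmic && is.finite(object$period_h)) {
    grid <- tibble::tibble(
      time_h = seq(min(object$data$time_h), max(object$data$time_h),
                   length.out = 400)
    )
    grid$position <- object$amplitude *
      exp(-object$damping * grid$time_h) *
      cos(2 * pi * (grid$time_h - object$phase_h) / object$period_h)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Plot windowed heterozygosity with called segments
#'
#' Heterozygous-call fraction along each chromosome with introgression
#' segments highlighted.
#'
#' @param windows Tibble from [window_het_fraction()].
#' @param segments Optional tibble from [call_segments()].
#' @return A ggplot object.
#' @export
plot_het_windows <- function(windows, segments = NULL) {
  windows <- dplyr::mutate(windows, mid = (.data$start + .data$end) / 2)
  p <- ggplot2::ggplot(windows,
                       ggplot2::aes(x = .data$mid / 1e6,
                                    y = .data$het_fraction)) +
    ggplot2::geom_line(colour = "firebrick", na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (Mb)", y = "heterozygous SNP fraction") +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0) {
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "steelblue", alpha = 0.2
    )
  }
  p
}
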