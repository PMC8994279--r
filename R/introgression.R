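#' Read genotype calls from a single-sample VCF
#'
#' Parses a VCF with `vcfR` and classifies each site's genotype call as
#' `hom_ref`, `het`, `hom_alt` or `missing` (phased and unphased separators
#' are both accepted). Only the first sample column is used.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @param sample Sample name; defaults to the first sample in the file.
#' @return Tibble with columns `chrom`, `pos` (1-based), `genotype`
#'   (factor: hom_ref / het / hom_alt / missing), ordered by position
#'   within chromosome.
#' @export
read_variants <- function(path, sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(sample)) sample <- colnames(gt)[1]
  if (!sample %in% colnames(gt)) {
    stop("sample ", sample, " not found in VCF", call. = FALSE)
  }
  calls <- classify_gt(gt[, sample])
  tibble::tibble(
    chrom = vcfR::getCHROM(vcf),
    pos = as.integer(vcfR::getPOS(vcf)),
    genotype = calls
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

classify_gt <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  out <- vapply(alleles, function(a) {
    if (length(a) < 2 || anyNA(a) || any(a == ".")) return("missing")
    if (a[1] != a[2]) return("het")
    if (a[1] == "0") return("hom_ref")
    "hom_alt"
  }, character(1))
  out[is.na(gt)] <- "missing"
  factor(out, levels = c("hom_ref", "het", "hom_alt", "missing"))
}

#' Heterozygous-call fraction in consecutive SNP windows
#'
#' Splits each chromosome's sites into non-overlapping windows of
#' `window_snps` consecutive variants (the last window may be short) and
#' computes the fraction of heterozygous calls among non-missing calls per
#' window. Runs of elevated heterozygosity in an otherwise homozygous
#' near-isogenic line mark donor introgressions.
#'
#' @param variants Tibble from [read_variants()] (columns `chrom`, `pos`,
#'   `genotype`), positions non-decreasing within chromosome.
#' @param window_snps Number of SNPs per window (>= 1; e.g. 1000 for a
#'   genome-wide scan, 100 for a zoomed view).
#' @return Tibble with `chrom`, `window` (index within chromosome),
#'   `start`, `end` (1-based inclusive), `n_sites`, `n_used` (non-missing),
#'   `het_fraction` (`NA` when a window has no usable call).
#' @export
window_het_fraction <- function(variants, window_snps = 1000) {
  if (!is.numeric(window_snps) || window_snps < 1) {
    stop("`window_snps` must be >= 1", call. = FALSE)
  }
  window_snps <- as.integer(window_snps)
  need <- c("chrom", "pos", "genotype")
  if (!all(need %in% names(variants))) {
    stop("`variants` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(variants) == 0) {
    message("empty variant table; no windows produced")
  }
  variants |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(window = (dplyr::row_number() - 1L) %/% window_snps) |>
    dplyr::group_by(.data$chrom, .data$window) |>
    dplyr::summarise(
      start = min(.data$pos),
      end = max(.data$pos),
      n_sites = dplyr::n(),
      n_used = sum(.data$genotype != "missing"),
      het_fraction = {
        used <- sum(.data$genotype != "missing")
        if (used > 0) sum(.data$genotype == "het") / used else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$window)
}

#' Call introgression segments from windowed heterozygosity
#'
#' Merges maximal runs of at least `min_windows` consecutive windows whose
#' heterozygous fraction reaches `threshold` into segments. Windows with
#' `NA` fractions break runs.
#'
#' @param windows Tibble from [window_het_fraction()].
#' @param threshold Minimum het fraction for a window to count, in
#'   `(0, 1]` (default 0.5).
#' @param min_windows Minimum run length in windows (default 3).
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   `mean_het_fraction`, `n_windows`; empty when nothing passes.
#' @export
call_segments <- function(windows, threshold = 0.5, min_windows = 3) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  }
  out <- windows |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      hit <- !is.na(df$het_fraction) & df$het_fraction >= threshold
      r <- rle(hit)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_windows
      if (!any(keep)) {
        return(tibble::tibble(
          start = integer(), end = integer(),
          mean_het_fraction = numeric(), n_windows = integer()
        ))
      }
      purrr::map_dfr(which(keep), function(i) {
        idx <- starts[i]:ends[i]
        tibble::tibble(
          start = df$start[idx[1]],
          end = df$end[idx[length(idx)]],
          mean_het_fraction = mean(df$het_fraction[idx]),
          n_windows = length(idx)
        )
      })
    }) |>
    dplyr::ungroup()
  out
}

#' Write introgression segments as BED
#'
#' BED uses 0-based, half-open coordinates, so `start - 1` and `end` are
#' written for 1-based inclusive segments.
#'
#' @param segments Tibble from [call_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(
    chrom = segments$chrom,
    start = segments$start - 1L,
    end = segments$end,
    name = sprintf("introgression_%d", seq_len(nrow(segments))),
    score = round(1000 * segments$mean_het_fraction)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
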