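#' Folded minor-allele-frequency spectrum
#'
#' Bins per-site folded MAF values over `[0, 0.5]` into `bins` equal-width
#' intervals, half-open `[a, b)` except the last which is closed so that
#' `maf = 0.5` is counted. Monomorphic sites fall in the first bin.
#'
#' @param g genotype table (or a tibble already carrying a `maf` column).
#' @param bins number of bins (default 50).
#' @param label dataset label carried into plots.
#' @return a tibble of class `maf_spectrum` with `bin_low`, `bin_high`,
#'   `n_sites`; the per-site MAF vector is the `"maf"` attribute.
#' @export
maf_spectrum <- function(g, bins = 50, label = "dataset") {
  if (!("maf" %in% names(g))) g <- site_stats(g)
  maf <- g$maf
  if (length(maf) == 0) rlang::abort("no sites")
  edges <- seq(0, 0.5, length.out = bins + 1)
  # [a, b) binning with a tolerance so edge values like 0.3 are not shifted
  # by floating-point representation of the bin boundaries
  idx <- pmin(bins, floor(maf / 0.5 * bins + 1e-9) + 1L)
  counts <- tabulate(idx, nbins = bins)
  out <- tibble::tibble(
    bin_low = edges[-length(edges)],
    bin_high = edges[-1],
    n_sites = as.integer(counts)
  )
  attr(out, "maf") <- maf
  attr(out, "label") <- label
  class(out) <- c("maf_spectrum", class(out))
  out
}

#' Ascertainment-bias comparison of two MAF spectra
#'
#' Pairs sites shared between two datasets strictly by
#' `(chrom, pos, ref, alt)` and correlates their folded MAF values (Pearson).
#' This is the per-site mode; `mode = "binned"` instead correlates the two
#' binned spectra (useful when site keys are not comparable across datasets).
#' Typical use: panel genotypes vs the whole-genome callset the panel was
#' designed from, where high correlation indicates limited ascertainment
#' bias.
#'
#' @param a,b genotype tables (or site-stats tibbles with `maf`).
#' @param mode `"per-site"` (default) or `"binned"`.
#' @param bins bins for `mode = "binned"`.
#' @return a `spectrum_comparison` object; see [tidy.spectrum_comparison()]
#'   and [glance.spectrum_comparison()].
#' @export
spectrum_correlation <- function(a, b, mode = c("per-site", "binned"), bins = 50) {
  mode <- match.arg(mode)
  if (!("maf" %in% names(a))) a <- site_stats(a)
  if (!("maf" %in% names(b))) b <- site_stats(b)
  if (mode == "binned") {
    ca <- maf_spectrum(a, bins = bins)$n_sites
    cb <- maf_spectrum(b, bins = bins)$n_sites
    r <- stats::cor(ca, cb)
    res <- list(mode = "binned", pearson_r = r, n_shared = NA_integer_,
                n_a = nrow(a), n_b = nrow(b), pairs = NULL)
  } else {
    key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
    pairs <- dplyr::inner_join(
      tibble::tibble(key = key(a), maf_a = a$maf),
      tibble::tibble(key = key(b), maf_b = b$maf),
      by = "key"
    )
    if (nrow(pairs) < 3) rlang::abort("fewer than 3 shared sites")
    r <- stats::cor(pairs$maf_a, pairs$maf_b)
    res <- list(mode = "per-site", pearson_r = r, n_shared = nrow(pairs),
                n_a = nrow(a), n_b = nrow(b), pairs = pairs)
  }
  structure(res, class = "spectrum_comparison")
}

#' @export
#' @method print spectrum_comparison
print.spectrum_comparison <- function(x, ...) {
  cat("MAF spectrum comparison (", x$mode, " mode)\n", sep = "")
  cat("  Pearson r =", format(x$pearson_r, digits = 4), "\n")
  if (!is.na(x$n_shared)) cat("  shared sites:", x$n_shared, "\n")
  cat("  sites in A:", x$n_a, " in B:", x$n_b, "\n")
  invisible(x)
}

#' Tidy the paired per-site MAF values of a spectrum comparison
#' @param x a `spectrum_comparison`.
#' @param ... unused.
#' @return tibble of shared-site MAF pairs (empty for binned mode).
#' @export
tidy.spectrum_comparison <- function(x, ...) {
  if (is.null(x$pairs)) return(tibble::tibble())
  x$pairs
}

#' One-row summary of a spectrum comparison
#' @param x a `spectrum_comparison`.
#' @param ... unused.
#' @return tibble with `mode`, `pearson_r`, `n_shared`, `n_a`, `n_b`.
#' @export
glance.spectrum_comparison <- function(x, ...) {
  tibble::tibble(mode = x$mode, pearson_r = x$pearson_r,
                 n_shared = x$n_shared, n_a = x$n_a, n_b = x$n_b)
}

#' Spacing between adjacent markers
#'
#' Computes the base-pair gaps between position-adjacent markers within each
#' chromosome (chromosomes with fewer than two markers contribute no gap) and
#' summarises them.
#'
#' @param sites tibble with `chrom` and `pos`.
#' @return one-row tibble with `n_gaps`, `mean_gap`, `median_gap`, `min_gap`,
#'   `max_gap`; the full per-gap tibble is the `"gaps"` attribute.
#' @export
adjacent_spacing <- function(sites) {
  gaps <- tibble::as_tibble(sites[, c("chrom", "pos")]) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::reframe(pos_left = .data$pos[-dplyr::n()],
                   pos_right = .data$pos[-1],
                   gap = diff(.data$pos))
  out <- tibble::tibble(
    n_gaps = nrow(gaps),
    mean_gap = if (nrow(gaps)) mean(gaps$gap) else NA_real_,
    median_gap = if (nrow(gaps)) stats::median(gaps$gap) else NA_real_,
    min_gap = if (nrow(gaps)) min(gaps$gap) else NA_real_,
    max_gap = if (nrow(gaps)) max(gaps$gap) else NA_real_
  )
  attr(out, "gaps") <- gaps
  out
}

#' Per-sample heterozygosity
#'
#' Fraction of heterozygous calls among non-missing calls, per sample.
#' Samples with no called genotype are dropped with a warning.
#'
#' @param g genotype table.
#' @return tibble with `sample`, `n_called`, `n_het`, `het`.
#' @export
sample_heterozygosity <- function(g) {
  assert_geno(g)
  gt <- g$gt
  n_called <- colSums(!is.na(gt))
  n_het <- colSums(gt == 1L, na.rm = TRUE)
  drop <- n_called == 0
  if (any(drop)) {
    rlang::warn(paste0("sample(s) with no called genotype excluded: ",
                       paste(colnames(gt)[drop], collapse = ", ")))
  }
  tibble::tibble(
    sample = colnames(gt)[!drop],
    n_called = as.integer(n_called[!drop]),
    n_het = as.integer(n_het[!drop]),
    het = n_het[!drop] / n_called[!drop]
  )
}
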