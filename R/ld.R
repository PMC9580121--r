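#' Composite linkage disequilibrium between two sites
#'
#' Squared Pearson correlation of genotype dosages (0/1/2) over the samples
#' called at both sites — the standard composite-LD r-squared that needs no
#' phase. Undefined (returned as `NA`) when fewer than two samples are
#' jointly called or either dosage vector is constant on the shared set.
#' Symmetric in its arguments and invariant to allele-coding swaps
#' (`g -> 2 - g`).
#'
#' @param g1,g2 integer dosage vectors with `NA` for missing.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
genotype_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD configuration
#'
#' @param r2_threshold pruning threshold on r-squared (default 0.3).
#' @param window_size sliding-window width in sites (default 50).
#' @param window_step step between window starts in sites (default 5).
#' @param max_decay_dist maximum pair distance for LD decay, bp
#'   (default 100000).
#' @param decay_bin decay distance bin width, bp (default 1000).
#' @param use_r prune on `|r| > sqrt(threshold)`-style absolute correlation
#'   instead of r-squared; when `TRUE` the threshold is compared against
#'   `|r|` directly.
#' @return an `ld_config` list.
#' @export
ld_config <- function(r2_threshold = 0.3, window_size = 50, window_step = 5,
                      max_decay_dist = 1e5, decay_bin = 1000, use_r = FALSE) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, window_step <= window_size)
  structure(list(r2_threshold = r2_threshold, window_size = window_size,
                 window_step = window_step, max_decay_dist = max_decay_dist,
                 decay_bin = decay_bin, use_r = use_r), class = "ld_config")
}

# pairwise LD statistic matrix for a dosage matrix (samples x sites)
ld_stat_matrix <- function(m, use_r = FALSE) {
  suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- NA
  if (use_r) abs(r) else r^2
}

#' Sliding-window LD pruning
#'
#' Scans sites in position order with a window of `window_size` sites moved
#' by `window_step`; within each window, while any retained pair exceeds the
#' threshold, the member with the lower MAF is dropped (tie: the later
#' position). Deterministic, and idempotent: re-pruning the output is a
#' no-op. Missing genotypes are handled with pairwise-complete samples.
#'
#' @param g genotype table (sites position-sorted).
#' @param cfg an [ld_config()].
#' @return the pruned genotype table; kept row indices (into the input) are
#'   the `"kept"` attribute.
#' @export
ld_prune <- function(g, cfg = ld_config()) {
  assert_geno(g)
  st <- site_stats(g)
  maf <- st$maf
  keep <- rep(TRUE, nrow(g))
  # iterate the windowed scan to a fixpoint: windows are laid over the
  # *currently kept* sites, so the output survives a re-scan unchanged
  repeat {
    changed <- FALSE
    for (chr in unique(g$chrom)) {
      idx <- which(g$chrom == chr & keep)
      if (length(idx) < 2) next
      starts <- seq(1, max(1, length(idx) - 1), by = cfg$window_step)
      for (s in starts) {
        win <- idx[s:min(s + cfg$window_size - 1, length(idx))]
        win <- win[keep[win]]
        if (length(win) < 2) next
        m <- t(g$gt[win, , drop = FALSE])
        ld <- ld_stat_matrix(m, use_r = cfg$use_r)
        repeat {
          alive <- keep[win]
          sub <- ld[alive, alive, drop = FALSE]
          prs <- which(upper.tri(sub) & sub > cfg$r2_threshold, arr.ind = TRUE)
          if (nrow(prs) == 0) break
          prs <- prs[order(prs[, 1], prs[, 2]), , drop = FALSE]
          i <- win[alive][prs[1, 1]]
          j <- win[alive][prs[1, 2]]
          drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else max(i, j)
          keep[drop] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- g[keep, , drop = FALSE]
  attr(out, "kept") <- which(keep)
  out
}

#' LD decay over physical distance
#'
#' All within-chromosome site pairs up to `max_decay_dist` apart are binned
#' by distance; mean r-squared and pair count are reported per bin. In a
#' randomly mating population with recombination the per-bin mean decays
#' towards the unlinked baseline with distance.
#'
#' @param g genotype table.
#' @param cfg an [ld_config()].
#' @return tibble with `dist_low`, `dist_high` (bp, half-open bins),
#'   `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(g, cfg = ld_config()) {
  assert_geno(g)
  res <- list()
  for (chr in unique(g$chrom)) {
    idx <- which(g$chrom == chr)
    if (length(idx) < 2) next
    pos <- g$pos[idx]
    for (a in seq_len(length(idx) - 1)) {
      b <- a + 1
      while (b <= length(idx) && pos[b] - pos[a] <= cfg$max_decay_dist) {
        r2 <- genotype_r2(g$gt[idx[a], ], g$gt[idx[b], ])
        res[[length(res) + 1]] <- c(d = pos[b] - pos[a], r2 = r2)
        b <- b + 1
      }
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(dist_low = numeric(), dist_high = numeric(),
                          mean_r2 = numeric(), n_pairs = integer()))
  }
  m <- do.call(rbind, res)
  bin <- floor(m[, "d"] / cfg$decay_bin)
  tibble::tibble(bin = bin, d = m[, "d"], r2 = m[, "r2"]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_r2 = mean(.data$r2, na.rm = TRUE),
                     n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::transmute(dist_low = .data$bin * cfg$decay_bin,
                     dist_high = (.data$bin + 1) * cfg$decay_bin,
                     mean_r2 = .data$mean_r2,
                     n_pairs = .data$n_pairs) |>
    dplyr::arrange(.data$dist_low)
}
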