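# Gamete model for a biallelic locus: a parent with dosage 0 transmits only
# the reference allele, dosage 2 only the alternate, a heterozygote either
# with probability 1/2.
gamete_alleles <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)

# allowed[p1+1, p2+1, off+1]: is the offspring dosage producible from one
# gamete of each parent?
mendel_allowed <- local({
  a <- array(FALSE, dim = c(3, 3, 3))
  for (p1 in 0:2) for (p2 in 0:2) {
    offs <- unique(outer(gamete_alleles[[p1 + 1]], gamete_alleles[[p2 + 1]], `+`))
    a[p1 + 1, p2 + 1, offs + 1] <- TRUE
  }
  a
})

#' Classify markers into pseudo-testcross (CP) configurations
#'
#' For an outbreeding F1 cross, markers are labelled by which parent is
#' heterozygous: `lmxll` (seed parent het, pollen parent hom), `nnxnp`
#' (pollen parent het), `hkxhk` (both het), `aaxbb` (parents homozygous for
#' opposite alleles), `monomorphic` (parents homozygous for the same allele),
#' or `missing_parent`.
#'
#' @param g_p1,g_p2 parental dosage vectors (0/1/2, `NA` missing); `g_p1` is
#'   the seed parent.
#' @return factor of CP codes, same length as the inputs.
#' @export
classify_cp_marker <- function(g_p1, g_p2) {
  stopifnot(length(g_p1) == length(g_p2))
  code <- rep("missing_parent", length(g_p1))
  ok <- !is.na(g_p1) & !is.na(g_p2)
  hom1 <- ok & g_p1 != 1L
  hom2 <- ok & g_p2 != 1L
  code[ok & g_p1 == 1L & hom2] <- "lmxll"
  code[ok & hom1 & g_p2 == 1L] <- "nnxnp"
  code[ok & g_p1 == 1L & g_p2 == 1L] <- "hkxhk"
  code[hom1 & hom2 & g_p1 == g_p2] <- "monomorphic"
  code[hom1 & hom2 & g_p1 != g_p2] <- "aaxbb"
  factor(code, levels = c("lmxll", "nnxnp", "hkxhk", "aaxbb",
                          "monomorphic", "missing_parent"))
}

#' Mendelian consistency of offspring calls
#'
#' An offspring genotype is consistent iff it can be formed from one gamete
#' of each parent (unphased). Any missing call among the three genotypes
#' makes the trio `unchecked`. Vectorised over markers/calls.
#'
#' @param g_p1,g_p2 parental dosages.
#' @param g_off offspring dosages (recycled shapes must match).
#' @return character vector in `{"consistent", "inconsistent", "unchecked"}`.
#' @export
mendelian_check <- function(g_p1, g_p2, g_off) {
  n <- max(length(g_p1), length(g_p2), length(g_off))
  g_p1 <- rep_len(g_p1, n); g_p2 <- rep_len(g_p2, n); g_off <- rep_len(g_off, n)
  out <- rep("unchecked", n)
  ok <- !is.na(g_p1) & !is.na(g_p2) & !is.na(g_off)
  out[ok] <- ifelse(mendel_allowed[cbind(g_p1[ok] + 1L, g_p2[ok] + 1L,
                                         g_off[ok] + 1L)],
                    "consistent", "inconsistent")
  out
}

# canonical parental genotypes per CP code (detectability depends only on
# the producible offspring set and the true offspring distribution, both
# invariant under allele relabelling)
cp_canonical_parents <- list(
  lmxll = c(1L, 0L), nnxnp = c(0L, 1L), hkxhk = c(1L, 1L),
  aaxbb = c(0L, 2L), monomorphic = c(0L, 0L)
)

#' Probability that a genotyping error is detectable as a Mendelian
#' inconsistency
#'
#' For a given CP configuration, enumerates the Mendelian distribution of
#' true offspring genotypes, every erroneous observation the error model can
#' produce, and whether [mendelian_check()] would flag it. Under the
#' `"uniform_swap"` model an erroneous call is replaced by one of the two
#' other dosage classes with equal probability (errors occur at any call);
#' under `"allelic_dropout"` a heterozygote is miscalled as either homozygote
#' with equal probability (errors occur only at heterozygous calls, so codes
#' whose offspring are never heterozygous have no error mass and return
#' `NaN`).
#'
#' @param code a CP code (see [classify_cp_marker()]); `missing_parent` is an
#'   error.
#' @param error_model `"uniform_swap"` (default) or `"allelic_dropout"`.
#' @return probability in `[0, 1]` (`NaN` where the model admits no error).
#' @export
detectable_fraction <- function(code, error_model = c("uniform_swap", "allelic_dropout")) {
  error_model <- match.arg(error_model)
  code <- as.character(code)
  if (length(code) > 1) {
    return(vapply(code, detectable_fraction, numeric(1),
                  error_model = error_model, USE.NAMES = FALSE))
  }
  par <- cp_canonical_parents[[code]]
  if (is.null(par)) rlang::abort(paste0("no detectability for code: ", code))
  p1g <- gamete_alleles[[par[1] + 1]]
  p2g <- gamete_alleles[[par[2] + 1]]
  true_dist <- table(factor(outer(p1g, p2g, `+`), levels = 0:2))
  true_dist <- as.numeric(true_dist) / sum(true_dist)
  producible <- which(true_dist > 0) - 1L
  num <- 0; den <- 0
  for (g in 0:2) {
    if (true_dist[g + 1] == 0) next
    wrong <- switch(error_model,
      uniform_swap = setdiff(0:2, g),
      allelic_dropout = if (g == 1L) c(0L, 2L) else integer(0)
    )
    if (length(wrong) == 0) next
    p_err_given_g <- 1  # conditional on an error occurring at this call
    den <- den + true_dist[g + 1] * p_err_given_g
    num <- num + true_dist[g + 1] * p_err_given_g *
      mean(!(wrong %in% producible))
  }
  if (den == 0) return(NaN)
  num / den
}

#' Assemble an F1 cross dataset
#'
#' Splits a genotype table into the two parents and the offspring and
#' attaches per-marker CP codes.
#'
#' @param g genotype table containing both parents and all offspring.
#' @param parent1,parent2 sample ids of the seed and pollen parent.
#' @return a `cross_dataset` list: `sites` tibble, `p1`/`p2` dosage vectors,
#'   `off` offspring dosage matrix (markers x offspring), `code` factor.
#' @export
cross_dataset <- function(g, parent1, parent2) {
  assert_geno(g)
  ids <- geno_samples(g)
  if (!all(c(parent1, parent2) %in% ids)) rlang::abort("parent id not found among samples")
  off_ids <- setdiff(ids, c(parent1, parent2))
  if (length(off_ids) == 0) rlang::abort("no offspring samples")
  p1 <- g$gt[, parent1]
  p2 <- g$gt[, parent2]
  site_cols <- intersect(c("chrom", "pos", "ref", "alt"), names(g))
  structure(list(
    sites = tibble::as_tibble(as.data.frame(g)[, site_cols]),
    p1 = p1, p2 = p2,
    off = g$gt[, off_ids, drop = FALSE],
    code = classify_cp_marker(p1, p2),
    p1_id = parent1, p2_id = parent2
  ), class = "cross_dataset")
}

#' @export
#' @method print cross_dataset
print.cross_dataset <- function(x, ...) {
  cat("F1 cross dataset:", nrow(x$off), "markers x", ncol(x$off), "offspring\n")
  cat("  parents:", x$p1_id, "x", x$p2_id, "\n")
  print(table(x$code))
  invisible(x)
}

#' Genotyping-error rate from Mendelian inconsistencies
#'
#' Checks every (marker, offspring) call with both parents and the offspring
#' called — segregating and monomorphic markers alike — against the set of
#' genotypes producible from parental gametes. The raw rate is
#' inconsistent / checked. Because some error classes are invisible (nothing
#' is inconsistent under an hk x hk marker; half of the possible wrong states
#' at an lm x ll marker remain consistent), the raw rate underestimates the
#' true per-call error rate; the detectability-adjusted rate divides by the
#' checked-call-weighted mean of the per-code detectable fractions
#' ([detectable_fraction()]). The singleton fraction — the share of flagged
#' markers with exactly one inconsistent offspring — is reported as a
#' diagnostic for isolated random miscalls versus systematic marker failure.
#'
#' @param cross a [cross_dataset()].
#' @param error_model passed to [detectable_fraction()].
#' @return an `error_estimate` object with `n_checked`, `n_inconsistent`,
#'   `raw_rate`, `detectable_fraction`, `adjusted_rate`,
#'   `singleton_fraction` and a per-code breakdown; see tidy()/glance()
#'   methods.
#' @export
estimate_error_rate <- function(cross, error_model = c("uniform_swap", "allelic_dropout")) {
  error_model <- match.arg(error_model)
  stopifnot(inherits(cross, "cross_dataset"))
  checked <- !is.na(cross$off) & !is.na(cross$p1) & !is.na(cross$p2)
  if (!any(checked)) rlang::abort("no checkable (marker, offspring) call")
  allowed_site <- mendel_allowed[cbind(
    rep(cross$p1 + 1L, 3), rep(cross$p2 + 1L, 3),
    rep(0:2 + 1L, each = length(cross$p1)))]
  dim(allowed_site) <- c(length(cross$p1), 3)  # marker x offspring dosage
  off <- cross$off
  incons <- matrix(FALSE, nrow(off), ncol(off))
  ok <- checked & !is.na(off)
  incons[ok] <- !allowed_site[cbind(row(off)[ok], off[ok] + 1L)]
  n_checked <- sum(checked)
  n_incons <- sum(incons & checked)

  per_site_checked <- rowSums(checked)
  per_site_incons <- rowSums(incons & checked)
  by_code <- tibble::tibble(code = cross$code,
                            n_checked = per_site_checked,
                            n_incons = per_site_incons) |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     n_checked = sum(.data$n_checked),
                     n_inconsistent = sum(.data$n_incons), .groups = "drop") |>
    dplyr::filter(.data$code != "missing_parent" | .data$n_checked > 0)
  by_code$detectable <- detectable_fraction(as.character(by_code$code),
                                            error_model = error_model)
  w <- by_code$n_checked
  d <- by_code$detectable
  usable <- w > 0 & !is.na(d) & !is.nan(d)
  det <- sum(w[usable] * d[usable]) / sum(w[usable])
  raw <- n_incons / n_checked
  adjusted <- if (is.finite(det) && det > 0) raw / det else NA_real_
  if (!is.finite(det) || det == 0) {
    rlang::warn("detectable fraction is zero; adjusted rate undefined")
  }
  flagged <- per_site_incons[per_site_incons > 0]
  structure(list(
    n_checked = n_checked, n_inconsistent = n_incons,
    raw_rate = raw, detectable_fraction = det, adjusted_rate = adjusted,
    singleton_fraction = if (length(flagged)) mean(flagged == 1) else NA_real_,
    error_model = error_model, by_code = by_code
  ), class = "error_estimate")
}

#' @export
#' @method print error_estimate
print.error_estimate <- function(x, ...) {
  cat("Mendelian-inconsistency error estimate (", x$error_model, ")\n", sep = "")
  cat(sprintf("  checked calls: %d, inconsistent: %d\n", x$n_checked, x$n_inconsistent))
  cat(sprintf("  raw rate: %.4f  detectable fraction: %.3f  adjusted rate: %.4f\n",
              x$raw_rate, x$detectable_fraction, x$adjusted_rate))
  cat(sprintf("  singleton fraction among flagged markers: %.3f\n",
              x$singleton_fraction))
  invisible(x)
}

#' Per-CP-code breakdown of an error estimate
#' @param x an `error_estimate`.
#' @param ... unused.
#' @return tibble with per-code marker counts, checked/inconsistent calls and
#'   detectable fraction.
#' @export
tidy.error_estimate <- function(x, ...) x$by_code

#' One-row summary of an error estimate
#' @param x an `error_estimate`.
#' @param ... unused.
#' @return one-row tibble of the headline rates.
#' @export
glance.error_estimate <- function(x, ...) {
  tibble::tibble(n_checked = x$n_checked, n_inconsistent = x$n_inconsistent,
                 raw_rate = x$raw_rate, detectable_fraction = x$detectable_fraction,
                 adjusted_rate = x$adjusted_rate,
                 singleton_fraction = x$singleton_fraction,
                 error_model = x$error_model)
}

#' Chi-square test for segregation distortion at a 1:1 marker
#'
#' Goodness-of-fit of the two producible offspring classes of an `lmxll` or
#' `nnxnp` marker against the expected 1:1 ratio (df = 1), on non-missing
#' counts.
#'
#' @param n1,n2 observed counts of the two offspring classes.
#' @param alpha significance level for the `distorted` flag (default 0.05,
#'   flagged at `p <= alpha`).
#' @return one-row tibble with `chisq`, `df`, `p_value`, `distorted`.
#' @export
segregation_distortion <- function(n1, n2, alpha = 0.05) {
  if (n1 + n2 == 0) rlang::abort("zero total count")
  e <- (n1 + n2) / 2
  chisq <- (n1 - e)^2 / e + (n2 - e)^2 / e
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  tibble::tibble(chisq = chisq, df = 1L, p_value = p, distorted = p <= alpha)
}

#' Segregation-distortion scan over a cross
#'
#' Applies [segregation_distortion()] to every single-parent-heterozygous
#' (`lmxll` / `nnxnp`) marker. The two counted classes are the producible
#' offspring genotypes of the configuration; non-producible (Mendelian
#' inconsistent) offspring calls are excluded from the counts.
#'
#' @param cross a [cross_dataset()].
#' @param alpha significance level (default 0.05).
#' @return tibble with one row per testable marker: site key, code, class
#'   counts, `chisq`, `p_value`, `distorted`.
#' @export
distortion_scan <- function(cross, alpha = 0.05) {
  stopifnot(inherits(cross, "cross_dataset"))
  idx <- which(cross$code %in% c("lmxll", "nnxnp"))
  rows <- lapply(idx, function(i) {
    hom <- if (cross$code[i] == "lmxll") cross$p2[i] else cross$p1[i]
    classes <- sort(unique(gamete_alleles[[2]] + gamete_alleles[[hom + 1]]))
    cnt <- c(sum(cross$off[i, ] == classes[1], na.rm = TRUE),
             sum(cross$off[i, ] == classes[2], na.rm = TRUE))
    if (sum(cnt) == 0) return(NULL)
    sd <- segregation_distortion(cnt[1], cnt[2], alpha = alpha)
    dplyr::bind_cols(cross$sites[i, c("chrom", "pos")],
                     tibble::tibble(code = as.character(cross$code[i]),
                                    n_class1 = cnt[1], n_class2 = cnt[2]),
                     sd)
  })
  dplyr::bind_rows(rows)
}

#' Collapse near-identical markers
#'
#' Computes pairwise genotype identity (fraction of pairwise-complete samples
#' with the same dosage), groups sites whose similarity strictly exceeds the
#' threshold by single linkage, and keeps one representative per group: the
#' site with the least missingness, ties broken by lowest `(chrom, pos)`.
#'
#' @param g genotype table with at least 2 sites.
#' @param similarity_threshold identity threshold (default 0.95, strict `>`).
#' @return the representative sites; attribute `"groups"` maps every input
#'   row to its group id and kept flag.
#' @export
collapse_identical <- function(g, similarity_threshold = 0.95) {
  assert_geno(g)
  m <- nrow(g)
  if (m < 2) rlang::abort("need at least 2 sites")
  gt <- g$gt
  called <- !is.na(gt) * 1
  eq <- matrix(0, m, m)
  for (v in 0:2) {
    av <- (gt == v & !is.na(gt)) * 1
    eq <- eq + av %*% t(av)
  }
  both <- called %*% t(called)
  sim <- ifelse(both > 0, eq / both, 0)
  # union-find over pairs above threshold (single linkage)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  prs <- which(upper.tri(sim) & sim > similarity_threshold, arr.ind = TRUE)
  for (k in seq_len(nrow(prs))) {
    a <- find(prs[k, 1]); b <- find(prs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  grp <- vapply(seq_len(m), find, integer(1))
  missing_n <- rowSums(is.na(gt))
  ord <- order(grp, missing_n, g$chrom, g$pos)
  keep_rows <- ord[!duplicated(grp[ord])]
  keep <- sort(keep_rows)
  out <- g[keep, , drop = FALSE]
  attr(out, "groups") <- tibble::tibble(
    row = seq_len(m), group = match(grp, sort(unique(grp))),
    kept = seq_len(m) %in% keep)
  out
}
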