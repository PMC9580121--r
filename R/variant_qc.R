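#' Per-site genotype statistics
#'
#' Computes, per SNP and over non-missing calls only: allele counts, the
#' alternate-allele frequency `alt_freq = (2 n_homalt + n_het) / (2 n_called)`,
#' the folded minor allele frequency `maf = min(alt_freq, 1 - alt_freq)`,
#' missingness, observed heterozygosity `hobs` (het calls / called), and
#' expected heterozygosity `hexp = 2 p (1 - p)`. An all-missing site is an
#' error.
#'
#' @param g genotype table.
#' @return the input tibble with `n_called`, `alt_freq`, `maf`, `missingness`,
#'   `hobs` and `hexp` columns appended.
#' @export
site_stats <- function(g) {
  assert_geno(g)
  gt <- g$gt
  n <- ncol(gt)
  n_called <- rowSums(!is.na(gt))
  if (any(n_called == 0)) {
    rlang::abort(paste0(sum(n_called == 0), " site(s) have no called genotype"))
  }
  n_het <- rowSums(gt == 1L, na.rm = TRUE)
  n_homalt <- rowSums(gt == 2L, na.rm = TRUE)
  p <- (2 * n_homalt + n_het) / (2 * n_called)
  out <- tibble::as_tibble(g)
  out$n_called <- as.integer(n_called)
  out$alt_freq <- p
  out$maf <- pmin(p, 1 - p)
  out$missingness <- (n - n_called) / n
  out$hobs <- n_het / n_called
  out$hexp <- 2 * p * (1 - p)
  class(out) <- class(g)
  out
}

#' Hard-filter configuration
#'
#' Thresholds of the site-level filtering cascade applied to raw SNP calls.
#' Comparisons are strict, matching the conventional GATK-style expression
#' `QD < 2.0 || MQ < 40.0 || MQRankSum < -12.5`: a site failing any rule is
#' removed, boundary values pass. `max_missing = 0.10` encodes the
#' "at least 90% of samples called" convention. Sites lacking an annotation
#' pass the corresponding rule by default (`fail_if_absent = FALSE`), as a
#' filtering engine evaluating the expression would do at, e.g., hom-only
#' sites with no MQRankSum.
#'
#' @param qd_min,mq_min,mqranksum_min annotation thresholds (strict less-than
#'   removal).
#' @param min_mean_dp minimum across-sample mean depth.
#' @param max_missing maximum per-site missingness fraction.
#' @param require_nonref drop sites with no observed alternate allele.
#' @param maf_min folded-MAF threshold of the clean-set stage (strict
#'   greater-than retention; see [maf_filter()]).
#' @param fail_if_absent treat a missing annotation as a failure.
#' @param per_sample_dp apply `min_mean_dp` to every sample's depth rather
#'   than the across-sample mean.
#' @return a `filter_config` list.
#' @export
filter_config <- function(qd_min = 2.0, mq_min = 40.0, mqranksum_min = -12.5,
                          min_mean_dp = 30, max_missing = 0.10,
                          require_nonref = TRUE, maf_min = 0.05,
                          fail_if_absent = FALSE, per_sample_dp = FALSE) {
  stopifnot(max_missing >= 0, max_missing <= 1,
            is.finite(qd_min), is.finite(mq_min), is.finite(mqranksum_min))
  structure(list(qd_min = qd_min, mq_min = mq_min,
                 mqranksum_min = mqranksum_min, min_mean_dp = min_mean_dp,
                 max_missing = max_missing, require_nonref = require_nonref,
                 maf_min = maf_min, fail_if_absent = fail_if_absent,
                 per_sample_dp = per_sample_dp),
            class = "filter_config")
}

#' Apply the hard-filter cascade to sites
#'
#' Removes a site iff `QD < qd_min` OR `MQ < mq_min` OR
#' `MQRankSum < mqranksum_min` OR `mean_dp < min_mean_dp` OR
#' `missingness > max_missing` OR (when `require_nonref`) no alternate allele
#' is observed. Removals are attributed to the *first* failing rule in that
#' order; the per-rule counts are attached as the `"removals"` attribute
#' (also available through [filter_removals()]).
#'
#' @param g genotype table, with `qd`/`mq`/`mqranksum`/`mean_dp` columns where
#'   the corresponding rules should be active.
#' @param cfg a [filter_config()].
#' @return the kept sites, with attribute `"removals"` (tibble of
#'   `rule`, `n_removed`).
#' @export
apply_hard_filters <- function(g, cfg = filter_config()) {
  assert_geno(g)
  st <- site_stats(g)
  n <- nrow(g)
  absent_fails <- cfg$fail_if_absent
  rule_fail <- function(x, thr, strict_less = TRUE) {
    if (is.null(x)) return(rep(absent_fails, n))
    f <- if (strict_less) x < thr else x > thr
    f[is.na(f)] <- absent_fails
    f
  }
  dp_fail <- if (cfg$per_sample_dp && !is.null(g[["dp"]])) {
    apply(g[["dp"]], 1, function(r) any(r < cfg$min_mean_dp, na.rm = TRUE))
  } else {
    rule_fail(st[["mean_dp"]], cfg$min_mean_dp)
  }
  fails <- cbind(
    qd = rule_fail(g[["qd"]], cfg$qd_min),
    mq = rule_fail(g[["mq"]], cfg$mq_min),
    mqranksum = rule_fail(g[["mqranksum"]], cfg$mqranksum_min),
    mean_dp = dp_fail,
    missingness = st$missingness > cfg$max_missing,
    nonref = if (cfg$require_nonref) st$alt_freq == 0 else rep(FALSE, n)
  )
  first_fail <- apply(fails, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  keep <- is.na(first_fail)
  removals <- tibble::tibble(
    rule = colnames(fails),
    n_removed = vapply(seq_len(ncol(fails)),
                       function(j) sum(first_fail == j, na.rm = TRUE), integer(1))
  )
  out <- g[keep, , drop = FALSE]
  attr(out, "removals") <- removals
  out
}

#' Per-rule removal counts of the last hard-filter run
#' @param g the output of [apply_hard_filters()].
#' @return tibble with `rule` and `n_removed`.
#' @export
filter_removals <- function(g) {
  r <- attr(g, "removals")
  if (is.null(r)) rlang::abort("no removal record attached; run apply_hard_filters() first")
  r
}

#' Minor-allele-frequency filter (clean-set stage)
#'
#' Keeps sites whose folded MAF is strictly greater than `maf_min`
#' (so `maf == maf_min` is removed, and monomorphic sites always are).
#' Idempotent.
#'
#' @param g genotype table.
#' @param maf_min threshold (default 0.05).
#' @return the filtered genotype table.
#' @export
maf_filter <- function(g, maf_min = 0.05) {
  st <- site_stats(g)
  g[st$maf > maf_min, , drop = FALSE]
}
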