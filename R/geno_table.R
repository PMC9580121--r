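#' Build a genotype table
#'
#' The central container of the package is an ordinary tibble with one row per
#' biallelic SNP and a *matrix column* `gt` holding diploid genotype dosages
#' (rows of the matrix follow the rows of the tibble, columns are samples).
#' Dosages are coded `0` = homozygous reference, `1` = heterozygous,
#' `2` = homozygous alternate, `NA` = missing. Phased data additionally carry
#' `hap1`/`hap2` matrix columns of per-haplotype alternate-allele indicators
#' (0/1). All positions are 1-based, as in VCF; every exported report states
#' its coordinate convention.
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   (single bases), plus any per-site annotation columns (`qd`, `mq`,
#'   `mqranksum`, `mean_dp`, ...).
#' @param gt integer matrix, `nrow(sites)` x n_samples, codes in
#'   `{0, 1, 2, NA}`. Column names are the sample ids.
#' @param hap1,hap2 optional 0/1 alternate-allele indicator matrices of the
#'   same shape as `gt` (phased haplotypes); `hap1 + hap2` must equal `gt`
#'   wherever all are non-missing.
#' @return a tibble of class `geno_tbl`, sorted by `(chrom, pos)`.
#' @examples
#' gt <- rbind(c(0L, 1L), c(2L, NA))
#' colnames(gt) <- c("s1", "s2")
#' geno_table(data.frame(chrom = "chr1", pos = c(10L, 40L),
#'                       ref = c("A", "C"), alt = c("G", "T")), gt)
#' @export
geno_table <- function(sites, gt, hap1 = NULL, hap2 = NULL) {
  sites <- tibble::as_tibble(sites)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(sites))
  if (length(miss) > 0) {
    rlang::abort(paste0("`sites` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (nrow(gt) != nrow(sites)) {
    rlang::abort("`gt` must have one row per site")
  }
  if (is.null(colnames(gt))) {
    colnames(gt) <- paste0("S", seq_len(ncol(gt)))
  }
  bad <- gt[!is.na(gt)]
  if (length(bad) > 0 && (min(bad) < 0L || max(bad) > 2L)) {
    rlang::abort("genotype codes must be 0, 1, 2 or NA")
  }
  if (any(sites$pos < 1L)) rlang::abort("positions must be >= 1")
  if (any(nchar(sites$ref) != 1L | nchar(sites$alt) != 1L)) {
    rlang::abort("ref and alt must be single bases (biallelic SNPs only)")
  }
  if (any(sites$ref == sites$alt)) rlang::abort("ref must differ from alt")
  if (anyDuplicated(paste(sites$chrom, sites$pos))) {
    rlang::abort("duplicate (chrom, pos) keys")
  }
  out <- sites
  out$gt <- gt
  if (!is.null(hap1) || !is.null(hap2)) {
    if (is.null(hap1) || is.null(hap2)) {
      rlang::abort("phased data need both `hap1` and `hap2`")
    }
    hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
    storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
    stopifnot(dim(hap1) == dim(gt), dim(hap2) == dim(gt))
    ok <- !is.na(hap1) & !is.na(hap2) & !is.na(gt)
    if (any((hap1 + hap2)[ok] != gt[ok])) {
      rlang::abort("hap1 + hap2 must equal gt where called")
    }
    colnames(hap1) <- colnames(gt); colnames(hap2) <- colnames(gt)
    out$hap1 <- hap1
    out$hap2 <- hap2
  }
  ord <- order(out$chrom, out$pos, method = "radix")
  out <- out[ord, , drop = FALSE]
  class(out) <- unique(c("geno_tbl", class(out)))
  out
}

#' Sample identifiers of a genotype table
#' @param g a genotype table (see [geno_table()]).
#' @return character vector of sample ids.
#' @export
geno_samples <- function(g) {
  colnames(assert_geno(g)$gt)
}

#' @keywords internal
assert_geno <- function(g) {
  if (!is.data.frame(g) || !("gt" %in% names(g)) || !is.matrix(g$gt)) {
    rlang::abort("expected a genotype table with a `gt` matrix column; see geno_table()")
  }
  g
}

#' @keywords internal
is_phased <- function(g) {
  all(c("hap1", "hap2") %in% names(g))
}

#' Subset the samples of a genotype table
#' @param g genotype table.
#' @param samples character vector of sample ids to keep (order respected).
#' @return genotype table restricted to `samples`.
#' @export
select_samples <- function(g, samples) {
  assert_geno(g)
  miss <- setdiff(samples, colnames(g$gt))
  if (length(miss) > 0) {
    rlang::abort(paste0("samples not present: ", paste(miss, collapse = ", ")))
  }
  g$gt <- g$gt[, samples, drop = FALSE]
  if (is_phased(g)) {
    g$hap1 <- g$hap1[, samples, drop = FALSE]
    g$hap2 <- g$hap2[, samples, drop = FALSE]
  }
  g
}
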