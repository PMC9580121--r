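#' Read a multi-sample VCF into a genotype table
#'
#' Parses a VCF 4.x file (plain or gzipped, via vcfR), keeping only simple
#' biallelic SNP records. Multiallelic records, indels and records with
#' symbolic alleles are skipped; the number skipped is attached as the
#' `"skipped"` attribute. Site-level caller annotations `QD`, `MQ` and
#' `MQRankSum` are imported when present (columns `qd`, `mq`, `mqranksum`),
#' as is the across-sample mean of per-sample `DP` (`mean_dp`). Phase is
#' retained: if any genotype is phased (`|` separator) the table carries
#' `hap1`/`hap2` haplotype columns with `NA` at unphased or missing calls.
#'
#' @param path VCF file.
#' @param sample_subset optional character vector restricting (and ordering)
#'   the samples; an empty intersection with the file's samples is an error.
#' @return a [geno_table()] tibble; attribute `"skipped"` counts excluded
#'   records.
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (!any(keep)) rlang::abort("no biallelic SNP records in file")
  v <- v[keep, ]
  fix <- fix[keep, , drop = FALSE]

  gt_raw <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  if (!is.null(sample_subset)) {
    inter <- intersect(sample_subset, colnames(gt_raw))
    if (length(inter) == 0) rlang::abort("no requested sample present in the VCF")
    gt_raw <- gt_raw[, inter, drop = FALSE]
  }
  sep_pipe <- grepl("|", gt_raw, fixed = TRUE)
  a1 <- suppressWarnings(as.integer(substr(gt_raw, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt_raw, 3, 3)))
  gt <- a1 + a2
  dim(gt) <- dim(gt_raw)
  dimnames(gt) <- list(NULL, colnames(gt_raw))

  sites <- tibble::tibble(
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = unname(ref[keep]),
    alt = unname(alt[keep])
  )
  info_num <- function(key) {
    x <- suppressWarnings(vcfR::extract.info(v, element = key, as.numeric = TRUE))
    if (is.null(x) || all(is.na(x))) NULL else as.numeric(x)
  }
  for (key in c(qd = "QD", mq = "MQ", mqranksum = "MQRankSum")) {
    val <- info_num(key)
    nm <- names(which(c(qd = "QD", mq = "MQ", mqranksum = "MQRankSum") == key))
    if (!is.null(val)) sites[[nm]] <- val
  }
  dp <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
    error = function(e) NULL
  )
  if (!is.null(dp) && !all(is.na(dp))) {
    if (!is.null(sample_subset)) dp <- dp[, colnames(gt_raw), drop = FALSE]
    sites$mean_dp <- rowMeans(dp, na.rm = TRUE)
  }

  hap1 <- hap2 <- NULL
  if (any(sep_pipe, na.rm = TRUE)) {
    hap1 <- ifelse(sep_pipe, a1, NA_integer_)
    hap2 <- ifelse(sep_pipe, a2, NA_integer_)
    dim(hap1) <- dim(gt); dim(hap2) <- dim(gt)
    dimnames(hap1) <- list(NULL, colnames(gt))
    dimnames(hap2) <- list(NULL, colnames(gt))
  }
  out <- geno_table(sites, gt, hap1 = hap1, hap2 = hap2)
  attr(out, "skipped") <- n_skip
  out
}

#' Write a genotype table as VCF 4.2
#'
#' Emits a minimal but valid VCF: `GT` genotypes (phased `a|b` where
#' haplotypes are present and called, `a/b` otherwise, `./.` for missing)
#' and any of the recognised site annotations (`qd`, `mq`, `mqranksum`)
#' as INFO fields. Positions are written 1-based as stored.
#'
#' @param g genotype table.
#' @param path output file (plain text).
#' @param contig_lengths optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, contig_lengths = NULL) {
  assert_geno(g)
  samples <- geno_samples(g)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=spetpanel",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))

  fmt_info <- function(i) {
    parts <- character(0)
    for (nm in c(qd = "QD", mq = "MQ", mqranksum = "MQRankSum")) {
      col <- names(which(c(qd = "QD", mq = "MQ", mqranksum = "MQRankSum") == nm))
      if (col %in% names(g) && !is.na(g[[col]][i])) {
        parts <- c(parts, paste0(nm, "=", format(g[[col]][i], trim = TRUE)))
      }
    }
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }
  phased <- is_phased(g)
  gt_str <- matrix("./.", nrow = nrow(g), ncol = length(samples))
  unphased_code <- c("0/0", "0/1", "1/1")
  called <- !is.na(g$gt)
  gt_str[called] <- unphased_code[g$gt[called] + 1L]
  if (phased) {
    ph <- !is.na(g$hap1) & !is.na(g$hap2)
    gt_str[ph] <- paste0(g$hap1[ph], "|", g$hap2[ph])
  }
  info <- vapply(seq_len(nrow(g)), fmt_info, character(1))
  body <- paste(g$chrom, g$pos, ".", g$ref, g$alt, ".", "PASS", info, "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  if (length(samples) == 0) rlang::abort("cannot write a VCF with no samples")
  writeLines(c(hdr, body), path)
  invisible(path)
}
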