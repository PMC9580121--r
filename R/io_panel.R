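#' Write a panel design to disk
#'
#' Emits two files: `<prefix>.tsv`, one row per target with 1-based
#' coordinates (`chrom`, `pos`, `ref`, `alt`, `context`, probe-window bounds,
#' `n_flanking`, `alt_freq`), and `<prefix>_probes.bed`, the probe windows as
#' 0-based half-open BED intervals (name `<chrom>_<pos>_<side>`). A probe
#' window outside its chromosome is an error.
#'
#' @param panel a `panel_design` (see [select_targets()]); must be non-empty.
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  if (nrow(panel) == 0) rlang::abort("empty panel")
  need <- c("chrom", "pos", "ref", "alt", "context",
            "left_start", "left_end", "right_start", "right_end")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0) rlang::abort(paste0("panel lacks: ", paste(miss, collapse = ", ")))
  if (any(panel$left_start < 1L)) rlang::abort("probe window outside chromosome bounds")
  if ("chrom_len" %in% names(panel) && any(panel$right_end > panel$chrom_len)) {
    rlang::abort("probe window outside chromosome bounds")
  }
  tsv <- paste0(prefix, ".tsv")
  bed <- paste0(prefix, "_probes.bed")
  cols <- intersect(c(need, "chrom_len", "n_flanking", "alt_freq", "hobs", "score"),
                    names(panel))
  utils::write.table(as.data.frame(panel)[, cols], tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed_df <- data.frame(
    chrom = rep(panel$chrom, 2),
    start = c(panel$left_start, panel$right_start) - 1L,  # 0-based half-open
    end = c(panel$left_end, panel$right_end),
    name = paste0(rep(panel$chrom, 2), "_", rep(panel$pos, 2), "_",
                  rep(c("left", "right"), each = nrow(panel)))
  )
  bed_df <- bed_df[order(bed_df$chrom, bed_df$start), ]
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(tsv = tsv, bed = bed))
}

#' Read a panel design TSV written by [write_panel()]
#'
#' @param tsv path to the `.tsv` file.
#' @return a `panel_design` tibble.
#' @export
read_panel <- function(tsv) {
  df <- utils::read.table(tsv, header = TRUE, sep = "\t",
                          colClasses = NA, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  out$context <- factor(out$context, levels = c("utr", "exon", "intron", "intergenic"))
  class(out) <- unique(c("panel_design", class(out)))
  out
}

#' Write probe sequences as FASTA
#' @param probes output of [extract_probe_sequences()].
#' @param path FASTA path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(probes, path) {
  seqs <- Biostrings::DNAStringSet(probes$seq)
  names(seqs) <- paste0(probes$target_id, "_", probes$side)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
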