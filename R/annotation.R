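#' Load a GFF3 gene annotation as a context index
#'
#' Imports a GFF3 file (via rtracklayer) and organises the features needed to
#' classify SNP positions into genomic contexts: gene bodies, coding exons
#' (`CDS`, falling back to `exon` features if the annotation carries no CDS),
#' and untranslated regions (`five_prime_UTR` / `three_prime_UTR`, or `UTR`).
#' Intervals are held as `GRanges`; all classification is point-in-interval
#' on 1-based positions.
#'
#' @param path GFF3 file, or a `GRanges` already imported with a `type`
#'   metadata column.
#' @return an `annotation_index` list with `genes`, `cds` and `utr` GRanges.
#' @export
annotation_index <- function(path) {
  gr <- if (methods::is(path, "GRanges")) path else rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type %in% c("gene")]
  if (length(genes) == 0) genes <- gr[type %in% c("mRNA", "transcript")]
  cds <- gr[type == "CDS"]
  if (length(cds) == 0) cds <- gr[type == "exon"]
  utr <- gr[type %in% c("five_prime_UTR", "three_prime_UTR", "UTR")]
  structure(list(genes = genes, cds = cds, utr = utr), class = "annotation_index")
}

#' Classify SNP positions by genomic context
#'
#' Assigns each site to `utr`, `exon`, `intron` or `intergenic`. When features
#' overlap, the default precedence is UTR before coding exon before intron
#' (`utr_first = FALSE` swaps UTR and exon); a position inside a gene body but
#' outside all exon/UTR intervals is an intron. Chromosomes absent from the
#' annotation are classified intergenic with a warning. Adds `context`,
#' `genic` and `gene_id` columns.
#'
#' @param sites genotype table or any tibble with `chrom` and `pos` columns.
#' @param index an [annotation_index()].
#' @param utr_first logical; classify UTR before coding exon on overlap
#'   (default `TRUE`).
#' @return the input with `context` (factor), `genic` (logical) and
#'   `gene_id` columns added.
#' @export
annotate_context <- function(sites, index, utr_first = TRUE) {
  if (!inherits(index, "annotation_index")) rlang::abort("`index` must be an annotation_index")
  pts <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, width = 1))
  ann_chroms <- unique(as.character(GenomicRanges::seqnames(index$genes)))
  absent <- setdiff(unique(sites$chrom), ann_chroms)
  if (length(absent) > 0) {
    rlang::warn(paste0("chromosome(s) absent from annotation, classified intergenic: ",
                       paste(absent, collapse = ", ")))
  }
  hit <- function(feat) {
    GenomicRanges::countOverlaps(pts, feat, ignore.strand = TRUE) > 0
  }
  in_gene <- hit(index$genes)
  in_cds <- hit(index$cds)
  in_utr <- hit(index$utr)
  context <- rep("intergenic", length(pts))
  context[in_gene] <- "intron"
  if (utr_first) {
    context[in_gene & in_cds] <- "exon"
    context[in_gene & in_utr] <- "utr"
  } else {
    context[in_gene & in_utr] <- "utr"
    context[in_gene & in_cds] <- "exon"
  }
  gene_id <- rep(NA_character_, length(pts))
  ov <- GenomicRanges::findOverlaps(pts, index$genes, ignore.strand = TRUE)
  if (length(ov) > 0) {
    ids <- if (!is.null(index$genes$ID)) as.character(index$genes$ID) else
      as.character(seq_along(index$genes))
    first <- !duplicated(S4Vectors::queryHits(ov))
    gene_id[S4Vectors::queryHits(ov)[first]] <- ids[S4Vectors::subjectHits(ov)[first]]
  }
  out <- tibble::as_tibble(sites)
  out$context <- factor(context, levels = c("utr", "exon", "intron", "intergenic"))
  out$genic <- in_gene
  out$gene_id <- gene_id
  class(out) <- class(sites)
  out
}
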