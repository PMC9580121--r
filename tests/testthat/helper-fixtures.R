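# small in-code fixtures shared across test files

# genotype table from a sites x samples code matrix
make_geno <- function(codes, chrom = "chr1", pos = NULL, ref = "A", alt = "G",
                      samples = NULL, ...) {
  codes <- as.matrix(codes)
  m <- nrow(codes)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(codes)))
  colnames(codes) <- samples
  sites <- tibble::tibble(chrom = rep_len(chrom, m), pos = as.integer(pos),
                          ref = rep_len(ref, m), alt = rep_len(alt, m), ...)
  geno_table(sites, codes)
}

# deterministic toy reference: one or more chromosomes of given length
toy_ref <- function(lens, seed = 424) {
  withr::with_seed(seed, {
    seqs <- Biostrings::DNAStringSet(vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)))
    names(seqs) <- paste0("chr", seq_along(lens))
    seqs
  })
}

# independent gamete-enumeration oracle for Mendelian consistency:
# loops explicitly over every transmissible allele pair
oracle_mendel_consistent <- function(p1, p2, off) {
  gam <- function(g) if (g == 0) 0 else if (g == 2) 1 else c(0, 1)
  for (a in gam(p1)) for (b in gam(p2)) if (a + b == off) return(TRUE)
  FALSE
}

# independent CP-configuration oracle from parental het status
oracle_cp_code <- function(p1, p2) {
  if (is.na(p1) || is.na(p2)) return("missing_parent")
  h1 <- p1 == 1; h2 <- p2 == 1
  if (h1 && !h2) "lmxll"
  else if (!h1 && h2) "nnxnp"
  else if (h1 && h2) "hkxhk"
  else if (p1 == p2) "monomorphic"
  else "aaxbb"
}

# brute-force maximum target count under the adjacent-pair spacing rule,
# enumerating every subset (instances are kept to <= 15 candidates)
oracle_max_targets <- function(pos, gap) {
  n <- length(pos)
  ord <- order(pos)
  pos <- pos[ord]; gap <- gap[ord]
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) <= best) next
    okay <- TRUE
    if (length(sel) > 1) {
      for (k in seq_len(length(sel) - 1)) {
        i <- sel[k]; j <- sel[k + 1]
        if (pos[j] - pos[i] < max(gap[i], gap[j])) { okay <- FALSE; break }
      }
    }
    if (okay) best <- length(sel)
  }
  best
}

# minimal candidate tibble accepted by select_targets()
make_candidates <- function(pos, context, chrom = "chr1", alt_freq = 0.5) {
  n <- length(pos)
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    ref = rep_len("A", n), alt = rep_len("G", n),
    context = factor(context, levels = c("utr", "exon", "intron", "intergenic")),
    alt_freq = rep_len(alt_freq, n),
    eligible = TRUE,
    left_start = pmax(1L, as.integer(pos) - 40L), left_end = as.integer(pos) - 1L,
    right_start = as.integer(pos) + 1L, right_end = as.integer(pos) + 40L
  )
}

# two fully heterozygous phased parents over m markers on one chromosome,
# both in coupling phase (hap1 all alt), for recombination tests
phased_parents <- function(m, pos = NULL, p2_hom = FALSE) {
  if (is.null(pos)) pos <- seq_len(m) * 100L
  h1a <- matrix(1L, m, 2); h2a <- matrix(0L, m, 2)
  if (p2_hom) { h1a[, 2] <- 0L }
  colnames(h1a) <- colnames(h2a) <- c("P1", "P2")
  geno_table(tibble::tibble(chrom = "chr1", pos = as.integer(pos),
                            ref = "A", alt = "G"),
             h1a + h2a, hap1 = h1a, hap2 = h2a)
}
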