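#' Panel design configuration
#'
#' Parameters of target-SNP selection for a SPET probe panel. Defaults follow
#' common practice for a 25K fruit-tree assay: a fixed probe budget; minimum
#' spacing between selected targets of 5 kb within genic (CDS) context and
#' 10 kb within intergenic context; an alternate-allele frequency window of
#' 0.10-0.90 (equivalently folded MAF >= 0.10); a cap on observed
#' heterozygosity as a proxy against collapsed paralogs; 40 bp probe windows
#' immediately flanking the target on both sides; and a requirement that at
#' least two additional known SNPs lie within the enrichment footprint so
#' accessory variants can be recovered.
#'
#' @param budget maximum number of targets (default 25000).
#' @param min_gap_cds minimum spacing between genic targets, bp (default
#'   5000).
#' @param min_gap_intergenic minimum spacing between intergenic targets, bp
#'   (default 10000).
#' @param maf_range eligible alternate-allele frequency range (default
#'   `c(0.10, 0.90)`, inclusive).
#' @param het_excess_max maximum observed heterozygosity (default 0.60).
#' @param probe_len probe window length, bp (default 40).
#' @param footprint_len enrichment footprint length, bp (default 150).
#' @param min_flanking_snps required additional known SNPs within the
#'   footprint (default 2).
#' @param max_probe_window_snps optional cap on known SNPs inside either
#'   probe window (default `Inf`; set to 0 to require polymorphism-free
#'   hybridisation windows).
#' @return a `design_config` list.
#' @export
design_config <- function(budget = 25000, min_gap_cds = 5000,
                          min_gap_intergenic = 10000,
                          maf_range = c(0.10, 0.90), het_excess_max = 0.60,
                          probe_len = 40, footprint_len = 150,
                          min_flanking_snps = 2,
                          max_probe_window_snps = Inf) {
  stopifnot(budget > 0, min_gap_cds > 0, min_gap_cds <= min_gap_intergenic,
            probe_len > 0, probe_len < footprint_len,
            length(maf_range) == 2, maf_range[1] <= maf_range[2])
  structure(list(budget = budget, min_gap_cds = min_gap_cds,
                 min_gap_intergenic = min_gap_intergenic,
                 maf_range = maf_range, het_excess_max = het_excess_max,
                 probe_len = probe_len, footprint_len = footprint_len,
                 min_flanking_snps = min_flanking_snps,
                 max_probe_window_snps = max_probe_window_snps),
            class = "design_config")
}

# spacing class of a context: genic contexts use the CDS gap
context_gap <- function(context, cfg) {
  ifelse(as.character(context) == "intergenic",
         cfg$min_gap_intergenic, cfg$min_gap_cds)
}

#' Screen candidate target SNPs for probe eligibility
#'
#' A candidate is eligible iff (checked in this order, the first failing rule
#' is recorded as `reason`):
#' * `maf_range`: alternate-allele frequency within `maf_range`;
#' * `het_excess`: observed heterozygosity `<= het_excess_max`;
#' * `probe_window`: both `probe_len` windows immediately 5' and 3' of the
#'   site lie within the chromosome and contain no ambiguous base (N);
#' * `flanking_snps`: at least `min_flanking_snps` other known SNPs within
#'   `footprint_len` bp;
#' * `probe_window_snps`: (only if capped) no more than
#'   `max_probe_window_snps` known SNPs inside either probe window.
#'
#' @param sites genotype table with site statistics (see [site_stats()]) and
#'   a `context` column (see [annotate_context()]). All sites in the table
#'   count as "known SNPs" for the flanking rule.
#' @param ref reference sequences as a named `Biostrings::DNAStringSet` (or
#'   FASTA path).
#' @param cfg a [design_config()].
#' @return tibble of all candidates with probe-window coordinates (1-based
#'   inclusive), `chrom_len`, `n_flanking`, `eligible` and `reason` columns.
#' @export
eligibility_filter <- function(sites, ref, cfg = design_config()) {
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  if (!("maf" %in% names(sites))) sites <- site_stats(sites)
  if (!("context" %in% names(sites))) {
    rlang::abort("`sites` needs a `context` column; run annotate_context() first")
  }
  names(ref) <- sub("\\s.*$", "", names(ref))
  missing_chrom <- setdiff(unique(sites$chrom), names(ref))
  if (length(missing_chrom) > 0) {
    rlang::abort(paste0("chromosome(s) absent from reference: ",
                        paste(missing_chrom, collapse = ", ")))
  }
  out <- tibble::as_tibble(sites)
  out$chrom_len <- as.integer(Biostrings::width(ref)[match(out$chrom, names(ref))])
  if (any(out$pos > out$chrom_len)) {
    rlang::abort("site position beyond reference sequence length")
  }
  out$left_start <- out$pos - cfg$probe_len
  out$left_end <- out$pos - 1L
  out$right_start <- out$pos + 1L
  out$right_end <- out$pos + cfg$probe_len

  in_bounds <- out$left_start >= 1L & out$right_end <= out$chrom_len
  no_n <- rep(FALSE, nrow(out))
  for (chr in unique(out$chrom)) {
    i <- which(out$chrom == chr & in_bounds)
    if (length(i) == 0) next
    windows <- IRanges::IRanges(
      start = c(out$left_start[i], out$right_start[i]),
      end = c(out$left_end[i], out$right_end[i]))
    seqs <- Biostrings::extractAt(ref[[chr]], windows)
    n_count <- Biostrings::letterFrequency(seqs, "N")[, 1]
    half <- length(i)
    no_n[i] <- n_count[seq_len(half)] == 0 & n_count[half + seq_len(half)] == 0
  }
  # known-SNP counts near each candidate (all sites in the table count)
  n_flank <- integer(nrow(out))
  n_in_windows <- integer(nrow(out))
  for (chr in unique(out$chrom)) {
    i <- which(out$chrom == chr)
    pos <- sort(out$pos[i])
    within <- function(lo, hi) {
      findInterval(hi, pos) - findInterval(lo - 1L, pos)
    }
    n_flank[i] <- within(out$pos[i] - cfg$footprint_len,
                         out$pos[i] + cfg$footprint_len) - 1L
    n_in_windows[i] <- within(out$left_start[i], out$left_end[i]) +
      within(out$right_start[i], out$right_end[i])
  }
  out$n_flanking <- n_flank
  reason <- rep(NA_character_, nrow(out))
  fail <- function(cond, lab) {
    reason[is.na(reason) & cond] <<- lab
  }
  fail(out$alt_freq < cfg$maf_range[1] | out$alt_freq > cfg$maf_range[2], "maf_range")
  fail(out$hobs > cfg$het_excess_max, "het_excess")
  fail(!(in_bounds & no_n), "probe_window")
  fail(out$n_flanking < cfg$min_flanking_snps, "flanking_snps")
  if (is.finite(cfg$max_probe_window_snps)) {
    fail(n_in_windows > cfg$max_probe_window_snps, "probe_window_snps")
  }
  out$eligible <- is.na(reason)
  out$reason <- reason
  out
}

# exact maximum-count selection on one chromosome under the adjacent-pair
# spacing rule: consecutive selected sites i < j need
# pos_j - pos_i >= max(gap_i, gap_j). Dynamic program over position-sorted
# candidates; deterministic tie-breaks (smallest indices).
select_chrom_dp <- function(pos, gap) {
  n <- length(pos)
  if (n == 0) return(integer(0))
  f <- integer(n)
  pred <- integer(n)
  for (j in seq_len(n)) {
    prev <- seq_len(j - 1)
    valid <- prev[pos[j] - pos[prev] >= pmax(gap[prev], gap[j])]
    if (length(valid) == 0) {
      f[j] <- 1L; pred[j] <- 0L
    } else {
      best <- max(f[valid])
      f[j] <- best + 1L
      pred[j] <- valid[which(f[valid] == best)[1]]
    }
  }
  end <- which(f == max(f))[1]
  chain <- integer(0)
  while (end != 0L) { chain <- c(end, chain); end <- pred[end] }
  chain
}

#' Select a budgeted, regularly spaced target panel
#'
#' From position-sorted eligible candidates, selects per chromosome the
#' maximum number of targets such that every pair of position-adjacent
#' selected targets is at least the applicable minimum gap apart — the gap
#' for a pair being the larger of the two candidates' class gaps
#' (genic 5 kb, intergenic 10 kb by default). If the unconstrained maximum
#' exceeds the budget, candidates are ranked globally by score
#' (`|alt_freq - 0.5|` ascending, genic before intergenic, then chromosome
#' and position) and re-selected greedily in rank order under the same
#' spacing constraints until the budget binds. Fully deterministic given
#' input and configuration.
#'
#' @param candidates output of [eligibility_filter()]; only rows with
#'   `eligible == TRUE` are considered.
#' @param cfg a [design_config()].
#' @return a `panel_design` tibble of selected targets (probe windows
#'   1-based inclusive); the configuration is the `"config"` attribute.
#' @export
select_targets <- function(candidates, cfg = design_config()) {
  cand <- dplyr::filter(tibble::as_tibble(candidates), .data$eligible)
  if (nrow(cand) == 0) rlang::abort("no eligible candidates")
  cand <- dplyr::arrange(cand, .data$chrom, .data$pos, .data$ref, .data$alt)
  cand$.gap <- context_gap(cand$context, cfg)
  sel_rows <- unlist(lapply(split(seq_len(nrow(cand)), cand$chrom), function(i) {
    i[select_chrom_dp(cand$pos[i], cand$.gap[i])]
  }), use.names = FALSE)
  if (length(sel_rows) > cfg$budget) {
    score_ord <- order(abs(cand$alt_freq - 0.5),
                       cand$context == "intergenic",
                       cand$chrom, cand$pos, method = "radix")
    accepted <- vector("list", length(unique(cand$chrom)))
    names(accepted) <- unique(cand$chrom)
    for (chr in names(accepted)) accepted[[chr]] <- list(pos = numeric(0), gap = numeric(0))
    sel_rows <- integer(0)
    for (r in score_ord) {
      if (length(sel_rows) >= cfg$budget) break
      chr <- cand$chrom[r]
      acc <- accepted[[chr]]
      p <- cand$pos[r]; gp <- cand$.gap[r]
      k <- findInterval(p, acc$pos)
      ok <- TRUE
      if (k >= 1 && p - acc$pos[k] < max(acc$gap[k], gp)) ok <- FALSE
      if (ok && k < length(acc$pos) &&
          acc$pos[k + 1] - p < max(acc$gap[k + 1], gp)) ok <- FALSE
      if (ok) {
        accepted[[chr]]$pos <- append(acc$pos, p, after = k)
        accepted[[chr]]$gap <- append(acc$gap, gp, after = k)
        sel_rows <- c(sel_rows, r)
      }
    }
  }
  panel <- cand[sort(sel_rows), , drop = FALSE]
  panel$score <- abs(panel$alt_freq - 0.5)
  panel$.gap <- NULL
  class(panel) <- unique(c("panel_design", class(panel)))
  attr(panel, "config") <- cfg
  panel
}

#' Extract probe sequences for a panel
#'
#' The left probe is the `probe_len` bases immediately 5' of the target on
#' the plus strand; the right probe is the reverse complement of the
#' `probe_len` bases immediately 3' (so both read towards the target).
#' Sequences are uppercased; an ambiguous base in a window is an error
#' (eligible candidates were screened for this).
#'
#' @param panel a `panel_design` (or any tibble with `chrom`, `pos` and probe
#'   window columns).
#' @param ref reference `DNAStringSet` or FASTA path.
#' @return tibble with `target_id`, `chrom`, `pos`, `side`, `start`, `end`
#'   (1-based inclusive, plus strand), `seq`.
#' @export
extract_probe_sequences <- function(panel, ref) {
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (nrow(panel) == 0) rlang::abort("empty panel")
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    chr <- panel$chrom[i]
    left <- Biostrings::subseq(ref[[chr]], panel$left_start[i], panel$left_end[i])
    right <- Biostrings::subseq(ref[[chr]], panel$right_start[i], panel$right_end[i])
    ls <- toupper(as.character(left))
    rs <- toupper(as.character(Biostrings::reverseComplement(right)))
    if (grepl("N", ls, fixed = TRUE) || grepl("N", rs, fixed = TRUE)) {
      rlang::abort(paste0("ambiguous base in probe window at ", chr, ":", panel$pos[i]))
    }
    tibble::tibble(
      target_id = paste0(chr, "_", panel$pos[i]),
      chrom = chr, pos = panel$pos[i],
      side = c("left", "right"),
      start = c(panel$left_start[i], panel$right_start[i]),
      end = c(panel$left_end[i], panel$right_end[i]),
      seq = c(ls, rs))
  })
  dplyr::bind_rows(rows)
}

#' Classify assay-called sites as target, accessory or unassigned
#'
#' A called site is a `target` when its `(chrom, pos)` matches a designed
#' target exactly; `accessory` when it lies within `footprint_len` bp of a
#' designed target (the enrichment footprint within which non-target
#' polymorphisms are sequenced) without being one; otherwise `unassigned`.
#'
#' @param called genotype table (or tibble with `chrom`, `pos`).
#' @param panel a `panel_design`.
#' @param cfg a [design_config()] (for `footprint_len`).
#' @return the input with a `panel_class` factor column added.
#' @export
classify_called_sites <- function(called, panel, cfg = design_config()) {
  out <- tibble::as_tibble(called)
  cls <- rep("unassigned", nrow(out))
  for (chr in unique(out$chrom)) {
    i <- which(out$chrom == chr)
    tpos <- sort(panel$pos[panel$chrom == chr])
    if (length(tpos) == 0) next
    exact <- out$pos[i] %in% tpos
    k <- findInterval(out$pos[i], tpos)
    d_left <- ifelse(k >= 1, out$pos[i] - tpos[pmax(k, 1)], Inf)
    d_right <- ifelse(k < length(tpos), tpos[pmin(k + 1, length(tpos))] - out$pos[i], Inf)
    near <- pmin(d_left, d_right) <= cfg$footprint_len
    cls[i][near] <- "accessory"
    cls[i][exact] <- "target"
  }
  out$panel_class <- factor(cls, levels = c("target", "accessory", "unassigned"))
  class(out) <- class(called)
  out
}
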