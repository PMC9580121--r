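test_that("eligibility records the first failing rule per candidate", {
  ref <- toy_ref(10000)
  cfg <- design_config(min_gap_cds = 100, min_gap_intergenic = 200,
                       footprint_len = 150, min_flanking_snps = 2)
  # cluster of sites so the middle ones have flanking SNPs
  pos <- c(20L, 5000L, 5050L, 5100L, 5150L, 9000L)
  gt <- rbind(
    c(1L, 1L, 0L, 0L, 0L),   # near chrom start: probe_window
    c(1L, 1L, 1L, 1L, 0L),   # fine
    c(1L, 0L, 0L, 0L, 0L),   # alt_freq 0.1: eligible boundary
    c(1L, 1L, 1L, 1L, 1L),   # hobs 1.0: het_excess
    c(1L, 0L, 0L, 0L, 0L),   # fine
    c(2L, 2L, 2L, 2L, 1L)    # alt_freq 0.9 boundary, but no flanking SNPs
  )
  g <- make_geno(gt, pos = pos)
  st <- site_stats(g)
  st$context <- factor("exon", levels = levels(annotate_context(
    tibble::tibble(chrom = "x", pos = 1L),
    annotation_index(GenomicRanges::GRanges("x", IRanges::IRanges(1, 2),
                                            type = "gene", ID = "g")))$context))
  out <- eligibility_filter(st, ref, cfg)
  expect_equal(out$reason[out$pos == 20], "probe_window")
  expect_equal(out$reason[out$pos == 5100], "het_excess")
  expect_equal(out$reason[out$pos == 9000], "flanking_snps")
  expect_true(out$eligible[out$pos == 5050])
  expect_true(is.na(out$reason[out$pos == 5050]))
  # exactly one recorded reason per ineligible candidate
  expect_true(all(is.na(out$reason) == out$eligible))
})

test_that("out-of-range allele frequency is excluded with reason maf_range", {
  ref <- toy_ref(10000)
  gt <- rbind(c(1L, rep(0L, 10)),       # alt_freq 1/22 = 0.045
              c(1L, 1L, rep(0L, 9)),    # 0.09
              c(rep(2L, 10), 1L))       # 0.95
  g <- make_geno(gt, pos = c(5000L, 5050L, 5100L))
  st <- site_stats(g)
  st$context <- factor("exon", levels = c("utr", "exon", "intron", "intergenic"))
  out <- eligibility_filter(st, ref, design_config(min_flanking_snps = 0))
  expect_equal(out$reason, rep("maf_range", 3))
})

test_that("spacing drives selection: 3 kb CDS pair collapses, 6 kb survives", {
  close_pair <- make_candidates(c(10000L, 13000L), c("exon", "exon"))
  sel1 <- select_targets(close_pair, design_config())
  expect_equal(nrow(sel1), 1L)

  far_pair <- make_candidates(c(10000L, 16000L), c("exon", "exon"))
  sel2 <- select_targets(far_pair, design_config())
  expect_equal(nrow(sel2), 2L)

  # mixed contexts use the larger class gap: 6 kb < 10 kb intergenic gap
  mixed <- make_candidates(c(10000L, 16000L), c("exon", "intergenic"))
  expect_equal(nrow(select_targets(mixed, design_config())), 1L)
  expect_error(select_targets(make_candidates(integer(0), character(0))),
               "no eligible")
})

test_that("selection attains the exhaustive-search maximum on random instances", {
  withr::with_seed(2024, {
    cfg <- design_config(min_gap_cds = 500, min_gap_intergenic = 1200,
                         budget = 50)
    for (inst in 1:200) {
      n <- sample(4:12, 1)
      pos <- sort(sample.int(8000, n))
      ctx <- sample(c("exon", "intron", "intergenic"), n, replace = TRUE)
      cand <- make_candidates(pos, ctx,
                              alt_freq = round(runif(n, 0.1, 0.9), 2))
      sel <- select_targets(cand, cfg)
      gap <- ifelse(ctx == "intergenic", cfg$min_gap_intergenic, cfg$min_gap_cds)
      expect_equal(nrow(sel), oracle_max_targets(pos, gap),
                   info = paste("instance", inst))
      # spacing invariant on the output
      sel_gap <- ifelse(as.character(sel$context) == "intergenic",
                        cfg$min_gap_intergenic, cfg$min_gap_cds)
      if (nrow(sel) > 1) {
        d <- diff(sel$pos)
        req <- pmax(sel_gap[-1], sel_gap[-nrow(sel)])
        expect_true(all(d >= req))
      }
    }
  })
})

test_that("the budget binds and high-score candidates win", {
  withr::with_seed(55, {
    n <- 60
    cand <- make_candidates(sort(sample.int(1e6, n)),
                            sample(c("exon", "intergenic"), n, TRUE),
                            alt_freq = round(runif(n, 0.1, 0.9), 3))
    cfg <- design_config(budget = 10, min_gap_cds = 500,
                         min_gap_intergenic = 1000)
    sel <- select_targets(cand, cfg)
    expect_lte(nrow(sel), 10L)
    expect_equal(nrow(sel), 10L)
    # budget-bound selection favours allele frequencies near 0.5
    unpicked <- dplyr::anti_join(cand, sel, by = c("chrom", "pos"))
    expect_lt(mean(abs(sel$alt_freq - 0.5)),
              mean(abs(unpicked$alt_freq - 0.5)))
  })
})

test_that("identical inputs produce byte-identical panel files", {
  withr::with_seed(9, {
    n <- 30
    cand <- make_candidates(sort(sample.int(2e5, n)),
                            sample(c("exon", "intergenic"), n, TRUE),
                            alt_freq = round(runif(n, 0.1, 0.9), 3))
  })
  cfg <- design_config(budget = 8, min_gap_cds = 500, min_gap_intergenic = 800)
  f1 <- tempfile(); f2 <- tempfile()
  write_panel(select_targets(cand, cfg), f1)
  write_panel(select_targets(cand, cfg), f2)
  expect_identical(readLines(paste0(f1, ".tsv")), readLines(paste0(f2, ".tsv")))
})

test_that("probe sequences are the exact flanking slices", {
  ref <- toy_ref(100)
  seq_chr <- as.character(ref[[1]])
  panel <- make_candidates(50L, "exon")
  probes <- extract_probe_sequences(panel, ref)
  left <- probes$seq[probes$side == "left"]
  # left probe = bases 10..49 of the toy sequence (1-based)
  expect_equal(left, toupper(substr(seq_chr, 10, 49)))
  right <- probes$seq[probes$side == "right"]
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(rc(rc(right)), right)                        # involution
  expect_equal(rc(right), toupper(substr(seq_chr, 51, 90)))
  expect_true(all(nchar(probes$seq) == 40L))
})

test_that("called sites classify as target, accessory or unassigned", {
  panel <- make_candidates(c(10000L, 50000L), c("exon", "exon"))
  called <- tibble::tibble(chrom = "chr1",
                           pos = c(10000L, 10030L, 15000L, 50140L))
  out <- classify_called_sites(called, panel, design_config(footprint_len = 150))
  expect_equal(as.character(out$panel_class),
               c("target", "accessory", "unassigned", "accessory"))
})
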