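test_that("reference simulation is deterministic with the stated geometry", {
  sim <- simulate_reference(n_chrom = 2, chrom_len = 5e4, seed = 3)
  expect_equal(length(sim$ref), 2L)
  expect_equal(unname(Biostrings::width(sim$ref)), c(5e4, 5e4))
  sim2 <- simulate_reference(n_chrom = 2, chrom_len = 5e4, seed = 3)
  expect_identical(as.character(sim$ref), as.character(sim2$ref))
  expect_identical(as.data.frame(sim$annotation), as.data.frame(sim2$annotation))
  expect_error(simulate_reference(seed = 1, genic_fraction = 1.2), "genic_fraction")
})

test_that("annotated gene span tracks the requested genic fraction", {
  sim <- simulate_reference(n_chrom = 1, chrom_len = 1e6,
                            genic_fraction = 0.6, seed = 17)
  genes <- sim$annotation[sim$annotation$type == "gene"]
  frac <- sum(GenomicRanges::width(genes)) / 1e6
  expect_gt(frac, 0.55)
  expect_lt(frac, 0.65)
})

test_that("founder genotypes follow inbreeding-adjusted Hardy-Weinberg", {
  fd <- simulate_founders(n_sites = 2000, n_samples = 300, f = 0,
                          n_chrom = 1, seed = 10)
  st <- site_stats(fd)
  mid <- st$true_af > 0.45 & st$true_af < 0.55
  expect_gt(sum(mid), 20)
  expect_equal(mean(st$hobs[mid]), 0.5, tolerance = 0.02)

  fd75 <- simulate_founders(n_sites = 2000, n_samples = 300, f = 0.75,
                            n_chrom = 1, seed = 10)
  st75 <- site_stats(fd75)
  mid75 <- st75$true_af > 0.45 & st75$true_af < 0.55
  # 2pq(1-F) at p = 0.5 is 0.125
  expect_equal(mean(st75$hobs[mid75]), 0.125, tolerance = 0.05)

  fd_b <- simulate_founders(n_sites = 50, n_samples = 5, n_chrom = 1, seed = 10)
  fd_c <- simulate_founders(n_sites = 50, n_samples = 5, n_chrom = 1, seed = 10)
  expect_identical(as.data.frame(fd_b[, c("chrom", "pos", "ref", "alt")]),
                   as.data.frame(fd_c[, c("chrom", "pos", "ref", "alt")]))
  expect_identical(fd_b$gt, fd_c$gt)
})

test_that("realised recombinant fraction follows the Haldane map function", {
  # two markers 50 cM apart; P2 homozygous so each offspring call reads off
  # the P1 gamete directly
  parents <- phased_parents(2, pos = c(1L, 101L), p2_hom = TRUE)
  cross <- simulate_f1(parents, n_offspring = 10000, cm_per_chrom = 50, seed = 77)
  gam <- cross$off  # dosage = P1 gamete allele (P2 contributes 0)
  rec <- mean(gam[1, ] != gam[2, ])
  expect_equal(rec, haldane_d_to_r(0.5), tolerance = 0.02 / 0.3161)  # within 0.02 absolute
})

test_that("completely linked markers never recombine", {
  parents <- phased_parents(5, p2_hom = TRUE)
  cross <- simulate_f1(parents, n_offspring = 500, cm_per_chrom = 0, seed = 5)
  same <- apply(cross$off, 2, function(col) length(unique(col)) == 1)
  expect_true(all(same))
})

test_that("hk x hk markers segregate 1:2:1 in the offspring", {
  parents <- phased_parents(40, pos = seq_len(40) * 1e4L)
  cross <- simulate_f1(parents, n_offspring = 500, cm_per_chrom = 200, seed = 42)
  expect_true(all(cross$code == "hkxhk"))
  counts <- table(factor(cross$off[10, ], levels = 0:2))
  chisq <- sum((counts - 500 * c(0.25, 0.5, 0.25))^2 / (500 * c(0.25, 0.5, 0.25)))
  p <- stats::pchisq(chisq, df = 2, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("unphased parents are rejected by the gamete simulator", {
  parents <- phased_parents(3)
  parents$hap1 <- NULL; parents$hap2 <- NULL
  expect_error(simulate_f1(parents, n_offspring = 5, seed = 1), "phased")
})

test_that("error injection perturbs the expected number of calls", {
  g <- make_geno(matrix(sample(0:2, 1000 * 1000, replace = TRUE), 1000, 1000),
                 pos = seq_len(1000))
  same <- inject_errors_and_missing(g, error_rate = 0, missing_rate = 0, seed = 2)
  expect_identical(same$gt, g$gt)

  pert <- inject_errors_and_missing(g, error_rate = 0.018, missing_rate = 0,
                                    seed = 3)
  n_err <- sum(attr(pert, "error_mask"))
  expect_equal(sum(pert$gt != g$gt, na.rm = TRUE), n_err)
  # binomial: 18000 +/- 3 sd
  sd3 <- 3 * sqrt(1e6 * 0.018 * 0.982)
  expect_lt(abs(n_err - 18000), sd3)

  pert2 <- inject_errors_and_missing(g, error_rate = 0.018, missing_rate = 0,
                                     seed = 3)
  expect_identical(pert$gt, pert2$gt)

  miss <- inject_errors_and_missing(g, error_rate = 0, missing_rate = 0.05,
                                    seed = 4)
  expect_lt(abs(mean(is.na(miss$gt)) - 0.05), 7e-4)  # ~3 binomial sd
})

test_that("allelic dropout only corrupts heterozygous calls", {
  g <- make_geno(matrix(rep(0:2, each = 200), 3, 200, byrow = TRUE),
                 pos = c(10L, 20L, 30L))
  pert <- inject_errors_and_missing(g, error_rate = 0.5,
                                    error_model = "allelic_dropout", seed = 6)
  changed <- which(pert$gt != g$gt, arr.ind = TRUE)
  expect_true(all(g$gt[changed] == 1L))
  expect_true(all(pert$gt[changed] %in% c(0L, 2L)))
  expect_error(inject_errors_and_missing(g, 0.1, "bogus", seed = 1), "unknown")
})

test_that("the simulated pipeline closes: reference to valid panel", {
  sim <- simulate_reference(n_chrom = 2, chrom_len = 2e5,
                            genic_fraction = 0.4, seed = 21)
  fd <- simulate_founders(ref = sim$ref, n_sites = 1200, n_samples = 30,
                          af_dist = "beta", seed = 22)
  st <- annotate_context(site_stats(fd), annotation_index(sim$annotation))
  cfg <- design_config(budget = 40, min_gap_cds = 2000,
                       min_gap_intergenic = 4000, min_flanking_snps = 1)
  cand <- eligibility_filter(st, sim$ref, cfg)
  panel <- select_targets(cand, cfg)
  expect_gt(nrow(panel), 0)
  expect_lte(nrow(panel), cfg$budget)
  expect_true(all(panel$eligible))
  for (chr in unique(panel$chrom)) {
    p <- panel[panel$chrom == chr, ]
    if (nrow(p) < 2) next
    gap <- ifelse(as.character(p$context) == "intergenic",
                  cfg$min_gap_intergenic, cfg$min_gap_cds)
    expect_true(all(diff(p$pos) >= pmax(gap[-1], gap[-nrow(p)])))
  }
  probes <- extract_probe_sequences(panel, sim$ref)
  expect_true(all(nchar(probes$seq) == cfg$probe_len))
})
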