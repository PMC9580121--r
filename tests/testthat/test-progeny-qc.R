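test_that("CP classification matches the gamete-status oracle on all 3x3 pairs", {
  for (p1 in c(0:2, NA)) for (p2 in c(0:2, NA)) {
    expect_equal(as.character(classify_cp_marker(p1, p2)),
                 oracle_cp_code(p1, p2),
                 info = paste("p1 =", p1, "p2 =", p2))
  }
  expect_equal(as.character(classify_cp_marker(1L, 0L)), "lmxll")
  expect_equal(as.character(classify_cp_marker(0L, 2L)), "aaxbb")
})

test_that("mendelian_check agrees with gamete-pair enumeration on all 27 triples", {
  for (p1 in 0:2) for (p2 in 0:2) for (off in 0:2) {
    expected <- if (oracle_mendel_consistent(p1, p2, off)) "consistent" else
      "inconsistent"
    expect_equal(mendelian_check(p1, p2, off), expected,
                 info = paste(p1, p2, off))
  }
  expect_equal(mendelian_check(0L, 0L, 1L), "inconsistent")
  expect_equal(mendelian_check(0L, 2L, 0L), "inconsistent")
  expect_equal(mendelian_check(1L, 1L, 0:2), rep("consistent", 3))
  expect_equal(mendelian_check(NA, 0L, 1L), "unchecked")
})

test_that("detectable fractions equal enumeration-derived probabilities", {
  # independent enumeration: true offspring states with Mendelian weights,
  # uniform swap to each of the two other states, flag by the oracle
  oracle_detectable <- function(p1, p2) {
    gam <- function(g) if (g == 0) 0 else if (g == 2) 1 else c(0, 1)
    num <- 0; den <- 0
    for (a in gam(p1)) for (b in gam(p2)) {
      truth <- a + b
      for (wrong in setdiff(0:2, truth)) {
        den <- den + 1
        if (!oracle_mendel_consistent(p1, p2, wrong)) num <- num + 1
      }
    }
    num / den
  }
  expect_equal(detectable_fraction("monomorphic"), 1.0)
  expect_equal(detectable_fraction("monomorphic"), oracle_detectable(0, 0))
  expect_equal(detectable_fraction("hkxhk"), 0.0)
  expect_equal(detectable_fraction("lmxll"), 0.5)
  expect_equal(detectable_fraction("lmxll"), oracle_detectable(1, 0))
  expect_equal(detectable_fraction("nnxnp"), oracle_detectable(0, 1))
  expect_equal(detectable_fraction("aaxbb"), oracle_detectable(0, 2))
  expect_error(detectable_fraction("nonsense"), "no detectability")
  # dropout: only het calls err; at lm x ll one of the two homozygotes is
  # consistent, at aa x bb neither is
  expect_equal(detectable_fraction("lmxll", "allelic_dropout"), 0.5)
  expect_equal(detectable_fraction("aaxbb", "allelic_dropout"), 1.0)
  expect_true(is.nan(detectable_fraction("monomorphic", "allelic_dropout")))
})

test_that("an error-free cross yields a zero error rate", {
  fd <- simulate_founders(n_sites = 800, n_samples = 2, af_dist = "beta",
                          n_chrom = 2, seed = 14)
  cross <- simulate_f1(fd, n_offspring = 40, seed = 15)
  est <- estimate_error_rate(cross)
  expect_equal(est$raw_rate, 0)
  expect_equal(est$adjusted_rate, 0)
  expect_gt(est$n_checked, 0)
})

test_that("adjusted rate recovers injected rates across a grid, raw does not", {
  fd <- simulate_founders(n_sites = 3000, n_samples = 2, af_dist = "beta",
                          n_chrom = 2, seed = 140)
  cross <- simulate_f1(fd, n_offspring = 80, seed = 141)
  has_hk <- sum(cross$code == "hkxhk")
  expect_gt(has_hk, 100)   # the invisible class is well represented
  inj_seeds <- c(41, 42, 43, 44)
  rates <- c(0.005, 0.01, 0.02, 0.05)
  for (k in seq_along(rates)) {
    pert <- inject_errors_and_missing(cross, rates[k], "uniform_swap",
                                      missing_rate = 0, seed = inj_seeds[k])
    est <- estimate_error_rate(pert)
    se <- sqrt(est$raw_rate * (1 - est$raw_rate) / est$n_checked) /
      est$detectable_fraction
    expect_lt(abs(est$adjusted_rate - rates[k]), 2 * se + 2e-4,
              label = paste("adjusted at rate", rates[k]))
    expect_lt(est$raw_rate, rates[k])   # under-detection without correction
  }
})

test_that("segregation distortion chi-square matches closed forms", {
  even <- segregation_distortion(45, 45)
  expect_equal(even$chisq, 0)
  expect_equal(even$p_value, 1)
  expect_false(even$distorted)

  skew <- segregation_distortion(60, 30)
  expect_equal(skew$chisq, 10.0)
  expect_equal(skew$p_value, 0.001565402, tolerance = 1e-6)
  expect_true(skew$distorted)

  mild <- segregation_distortion(50, 44)
  expect_equal(mild$chisq, 36 / 94, tolerance = 1e-12)
  expect_equal(mild$p_value, 0.5360, tolerance = 1e-3)
  expect_false(mild$distorted)

  expect_error(segregation_distortion(0, 0), "zero total")
})

test_that("distortion p-values are uniform under a true 1:1 segregation", {
  withr::with_seed(1001, {
    n_off <- 5000
    p_vals <- vapply(seq_len(2000), function(i) {
      n1 <- rbinom(1, n_off, 0.5)
      segregation_distortion(n1, n_off - n1)$p_value
    }, numeric(1))
    ks <- suppressWarnings(stats::ks.test(p_vals, "punif"))
    expect_gt(ks$p.value, 0.001)
    expect_lt(abs(mean(p_vals <= 0.05) - 0.05), 0.015)
  })
})

test_that("distortion scan tests only single-parent-het markers", {
  g <- make_geno(cbind(c(1L, 0L, 1L), c(0L, 1L, 1L),
                       c(0L, 0L, 1L), c(1L, 1L, 2L), c(0L, 1L, 0L)),
                 samples = c("P1", "P2", "o1", "o2", "o3"))
  cross <- cross_dataset(g, "P1", "P2")
  sc <- distortion_scan(cross)
  expect_equal(sort(sc$code), c("lmxll", "nnxnp"))
  expect_equal(sc$n_class1 + sc$n_class2, c(3L, 3L))
})

test_that("near-identical loci collapse to one representative", {
  withr::with_seed(31, {
    base <- sample(0:2, 100, replace = TRUE)
    twin <- base
    twin[1:4] <- (base[1:4] + 1L) %% 3L     # identical in 96 of 100
    other <- sample(0:2, 100, replace = TRUE)
    g <- make_geno(rbind(base, base, twin, other),
                   pos = c(10L, 20L, 30L, 40L))
    out <- collapse_identical(g, 0.95)
    grp <- attr(out, "groups")
    expect_equal(nrow(out), 2L)                      # {base, base, twin} + other
    expect_equal(length(unique(grp$group[1:3])), 1L) # 0.96 > 0.95 joins twin
    expect_equal(out$pos[1], 10L)                    # tie -> lowest position
  })
})

test_that("distinct random markers are not collapsed", {
  withr::with_seed(93, {
    gt <- matrix(sample(0:2, 50 * 80, replace = TRUE), 50, 80)
    g <- make_geno(gt, pos = seq_len(50) * 9L)
    out <- collapse_identical(g, 0.95)
    expect_equal(nrow(out), 50L)
  })
})

test_that("CP locus export encodes lm x ll and nn x np offspring calls", {
  g <- make_geno(cbind(c(1L, 0L), c(0L, 1L), c(0L, 0L), c(1L, 1L)),
                 samples = c("P1", "P2", "o1", "o2"))
  cross <- cross_dataset(g, "P1", "P2")
  lines <- export_cp_loci(cross)
  expect_length(lines, 2)
  expect_match(lines[1], "<lmxll>\tll\tlm")
  expect_match(lines[2], "<nnxnp>\tnn\tnp")
})
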