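# derive independent child seeds from one master seed (kept below 2^31)
seed_children <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Haldane and Kosambi map functions
#'
#' Conversions between genetic distance (Morgans) and recombinant fraction.
#' Gamete simulation uses Haldane (no crossover interference); the Kosambi
#' pair is provided for conversion of externally estimated distances only.
#'
#' @param d genetic distance in Morgans.
#' @param r recombinant fraction in `[0, 0.5)`.
#' @return the converted quantity.
#' @export
haldane_d_to_r <- function(d) (1 - exp(-2 * d)) / 2

#' @rdname haldane_d_to_r
#' @export
haldane_r_to_d <- function(r) -log(1 - 2 * r) / 2

#' @rdname haldane_d_to_r
#' @export
kosambi_d_to_r <- function(d) tanh(2 * d) / 2

#' @rdname haldane_d_to_r
#' @export
kosambi_r_to_d <- function(r) atanh(2 * r) / 2

# one random gene model: 5'UTR, coding exons with introns, 3'UTR
random_gene_model <- function(start) {
  n_ex <- sample(2:4, 1)
  utr5 <- sample(150:300, 1)
  utr3 <- sample(150:300, 1)
  ex <- sample(200:500, n_ex, replace = TRUE)
  intr <- sample(150:600, n_ex - 1, replace = TRUE)
  parts <- list(c("five_prime_UTR", utr5))
  for (k in seq_len(n_ex)) {
    parts <- c(parts, list(c("CDS", ex[k])))
    if (k < n_ex) parts <- c(parts, list(c("intron", intr[k])))
  }
  parts <- c(parts, list(c("three_prime_UTR", utr3)))
  type <- vapply(parts, `[`, character(1), 1)
  len <- as.integer(vapply(parts, `[`, character(1), 2))
  ends <- start - 1L + cumsum(len)
  starts <- c(start, ends[-length(ends)] + 1L)
  tibble::tibble(type = type, start = starts, end = ends)
}

#' Simulate a reference genome with gene annotation
#'
#' Random A/C/G/T chromosomes plus non-overlapping gene models (5'UTR,
#' coding exons, introns, 3'UTR) covering approximately `genic_fraction` of
#' the genome; intergenic gap lengths are exponential with the mean implied
#' by the target fraction. Deterministic given the seed.
#'
#' @param n_chrom number of chromosomes (default 2).
#' @param chrom_len chromosome length in bp (scalar or per-chromosome).
#' @param genic_fraction target fraction of the genome inside gene bodies
#'   (default 0.3; must be in `(0, 1]`).
#' @param seed integer seed (required).
#' @return list with `ref` (named `DNAStringSet`) and `annotation`
#'   (`GRanges` with `type` in gene/CDS/five_prime_UTR/three_prime_UTR and a
#'   gene `ID`).
#' @export
simulate_reference <- function(n_chrom = 2, chrom_len = 1e5,
                               genic_fraction = 0.3, seed) {
  if (missing(seed)) rlang::abort("`seed` is required")
  if (genic_fraction > 1 || genic_fraction <= 0) {
    rlang::abort("genic_fraction must be in (0, 1]")
  }
  chrom_len <- as.integer(rep_len(chrom_len, n_chrom))
  withr::with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    seqs <- Biostrings::DNAStringSet(vapply(chrom_len, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)))
    names(seqs) <- chroms
    mean_gene <- 2000
    mean_gap <- max(1, mean_gene * (1 / genic_fraction - 1))
    feats <- list()
    gid <- 0L
    for (ci in seq_len(n_chrom)) {
      at <- 1L + as.integer(stats::rexp(1, 1 / mean_gap))
      while (TRUE) {
        gm <- random_gene_model(at)
        if (max(gm$end) > chrom_len[ci]) break
        gid <- gid + 1L
        id <- sprintf("gene%05d", gid)
        gene_row <- tibble::tibble(type = "gene", start = min(gm$start),
                                   end = max(gm$end))
        gm_all <- dplyr::bind_rows(gene_row, gm[gm$type != "intron", ])
        gm_all$chrom <- chroms[ci]
        gm_all$ID <- id
        feats[[length(feats) + 1]] <- gm_all
        at <- max(gm$end) + 1L + as.integer(stats::rexp(1, 1 / mean_gap))
      }
    }
    ann <- dplyr::bind_rows(feats)
    # reading-frame phase for CDS features (GFF3 column 8), per gene
    ann$phase <- NA_integer_
    for (id in unique(ann$ID)) {
      ci <- which(ann$ID == id & ann$type == "CDS")
      if (length(ci) == 0) next
      lens <- ann$end[ci] - ann$start[ci] + 1L
      ann$phase[ci] <- as.integer((3L - (cumsum(c(0L, lens[-length(lens)])) %% 3L)) %% 3L)
    }
    gr <- GenomicRanges::GRanges(ann$chrom,
                                 IRanges::IRanges(ann$start, ann$end),
                                 strand = "+")
    gr$type <- ann$type
    gr$ID <- ann$ID
    gr$phase <- ann$phase
    list(ref = seqs, annotation = gr)
  })
}

#' Simulate founder genotypes under Hardy-Weinberg with inbreeding
#'
#' Places `n_sites` biallelic SNPs (uniformly, avoiding duplicates) on the
#' reference, draws a per-site alternate-allele frequency from the chosen
#' spectrum, and samples phased genotypes with inbreeding coefficient `f`:
#' with probability `f` the two haplotypes are identical by descent (one
#' Bernoulli(p) draw), otherwise independent — giving genotype probabilities
#' `p^2 + f p q`, `2 p q (1 - f)`, `q^2 + f p q`.
#'
#' @param ref named `DNAStringSet` (e.g. from [simulate_reference()]), or
#'   `NULL` with `chrom_len`/`n_chrom` given.
#' @param n_sites number of SNPs.
#' @param n_samples number of diploid samples.
#' @param af_dist `"uniform"` (on `[0.01, 0.99]`) or `"beta"` (scaled to the
#'   same support).
#' @param beta_shape shape parameters for `af_dist = "beta"`
#'   (default `c(0.5, 0.5)`, a U-shaped spectrum rich in rare alleles as in
#'   an unascertained callset).
#' @param f inbreeding coefficient in `[0, 1)`.
#' @param n_chrom,chrom_len used only when `ref` is `NULL`.
#' @param seed integer seed (required).
#' @return a phased [geno_table()]; true allele frequencies in the
#'   `true_af` column.
#' @export
simulate_founders <- function(ref = NULL, n_sites = 1000, n_samples = 20,
                              af_dist = c("uniform", "beta"),
                              beta_shape = c(0.5, 0.5), f = 0,
                              n_chrom = 2, chrom_len = 1e6, seed) {
  if (missing(seed)) rlang::abort("`seed` is required")
  af_dist <- match.arg(af_dist)
  stopifnot(f >= 0, f < 1)
  if (!is.null(ref)) {
    chroms <- names(ref)
    lens <- Biostrings::width(ref)
  } else {
    chroms <- paste0("chr", seq_len(n_chrom))
    lens <- rep_len(as.integer(chrom_len), n_chrom)
  }
  withr::with_seed(seed, {
    chrom_i <- sample.int(length(chroms), n_sites, replace = TRUE,
                          prob = lens / sum(lens))
    pos <- vapply(chrom_i, function(i) sample.int(lens[i], 1), integer(1))
    key <- paste(chrom_i, pos)
    while (anyDuplicated(key)) {
      dup <- which(duplicated(key))
      pos[dup] <- vapply(chrom_i[dup], function(i) sample.int(lens[i], 1), integer(1))
      key <- paste(chrom_i, pos)
    }
    bases <- c("A", "C", "G", "T")
    if (!is.null(ref)) {
      ref_al <- vapply(seq_len(n_sites), function(k) {
        as.character(Biostrings::subseq(ref[[chrom_i[k]]], pos[k], pos[k]))
      }, character(1))
      ref_al[!(ref_al %in% bases)] <- "A"
    } else {
      ref_al <- sample(bases, n_sites, replace = TRUE)
    }
    alt_al <- vapply(ref_al, function(b) sample(setdiff(bases, b), 1), character(1))
    p <- switch(af_dist,
                uniform = stats::runif(n_sites, 0.01, 0.99),
                beta = 0.01 + 0.98 * stats::rbeta(n_sites, beta_shape[1], beta_shape[2]))
    ibd <- matrix(stats::runif(n_sites * n_samples) < f, n_sites, n_samples)
    h1 <- matrix(stats::runif(n_sites * n_samples) < p, n_sites, n_samples) * 1L
    h2 <- matrix(stats::runif(n_sites * n_samples) < p, n_sites, n_samples) * 1L
    h2[ibd] <- h1[ibd]
    colnames(h1) <- colnames(h2) <- sprintf("S%03d", seq_len(n_samples))
    sites <- tibble::tibble(chrom = chroms[chrom_i], pos = as.integer(pos),
                            ref = ref_al, alt = unname(alt_al), true_af = p)
    ord <- order(sites$chrom, sites$pos, method = "radix")
    geno_table(sites[ord, ], (h1 + h2)[ord, , drop = FALSE],
               hap1 = h1[ord, , drop = FALSE], hap2 = h2[ord, , drop = FALSE])
  })
}

# simulate one parent's gametes for all offspring on one chromosome:
# Markov walk along markers with Haldane switch probabilities
sim_gametes <- function(hap1, hap2, cm_pos, n) {
  m <- length(cm_pos)
  r <- haldane_d_to_r(diff(cm_pos) / 100)
  state <- matrix(0L, n, m)
  state[, 1] <- stats::runif(n) < 0.5
  if (m > 1) {
    sw <- matrix(stats::runif(n * (m - 1)) < rep(r, each = n), n, m - 1)
    state[, -1] <- sw
    state <- t(apply(state, 1, cumsum)) %% 2L
  }
  # rows: meioses; columns: markers; value: transmitted allele
  out <- matrix(0L, n, m)
  out[state == 0L] <- rep(hap1, each = n)[state == 0L]
  out[state == 1L] <- rep(hap2, each = n)[state == 1L]
  out
}

#' Simulate an F1 progeny from two phased parents
#'
#' Each offspring receives one gamete per parent; gametes follow a Markov
#' crossover process along each chromosome with Haldane (no interference)
#' recombinant fractions between adjacent markers, under a linear genetic
#' map of `cm_per_chrom` centimorgans per chromosome (proportional to bp).
#' Meioses are independent. Unphased parents are an error.
#'
#' @param parents phased genotype table with (at least) the two parent
#'   samples.
#' @param parent1,parent2 sample ids (default: first two samples).
#' @param n_offspring number of F1 individuals.
#' @param cm_per_chrom genetic length per chromosome in cM (scalar or named
#'   by chromosome).
#' @param seed integer seed (required).
#' @return a `cross_dataset` (see [cross_dataset()]); offspring are named
#'   `F1_001`, ...
#' @export
simulate_f1 <- function(parents, parent1 = NULL, parent2 = NULL,
                        n_offspring = 100, cm_per_chrom = 100, seed) {
  if (missing(seed)) rlang::abort("`seed` is required")
  assert_geno(parents)
  if (!is_phased(parents)) rlang::abort("parents must be phased (hap1/hap2 present)")
  ids <- geno_samples(parents)
  if (is.null(parent1)) parent1 <- ids[1]
  if (is.null(parent2)) parent2 <- ids[2]
  chroms <- unique(parents$chrom)
  cm <- if (is.null(names(cm_per_chrom))) {
    stats::setNames(rep_len(cm_per_chrom, length(chroms)), chroms)
  } else cm_per_chrom
  seeds <- seed_children(seed, 2 * length(chroms))
  off <- matrix(NA_integer_, nrow(parents), n_offspring)
  colnames(off) <- sprintf("F1_%03d", seq_len(n_offspring))
  for (ci in seq_along(chroms)) {
    i <- which(parents$chrom == chroms[ci])
    span <- max(parents$pos[i]) - min(parents$pos[i])
    cm_pos <- if (span == 0) rep(0, length(i)) else
      (parents$pos[i] - min(parents$pos[i])) / span * cm[[chroms[ci]]]
    g1 <- withr::with_seed(seeds[2 * ci - 1], sim_gametes(
      parents$hap1[i, parent1], parents$hap2[i, parent1], cm_pos, n_offspring))
    g2 <- withr::with_seed(seeds[2 * ci], sim_gametes(
      parents$hap1[i, parent2], parents$hap2[i, parent2], cm_pos, n_offspring))
    off[i, ] <- t(g1 + g2)
  }
  g <- geno_table(parents[, c("chrom", "pos", "ref", "alt")],
                  cbind(parents$gt[, c(parent1, parent2)], off))
  cross_dataset(g, parent1, parent2)
}

# core perturbation on a dosage matrix
perturb_matrix <- function(gt, error_rate, error_model, missing_rate, seed) {
  withr::with_seed(seed, {
    err_sel <- matrix(stats::runif(length(gt)) < error_rate, nrow(gt))
    err_sel[is.na(gt)] <- FALSE
    new <- gt
    if (error_model == "uniform_swap") {
      idx <- which(err_sel)
      shift <- sample(1:2, length(idx), replace = TRUE)
      new[idx] <- (gt[idx] + shift) %% 3L
    } else if (error_model == "allelic_dropout") {
      idx <- which(err_sel & gt == 1L)
      new[idx] <- sample(c(0L, 2L), length(idx), replace = TRUE)
      err_sel <- err_sel & gt == 1L  # only realised errors
    } else {
      rlang::abort(paste0("unknown error model: ", error_model))
    }
    miss_sel <- matrix(stats::runif(length(gt)) < missing_rate, nrow(gt))
    miss_sel[is.na(gt)] <- FALSE
    new[miss_sel] <- NA_integer_
    list(gt = new, error_mask = err_sel, missing_mask = miss_sel)
  })
}

#' Inject genotyping errors and missingness
#'
#' Perturbs each call independently: with probability `error_rate` it is
#' made erroneous under the chosen model (`"uniform_swap"`: replaced by one
#' of the two other dosage classes, equiprobably; `"allelic_dropout"`: a
#' heterozygote becomes either homozygote — selected non-het calls are left
#' unchanged and not counted as errors), then with probability
#' `missing_rate` it is masked missing. The truth masks of realised errors
#' and masked calls are attached as attributes `"error_mask"` and
#' `"missing_mask"`.
#'
#' @param x a genotype table or a `cross_dataset` (only offspring calls are
#'   perturbed for a cross).
#' @param error_rate per-call error probability.
#' @param error_model `"uniform_swap"` (default) or `"allelic_dropout"`.
#' @param missing_rate per-call missing probability.
#' @param seed integer seed (required).
#' @return the perturbed object, with truth-mask attributes.
#' @export
inject_errors_and_missing <- function(x, error_rate, error_model = "uniform_swap",
                                      missing_rate = 0, seed) {
  if (missing(seed)) rlang::abort("`seed` is required")
  stopifnot(error_rate >= 0, error_rate < 1, missing_rate >= 0, missing_rate < 1)
  if (inherits(x, "cross_dataset")) {
    p <- perturb_matrix(x$off, error_rate, error_model, missing_rate, seed)
    x$off <- p$gt
    attr(x, "error_mask") <- p$error_mask
    attr(x, "missing_mask") <- p$missing_mask
    return(x)
  }
  assert_geno(x)
  p <- perturb_matrix(x$gt, error_rate, error_model, missing_rate, seed)
  x$gt <- p$gt
  x$hap1 <- NULL  # phase no longer consistent with perturbed calls
  x$hap2 <- NULL
  attr(x, "error_mask") <- p$error_mask
  attr(x, "missing_mask") <- p$missing_mask
  x
}
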