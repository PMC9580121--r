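---
title: "Designing and validating SPET genotyping panels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating SPET genotyping panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spetpanel)
```

## Scope

Single primer enrichment technology (SPET) genotypes a fixed set of *target*
SNPs by hybridising ~40-base probes immediately adjacent to each target; the
sequenced enrichment footprint downstream of a probe also recovers nearby
*accessory* (non-target) polymorphisms. spetpanel covers the two computational
ends of such an assay:

* **design** — turning a whole-genome variant callset, a reference sequence
  and a gene annotation into a budgeted, regularly spaced panel of eligible
  target SNPs with probe windows; and
* **validation** — classifying post-assay calls as target/accessory, checking
  ascertainment bias by MAF-spectrum correlation, pruning linkage
  disequilibrium, classifying pseudo-testcross marker configurations in F1
  progenies, and estimating the genotyping-error rate from Mendelian
  inconsistencies.

Read alignment and variant calling are upstream of the package: it consumes
VCF. Map construction, QTL mapping, GWAS and population-structure inference
are downstream and out of scope.

## Genotype representation

Genotypes are diploid dosages of the alternate allele (0/1/2, `NA` missing)
held in a matrix column `gt` of a tibble with one row per site; phased data
carry 0/1 haplotype indicator columns `hap1`/`hap2`. Internally every
interval computation is done on 1-based inclusive coordinates as stored from
VCF; BED output is converted to 0-based half-open at the writer, and each
report states its convention.

## Site filtering

`apply_hard_filters()` reproduces the conventional GATK-style hard-filter
cascade on caller annotations, with strict comparisons exactly as the filter
expression `QD < 2.0 || MQ < 40.0 || MQRankSum < -12.5` is evaluated:
boundary values pass. Sites lacking an annotation pass that specific rule by
default — a hom-only site has no `MQRankSum`, and a filtering engine skips
the clause — with `fail_if_absent` available for stricter behaviour. The
depth rule uses the across-sample mean of per-sample `DP` (`min_mean_dp`,
default 30); a per-sample variant is provided because conventions differ
between callsets. Missingness is capped at 0.10, i.e. at least 90% of
samples called. The clean-set stage `maf_filter()` retains sites with folded
minor-allele frequency strictly greater than 0.05; being a strict
inequality, a site at exactly the threshold is removed, and the filter is
idempotent.

## Panel design

A candidate target must satisfy four classes of rule
(`eligibility_filter()`, which records the first failing rule per
candidate):

1. **Informativeness** — alternate-allele frequency within 0.10–0.90
   (equivalently, folded MAF at least 0.10).
2. **Paralogy guard** — observed heterozygosity at most `het_excess_max`
   (default 0.60); an excess of heterozygotes is the classic signature of
   collapsed paralogous loci.
3. **Probe geometry** — both `probe_len` = 40 bp windows immediately 5' and
   3' of the site must lie inside the chromosome and contain no ambiguous
   base, so a probe can be designed on either border.
4. **Accessory potential** — at least `min_flanking_snps` = 2 other known
   SNPs within the `footprint_len` = 150 bp enrichment footprint. We read
   the flanking-SNP criterion as *requiring* nearby polymorphism (it is what
   makes accessory discovery productive); the opposite reading — probes must
   avoid polymorphisms for clean hybridisation — is available through
   `max_probe_window_snps`.

`select_targets()` then maximises the number of selected targets per
chromosome subject to the spacing rule: position-adjacent selected targets
must be at least 5 kb apart when genic (CDS-context) and 10 kb when
intergenic, a mixed adjacent pair taking the larger of the two class gaps
(the conservative combination; per-class gaps alone do not define the mixed
case). Selection is an exact dynamic program over position-sorted
candidates rather than a single greedy sweep: with class-dependent gaps the
plain left-to-right greedy scan is not optimal (a low-gap pair just behind
an accepted high-gap candidate can be lost), whereas the adjacent-pair DP
attains the true maximum and coincides with the greedy solution whenever
the gap is uniform. Ties are broken deterministically toward the earliest
positions, then `(ref, alt)` lexicographically. If the unconstrained
maximum exceeds the probe `budget` (default 25,000), candidates are
re-ranked globally — `|alt_freq - 0.5|` ascending (favouring maximally
informative markers), genic before intergenic, then position — and accepted
greedily in rank order under the same spacing constraints until the budget
binds. The design is byte-reproducible given inputs and configuration.

Probe sequences are emitted for both sides (`extract_probe_sequences()`),
the right probe reverse-complemented so both read toward the target.
Thermodynamic probe scoring (Tm, hairpins, cross-hybridisation) is a vendor
step and deliberately out of scope. Post-assay, `classify_called_sites()`
labels a called site `target` on an exact `(chrom, pos)` match and
`accessory` within `footprint_len` of a target.

## Ascertainment bias and panel summaries

`maf_spectrum()` bins folded MAF on [0, 0.5] (half-open bins, last closed;
bin indices are computed with a 1e-9 tolerance so representable edge values
such as 0.3 land in their nominal bin). `spectrum_correlation()` pairs
shared sites strictly by `(chrom, pos, ref, alt)` and reports the Pearson
correlation of per-site folded MAF between, typically, the assay panel and
the whole-genome callset the panel was designed from; strong correlation
indicates the selected markers still reflect population-wide allele
frequencies. Because "correlating spectra" can also mean correlating the
binned histograms, a `binned` mode is provided; `glance()` reports which
mode produced the number together with both dataset sizes and the shared
count. `adjacent_spacing()` and `sample_heterozygosity()` provide the
spacing and per-sample heterozygosity summaries used in panel reports.

## Linkage disequilibrium

`genotype_r2()` is composite LD: the squared Pearson correlation of dosages
over samples called at both sites. It needs no phase, is symmetric, and is
invariant to allele-coding swaps; a constant dosage vector on the shared
sample set leaves it undefined (`NA`). `ld_prune()` slides a window of
`window_size` = 50 sites stepped by `window_step` = 5; within a window the
lower-MAF member of any pair exceeding `r2_threshold` = 0.3 is dropped
(ties: the later position). The windowed scan is iterated to a fixpoint
over the currently kept sites, so pruning its own output is a no-op. A
threshold on |r| instead of r² is available (`use_r`) since pruning
thresholds are sometimes quoted on the correlation scale. `ld_decay()` bins
all within-chromosome pairs up to `max_decay_dist` by physical distance and
reports per-bin mean r² with pair counts. Missing data are handled by
pairwise-complete samples throughout; no imputation, no phased D'.

## Mendelian-inconsistency error estimation

For an F1 cross, markers classify by parental heterozygosity
(`classify_cp_marker()`): `lmxll` (seed parent heterozygous), `nnxnp`
(pollen parent), `hkxhk` (both), `aaxbb` (opposite homozygotes),
`monomorphic`, or `missing_parent`. Every (marker, offspring) call with
both parents and the offspring called — segregating *and* monomorphic
markers — is checked against the set of genotypes producible from one
gamete per parent (`mendelian_check()`).

The raw inconsistency rate understates the true per-call error rate because
error detectability depends on the configuration: at an hk×hk marker all
three genotypes are producible, so *no* error is visible; at lm×ll exactly
half of the possible wrong states remain consistent; at monomorphic and
aa×bb markers every wrong state is inconsistent. `detectable_fraction()`
derives these probabilities by exact enumeration over the Mendelian
distribution of true offspring genotypes and the error model — they are
computed, not hard-coded. `estimate_error_rate()` reports

* `raw_rate` = inconsistent / checked calls,
* `detectable_fraction` = checked-call-weighted mean of per-code
  detectable fractions, and
* `adjusted_rate` = raw / detectable — the de-biased per-call error rate,

plus the singleton fraction (share of flagged markers with exactly one
inconsistent offspring), a useful diagnostic separating isolated random
miscalls from systematically failing markers. Singleton inconsistencies are
counted in the rate, not excluded.

Two error models are exposed. `uniform_swap` (default): an erroneous call
is replaced by one of the two other dosage classes with equal probability;
under this model the checked-call-weighted adjustment is exactly unbiased,
which the test suite verifies by parameter recovery across injected rates
0.5–5%. `allelic_dropout`: a heterozygote is miscalled as either homozygote;
errors then only occur at heterozygous calls, so codes with no heterozygous
offspring carry no error mass (their detectable fraction is `NaN` and they
are dropped from the weighted mean), and the adjustment is approximate
because the weighting ignores the varying proportion of heterozygous
offspring per code. Both raw and adjusted figures are always reported, as
is the per-code breakdown (`tidy()`).

`segregation_distortion()` is the df = 1 chi-square goodness-of-fit of the
two producible offspring classes of an lm×ll / nn×np marker against 1:1,
flagged at p <= 0.05; `collapse_identical()` groups markers whose pairwise
genotype identity exceeds 0.95 by single linkage and keeps the least-missing
representative (ties: lowest position). `export_cp_loci()` writes the
mappable single-parent-heterozygous markers in a JoinMap-style CP coding.

## The simulator

The simulator exists so that the full pipeline — reference, annotation,
founders, panel design, F1 progenies, error injection — runs with known
ground truth and no external data. Its defaults emulate the data regime the
assay targets: a SNP-dense plant genome with a U-shaped unascertained
allele-frequency spectrum (Beta(0.5, 0.5) scaled to [0.01, 0.99]),
outbred founders (`f` = 0) with an inbreeding option for selfed material,
low missingness, and per-call error rates around 1–2%.

* `simulate_reference()` draws uniform A/C/G/T chromosomes and
  non-overlapping gene models (5'UTR, 2–4 coding exons with introns, 3'UTR;
  mean gene ~2 kb) with exponential intergenic gaps whose mean is set by
  the target genic fraction.
* `simulate_founders()` draws per-site allele frequencies from the chosen
  spectrum and phased genotypes with inbreeding coefficient `f` via an
  identity-by-descent indicator, giving genotype probabilities
  p² + f·p·q, 2pq(1 − f), q² + f·p·q.
* `simulate_f1()` forms each gamete by a Markov walk along the markers of a
  chromosome with Haldane (no-interference) recombinant fractions
  r = (1 − e^(−2d))/2 between adjacent markers, under a linear genetic map
  (`cm_per_chrom`, default 100 cM). Haldane was chosen over Kosambi as the
  simpler null — crossover interference is irrelevant to the estimators
  tested here; Kosambi conversions are provided as utilities only.
* `inject_errors_and_missing()` perturbs each call independently under the
  chosen error model, then masks calls missing, recording exact truth
  masks. Under `allelic_dropout` a selected non-heterozygous call is left
  unchanged and not counted as a realised error.

All randomness flows from explicit `seed` arguments; child seeds are drawn
from a parent seed so each stage is independently reproducible, and no
function touches the global RNG state (restored via `withr`).

### What the simulator does not emulate

Founder sites are in linkage equilibrium (no coalescent ancestry), there is
no population structure or selection, error rates are homogeneous across
sites and samples, and depth/quality annotations are not generated jointly
with genotypes. Passing recovery tests on these data therefore demonstrates
the correctness of the estimators and selection logic, not robustness to
structured real-world artefacts such as clustered errors at paralogs —
which the heterozygosity-excess guard addresses only heuristically.

## Validation scale and numerical choices

The shipped tests run at desk scale: error-rate recovery uses 2 phased
parents, 150 offspring and 20,000 markers spanning all CP classes (3 x 10^6
checked calls; the adjusted estimate is required to land within
1.6–2.0% of the injected 1.8%); designer optimality is verified against
exhaustive subset enumeration on 200 random instances of up to 15
candidates; LD statistics are checked against from-scratch correlations on
1,000 random pairs; map-function calibration uses 10,000 meioses (realised
recombinant fraction at 50 cM within 0.02 of the Haldane value 0.316); and
distortion p-values are checked for uniformity on 2,000 markers of 5,000
offspring each — the large per-marker count keeps the discreteness of the
binomial lattice well below the Kolmogorov–Smirnov resolution. Monte-Carlo
tolerances are set at 2–3 standard errors of the quantity under its fixed
seed.

Other numerical conventions: folded frequencies are used everywhere a MAF
is reported; dosage correlations use pairwise-complete observations; the
chi-square test is the closed-form df = 1 statistic (no continuity
correction), matching its textbook use for 1:1 segregation; and all
selection and pruning tie-breaks are deterministic so identical inputs give
byte-identical outputs.

## Known limitations

* The budget-constrained re-selection is greedy in score order; when the
  budget binds it is deterministic and spacing-feasible but not provably
  count- or score-optimal (the unbudgeted maximisation is exact).
* Composite r² treats dosages as numeric; for strongly inbred material an
  explicit genotypic disequilibrium measure would be preferable.
* The detectability adjustment assumes parental genotypes are error-free;
  parental errors misclassify the configuration and bias the estimate
  (validation progenies are normally genotyped at depth precisely to pin
  the parents down).
* Chromosome names are opaque labels; no liftover or linkage-group
  reassignment is attempted.
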