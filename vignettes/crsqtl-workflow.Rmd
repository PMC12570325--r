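---
title: "Collapsed rare-variant splicing QTL analysis with crsqtlkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapsed rare-variant splicing QTL analysis with crsqtlkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Rare-variant burden tests (BTs) collapse qualifying variants in a gene into a
single carrier indicator and regress case-control status on it. Their power
hinges on the qualifying-variant definition: when only a subset of
splice-altering variants in a gene is pathogenic, benign qualifying variants
dilute the signal. A collapsed rare-variant splicing QTL (crsQTL) addresses
this by grouping variants not by gene but by a shared, experimentally
observed splicing consequence: a reference splice junction detected in
RNA-seq of disease-relevant tissue. Variants are linked to junctions through
sequence-to-function splice predictions (SpliceAI or Pangolin annotations),
and each junction's variant set is then tested as its own collapsing unit.

The pipeline has three stages:

1. **Reference junction database.** Per-sample junction outlier p-values
   (from an upstream outlier model such as LeafCutterMD; consumed as input,
   never recomputed) are thresholded at `alpha = 0.05` (strict `<`).
   Candidate junctions are classified against the gene annotation plus an
   external known-junction catalog; only `unannotated_exon_skipping`,
   `unannotated_donor` and `unannotated_acceptor` events survive
   (`annotated` and `complex` are dropped). Region filters remove junctions
   in blacklist intervals (any-base overlap), in genes with median
   expression TPM < 2 (strict), and on sex chromosomes. Cohort-mode entries
   must replicate in at least 2 tissue types of the same donor; each donor's
   tissue p-values are combined with Fisher's method
   (X = -2 &Sigma; log p ~ &chi;&sup2; with 2k df). An alternative
   cryptic-exon mode keeps junctions detectable (raw read count &ge; 1) in
   any case sample but in at most 10% of control samples.
2. **Variant-junction matching.** A qualifying prediction (delta score
   &ge; 0.2) matches a junction if (a) it predicts **gain** of an
   *unannotated* site and the junction uses that site as a boundary, or (b)
   it predicts **loss** of an *annotated* site and the junction omits that
   site. Candidate variants are restricted to the window spanning the
   nearest annotated exon on each side of the junction plus the intervening
   sequence. A variant is a *full* match when all of its qualifying
   predictions match, *partial* when only some do; both tiers are collapsed
   by default.
3. **Association.** Carrier indicators (allelic: genotype &ge; 1; recessive:
   genotype = 2) are tested with Firth penalized logistic regression,
   &ell;*(&beta;) = &ell;(&beta;) + &frac12; log det I(&beta;), which stays
   finite under complete separation — the operative regime when carriers
   appear only in cases. P-values are penalized likelihood-ratio tests.
   Units with fewer than 3 carriers are skipped, not tested.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `alpha` (outlier cutoff) | 0.05 | strict `<`, applied per sample and tissue |
| `min_tissues` (replication) | 2 | distinct tissues within one donor |
| `tpm_floor` | 2 | strict `<` removes the gene's junctions |
| `max_control_fraction` (CE mode) | 0.1 | strictly more than 10% removes |
| `delta_min` (qualifying score) | 0.2 | inclusive (&ge;), both SpliceAI and Pangolin |
| `tol` / `--site-tolerance` | 2 bp | 0 gives exact boundary matching |
| `pop_af_max`, `cohort_carrier_max` | 0.001 | strict `<`; allelic uses carrier, recessive homozygote frequency |
| `min_carriers` | 3 | skip gate for association units |

The site tolerance exists because the exact genomic base a predictor's
position offset denotes (intronic boundary base vs adjacent exonic base) is
convention-dependent; a match is accepted within `tol` of either the
junction's boundary base or its adjacent exonic base, so results are robust
to the off-by-one between conventions. Set `tol = 0` for exact matching.

## Conventions and design choices

These were genuinely open choices; the package fixes them as follows.

* **Coordinates.** Junctions are stored 1-based inclusive over the intronic
  interval, identifier `chrom:start:end:strand`. RegTools BED input
  (0-based, with anchor overhangs encoded in the block sizes) is converted
  on read.
* **Donor/acceptor sites** are keyed by the intronic boundary base: on `+`
  the donor is the intron start and the acceptor the intron end, mirrored
  on `-`. The &plusmn;2 bp tolerance makes matching insensitive to the
  alternative (exon-side) convention.
* **Gene assignment** is strand-aware; a junction overlapping zero or more
  than one gene on its own strand is `complex`. A junction whose boundaries
  are both annotated sites but which skips no annotated exon and equals no
  known junction is also `complex` (a low-confidence novel combination, not
  a clean skipping event).
* **Nearest flanking exon**: the annotated exon (any retained transcript)
  whose inner boundary is closest to the junction on that side; ties go to
  the longer exon. Different transcripts can disagree here; the tie rule is
  a package choice.
* **"Omits an annotated site"** is operationalized as *either* the site
  lying strictly inside the intron interval (spliced over, e.g. exon
  skipping) *or* same-side alternative-site usage within the flanking
  window. Each match records which clause fired. Either clause alone would
  miss real cases (intron-retention-adjacent vs exon skipping).
* **Cross-tissue replication** requires the outlier p-value to pass
  `alpha` in each tissue, the stricter reading of "reproducible outlier";
  mere detection in a second tissue does not count.
* **Fisher combination** is per donor; when several donors carry a
  junction the minimum donor meta-p is stored and all donors recorded.
* **Pangolin usage-increase at an annotated site never matches**: the gain
  rule requires the gained site to be unannotated, so increased usage of an
  existing junction is not evidence for a *novel* junction.
* **Recessive model** counts homozygous-alternate carriers only; compound
  heterozygosity is out of scope (phasing unavailable).
* **Min-carrier gating** counts carriers (samples), not variant
  observations.
* **Missing genotypes** are non-carriers for burden and frequency purposes;
  per-variant missingness is reported.
* **Firth numerics.** Newton iteration with step-halving on any decrease of
  the penalized likelihood; convergence at max |score| < 1e-6 or step norm
  < 1e-8, at most 50 iterations; non-convergence is an error, never a
  silent result. All coefficients (covariates included) share the Jeffreys
  penalty. P-values are penalized LRTs (refit with the coefficient pinned
  at zero, penalty still evaluated on the full design) because Wald
  intervals degenerate under separation. Collinear designs are rejected.
* **Fisher's method** is computed directly against the chi-square
  upper tail (the dedicated pooling package the workflow originated with is
  not a dependency here).
* **VCF genotypes** are read with a light text pass rather than the full
  S4 VCF genotype parser, whose preallocation is prohibitive on
  cohort-width (thousands of samples) uncompressed VCFs; fixed fields and
  INFO still go through `VariantAnnotation`.

## What the synthetic generator emulates

`simulate_cohort()` emits every input the pipeline reads: a toy multi-gene
annotation (GTF with `basic` tags), a known-junction catalog, junction
counts and outlier p-values over an RNA reference cohort (default 294 case /
76 control donors, 1-4 CNS tissues each), an annotated VCF with genotypes
for a WGS case-control cohort (default 6,625 / 2,472), population
frequencies, gene TPMs and a blacklist. Planted crsQTLs are exon-skipping
junctions expressed (near-zero outlier p-values, non-zero counts) in a
configurable number of case donors across &ge; 2 tissues, with pathogenic
variants carrying qualifying acceptor-loss predictions that point at the
skipped exon's annotated acceptor. Benign variants carry qualifying scores
whose predicted sites match nothing. Case-control genotypes are drawn
retrospectively: carrier probability in controls is the configured
frequency, in cases the frequency implied by the configured odds ratio.
Null outlier p-values are uniform; planted ones are drawn from
10^-U(3.5, 6).

Each output file has its own pseudo-random stream derived from the master
seed, so adding outputs never perturbs existing ones, and identical
configurations reproduce byte-identical bundles.

What the generator deliberately does **not** emulate: linkage
disequilibrium, population stratification, sequencing error, read-level
noise in the outlier statistics (p-values are generated directly, since the
upstream outlier model is an input, not part of this package), and
covariate confounding. A green end-to-end test therefore establishes that
the pipeline's logic recovers planted structure under its stated
assumptions — not that those assumptions hold in any particular real
cohort. Published odds ratios and p-values from real cohorts are likewise
not reproduction targets: they depend on covariates (sex, platform,
principal components, synonymous burden) that are not available here.

The dilution scenario (`make_fig1a_scenario()`) isolates the mechanism the
framework exists for: a few pathogenic variants (default 3) matched to one
planted junction among many benign qualifying variants (default 23) in the
same gene, in a balanced 5000/5000 cohort with odds ratio 20 and a control
carrier frequency of 1e-4 (about ten expected case carriers). At those
defaults the crsQTL test yields a smaller p-value than the score-filtered
gene burden test in well over 95% of replicates — that comparison, not any
absolute power figure, is the claim the simulation supports. The absolute
power of the crsQTL unit test at these defaults is about 0.91 at
&alpha; = 0.05 (estimated by simulation; the carrier count is small and
variable), which the test suite asserts via a binomial envelope around the
simulated value.

## Degenerate inputs

Junctions without an annotated flanking exon on one side raise a
`WindowUndefined` condition and are skipped with a warning in bulk
operations. Empty variant sets are errors for burden collapsing; zero
qualifying variants yield a skipped association row, not an error. Constant
dosage is an error for the dosage-usage regression. Multi-allelic VCF
records must be pre-split. p-values outside (0, 1] are domain errors for
Fisher combination.

## Known limitations

* The framework can only build crsQTLs for junctions its reference RNA-seq
  cohort happened to express; `detection_probability(p, n) = 1 - exp(-np)`
  quantifies that ceiling as a function of junction frequency and reference
  cohort size.
* Matching quality is bounded by the upstream splice predictors; variants
  whose effect is condition-dependent (e.g. apparent only under TDP-43
  dysfunction) are invisible to them.
* When most splice-altering variants in a gene are pathogenic, a plain
  score-filtered gene burden test is the more powerful design; the crsQTL
  framework complements rather than replaces it.
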