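---
title: "Differential methylation calling and methylome discrimination with methylDMA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation calling and methylome discrimination with methylDMA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

methylDMA analyses whole-genome bisulfite methylomes given as per-cytosine
count tables (methylated and unmethylated reads per position, strand and
sequence context). Plant genomes methylate cytosines in three contexts —
CG, CHG and CHH (H = A, C or T) — through distinct pathways, so every step
of the pipeline is context-aware. The pipeline has four stages:

1. **Pairwise DMP calling.** At each cytosine covered by at least four
   reads in both samples and by at least two methylated reads in at least
   one, the 2x2 table (methylated/unmethylated by sample) is tested with a
   two-sided Fisher exact test. CG positions are called differentially
   methylated (DMPs) at a Storey q-value below 0.05 computed over all
   tested CG sites. CHG and CHH use a two-stage rule: only positions with
   raw p < 0.05 enter the q-value computation, and calls require q < 0.035
   within that subset. Tested-but-not-significant positions are NDMPs;
   positions failing the coverage filter are reported as untested rather
   than folded into the NDMP class, because the two kinds of "not a DMP"
   have different evidential status.
2. **Annotation.** DMPs are assigned to containing features (priority
   te_gene > transposon > gene, then smallest interval), boundary-bin
   metaprofiles are accumulated in 100-bp bins from -2 kb to +2 kb around
   feature starts and ends, and chromosome-scale density tracks are
   normalized to the genome-wide maximum window so all chromosomes share
   one scale. A Fisher test on (DMR-associated vs not) x (contains TE gene
   vs not) quantifies TE-gene enrichment.
3. **Group-wise DMRs and tiling windows.** Candidate regions are maximal
   runs of well-covered same-context sites (gaps <= 100 bp, >= 5 sites);
   per-sample region levels are pooled proportions; the region test is a
   two-sided Fisher exact test on group-pooled counts with
   Benjamini-Hochberg adjustment, an effect-size gate (mean difference
   >= 0.1) and two consistency gates described below. Annotation-free
   tiling windows (340 bp, >= 20 covered sites) provide an alternative
   feature space.
4. **Discriminant analysis.** Samples become vectors of region methylation
   means; PCA (first four components) feeds an LDA with two discriminant
   functions; Ward clustering with squared Euclidean distances groups the
   LDA coordinates; Pillai's trace V = tr(H(H+E)^-1) with its F
   approximation tests centroid separation; repeated stratified k-fold
   cross-validation (LDA and a linear-kernel SVM) estimates discrimination
   accuracy.

# Statistical and numerical choices

**Two-sided Fisher rule.** The two-sided p-value sums hypergeometric point
probabilities not exceeding the observed table's probability within
relative tolerance 1e-7 (the conventional definition; no mid-p variant).
The implementation is vectorized over sites via `dhyper`; the test suite
checks it against an independent exhaustive enumeration over every 2x2
table with margins up to 30 at relative error below 1e-12.

**Storey q-values.** pi0 is estimated by evaluating
pi0(lambda) = #{p > lambda}/(m(1-lambda)) on lambda = 0, 0.05, ..., 0.90,
smoothing with a cubic spline (df = 3) and reading the fit at the largest
lambda, clipped to (0, 1]. Below 100 p-values the smoother is unstable and
pi0 falls back to 1, making the q-values the classic step-up adjustment.
Computing non-CG q-values inside the p < 0.05 subset follows the two-stage
policy literally; the statistical caveat is that subsetting breaks the
uniform-null assumption behind pi0 (estimates are biased upward, making
the rule conservative). `genomewideNonCg = TRUE` switches to genome-wide
q-values for CHG/CHH.

**Eligibility and ties.** "Genotype" is a single sample — the design
compares individual plants without replicate pooling at the position
level. Sites with equal proportions give p = 1 and can never be DMPs;
direction (hyper/hypo) is defined only for DMPs, relative to the
reference sample (the second sample of the pair).

**Boundary bins.** Offsets are strand-oriented (negative = upstream of
the 5' boundary; unstranded features are treated as plus-strand), binned
by floor((offset + 2000)/100) into bins 0..39, so offset 0 (the boundary
base) falls in bin 20. The length-adjustment denominator is the
proportion of annotated features long enough to host each interior bin
(a bin covering offsets [lo, hi) from the start anchor needs length
>= hi); a flag switches the denominator to DMP-bearing features only.
The feature-based default is deterministic given the annotation and
matches the correction's purpose: short features cannot host deep
interior bins, which would otherwise depress interior frequencies.
Max scaling divides by the maximum over all samples and contexts, and
across feature kinds when kinds are being compared
(`scaleAcrossKinds = TRUE`, the default).

**DMR caller.** The region caller is a deliberately transparent
substitute for smoothed beta-regression approaches: cluster, pool, test,
adjust, gate. Two guard gates supplement the pooled testing
because pooling treats reads as replicates and ignores site
heterogeneity. A region straddling a feature boundary can mix baseline
levels of 0.85 and 0.05; negative-binomial coverage fluctuations then
move each sample's coverage-weighted pooled level by enough (about 0.05
to 0.15) to clear both the pooled-Fisher test and the effect-size gate
without any group effect. The replicate gate (Welch t-test on per-sample
region levels, p < 0.05, skipped when a group has fewer than two
samples) requires the shift to reproduce across samples; the stratified
gate (Cochran-Mantel-Haenszel across per-site strata, p < 0.05)
conditions between-site baselines away entirely, so pooled-level
artifacts that vanish within sites are rejected. In the planted-truth
benchmarks these gates remove boundary artifacts (stratified CMH p
around 0.4) while planted regions retain p-values below 1e-200. Both
gates are parameters and `NA` disables them. Defaults: minimum coverage
4 (reusing the DMP floor), 75% of samples covered, 100-bp maximum gap,
5-site minimum, FDR 0.05, minimum difference 0.1. Group-wise DMRs are
computed for CG and CHG; CHH is available by argument.

**LDA regularization.** Discriminant directions solve the generalized
eigenproblem of between- versus within-group scatter via a symmetric
reduction. With very small groups the raw within-scatter underestimates
variance along the leading discriminant directions — an overfitting
artifact that inflates the sphered coordinates and destabilizes held-out
classification. The within scatter is therefore shrunk linearly toward
its average-variance sphere, (1-s)E + s(tr(E)/p)I with s = 0.05 by
default, plus a 1e-6 tr(E)/p ridge floor against outright singularity;
s = 0 recovers the classic estimator. In held-out benchmarks with three
samples per group any s in [0.01, 0.3] gives equivalent accuracy, so the
default was set at the low end to stay close to classic LDA. Axes (PCA
and LDA) are signed so the largest-magnitude loading is positive, making
reports reproducible across platforms. LDA loadings are reported both in
PC space and back-projected to region space.

**Cross-validation.** The fold count is min(requested folds, smallest
class size, n) — with three samples per class, "10-fold" becomes
stratified 3-fold; with singleton-free classes equal to n it becomes
leave-one-out. PCA and the classifier are refit inside every training
fold, so no information leaks from held-out samples. Fold assignments
are resampled (up to 100 tries) if a training fold would lose a class.
The SVM corroboration uses a linear kernel with unit cost and
one-vs-one voting for more than two groups.

**Pillai's trace** uses the standard F approximation with
s = min(g-1, p), m = (|p-g+1|-1)/2, n* = (N-g-p-1)/2; the total scatter
is ridge-regularized at 1e-6 tr(T)/p before inversion. The statistic is
bounded by s; the test suite verifies the bound, the zero case for
identical groups, and agreement with `summary(manova(...))`.

# The synthetic methylome generator

The generator is a first-class module: it emulates the structural
features the analysis depends on, and it records every planted effect so
recovery can be scored exactly.

* **Genome.** Two chromosomes of 1 Mb by default, centromere at the
  midpoint, pericentromere +/- 150 kb. 200 genes (1-4 kb) uniform on the
  arms; 150 transposons (0.8-3 kb) with half-normal placement around the
  centromere (sd = the pericentromere half-width), 60% flagged as
  containing a TE gene.
* **Cytosines.** Scattered sites per context (defaults 0.008, 0.004 and
  0.012 sites/bp for CG, CHG, CHH — tens of thousands of sites at toy
  scale), plus dense "islands" (25 sites at 25-bp spacing, one per host
  feature where possible) that act as substrate for planted DMRs.
* **Counts.** Coverage is negative binomial with mean 30 and size 5
  (real experiments of this kind reach 50x or more; 30 keeps the test
  suite fast and is configurable); methylated counts are binomial at the
  site's true level. Baselines: gene CG 0.20, transposon CG/CHG/CHH
  0.85/0.60/0.15, everything else 0.05 — the qualitative shape of an
  Arabidopsis methylome.
* **Group profiles.** `wildtype` plants nothing. `mutant` plants non-CG
  hypermethylation (CHG +0.3, CHH +0.4) confined to pericentromeric
  transposons. `epiline` plants genome-wide genic CG gain (+0.3),
  transposon CG loss (-0.4) and transposon CHH gain (+0.3). Scattered
  effects hit a configurable fraction (default 20%) of matching sites as
  group-level DMPs; island effects hit a configurable fraction (default
  50%) of matching islands as group DMRs. Effect sizes default to the
  0.3-0.6 range; these are placeholders for power analysis, not
  estimates of any real biology. Levels are clipped to [0.01, 0.99] to
  avoid degenerate all-or-none sites; with the default baselines and
  deltas no clipping occurs, so every planted effect's true level
  difference equals its delta exactly.
* **Determinism.** All randomness flows from the configuration seed;
  identical configurations reproduce byte-identical count matrices,
  truth tables and pipeline outputs.

What the generator does **not** emulate: sequence-level reads (counts
are drawn directly, so mapping bias, bisulfite non-conversion and PCR
duplicates are absent), spatial autocorrelation of methylation outside
the planted islands, biological replicate variability beyond binomial
sampling, and any TE-family structure. Passing the recovery benchmarks
therefore demonstrates that the statistics behave as designed under
idealized counts — not that real methylomes at these settings would give
the same sensitivity.

# Benchmark problem sizes

The test suite runs the pipeline at deliberately compact sizes chosen to
exercise every code path while keeping a full run in tens of seconds:
null false-positive control uses 20 replicate null methylomes of about
50,000 sites; DMP power uses delta 0.6 at coverage 30; DMR recovery uses
6 samples in 2 groups at delta 0.5; discrimination uses the default
3x3-sample three-group design with 50 repeated cross-validations. The
acceptance script (`scripts/acceptance.R`) recomputes the same
quantities from scratch at a caller-supplied seed.

# Known limitations

* The DMR caller is not a reimplementation of smoothed beta-regression
  methods; real-data DMR counts from such tools will not be reproduced.
* The two-stage non-CG FDR rule is conservative by construction (see
  above); its nominal 0.035 level is an upper bound, not an estimate.
* With a handful of samples, LDA cross-validation accuracy is a coarse
  statistic (nine samples quantize accuracy in steps of 1/9).
* `tilingMethylation` defines "covered" with a per-sample floor of 1
  read by default; analyses that need parity with the DMP filter should
  set `minCoverage = 4`.
* Excluding repetitive or homologous regions is supported only through
  a user-supplied exclusion list applied upstream (filter the input
  tables); no homology search is performed.
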