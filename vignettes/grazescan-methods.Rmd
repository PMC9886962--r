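---
title: "Models and methods behind grazescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grazescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

grazescan implements the computational core of a landscape-genomics study
of outcrossing forage populations (the motivating system is alfalfa,
*Medicago sativa*, sampled from long-term grazing sites across contrasting
soil zones): population structure from SNP dosages, a redundancy-analysis
(RDA) genome scan for genotype-environment associations (GEA), linkage
disequilibrium (LD) decay, and ancestry-aware phenotype statistics. This
vignette records the models, the defaults and why they were chosen, the
numerical decisions, and what the simulation-based validation does and
does not establish.

## Genotype representation

Genotypes are ALT-allele dosages `g in {0, 1, 2}` with `NA` for missing
calls — the diploid coding convention of SNP callers, retained here even
though cultivated alfalfa is autotetraploid; this is a biological
simplification inherited from diploid-coded GBS calls, not a claim about
ploidy. Which allele is "minor" is always recomputed from the data
(`locus_maf()`), never assumed from REF/ALT orientation.

QC follows the usual genome-scan order: loci and individuals over a
missingness ceiling (default 0.5, our choice) are removed, then loci with
MAF < 5% (the conventional threshold for association scans; both strict
inequalities). Missing calls are imputed with the locus mean dosage.
The mean is the variance-minimizing single-value fill for the
centered-dosage statistics downstream (RDA, LD, DAPC, PCA), so nothing
fancier is warranted at this stage; the admixture EM instead uses the
observed-data likelihood and must be given the *unimputed* matrix.

## Admixture model and model-order selection

The STRUCTURE-style admixture model treats each allele copy as drawn from
one of K ancestral pools: with ancestry proportions `Q` (rows on the
simplex) and ancestral frequencies `P`,
`f_il = sum_k Q_ik P_kl` and the observed-data log-likelihood is
`sum_il [ g_il log f_il + (2 - g_il) log(1 - f_il) ]` (binomial constant
omitted; missing cells skipped). Rather than MCMC we maximize this
likelihood by EM with closed-form updates (implemented in compiled code),
multiple seeded restarts, and a monotone log-likelihood trace — the same
estimands `Q` and `P`, but deterministic under a seed and fast enough for
replicate runs at desk scale. The log-likelihood plays the role of
`ln P(K)` in model-order selection.

Model order is chosen with the Evanno second-difference statistic
`delta K(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / SD(L(K))` over
replicate runs, defined only for interior K; K values with zero run SD
are excluded (the statistic is undefined there). Replicate runs are
aligned by permuting ancestry labels against the first run (exhaustive
over K! for K <= 6, greedy assignment above) and averaged into a
consensus Q — the same role CLUMPP plays for STRUCTURE output.
Individuals are classified to an ancestry when membership strictly
exceeds 50%; a membership of exactly 0.5 falls to the alternative class
and is flagged, since "greater than 50%" leaves the boundary open and we
prefer the conservative reading.

EM tolerances: `fit_admixture()` defaults to `tol = 1e-6` on the absolute
log-likelihood gain; the replicate-run driver `admixture_scan()` uses
`tol = 1e-3` and `max_iter = 500` by default because log-likelihood
differences between K values are of order 10^2–10^3 and delta-K is
insensitive to the last decimals. Replicates differ only by their
initialization seed.

## Distance trees and DAPC

Between-population divergence uses Nei's (1972) standard distance on
biallelic frequencies: `Jx = mean(x^2 + (1-x)^2)`, `Jxy = mean(xy +
(1-x)(1-y))`, `I = Jxy / sqrt(Jx Jy)`, `D = -ln I`. `I <= 0` (possible
only with fixed opposite alleles) would be infinite and is capped at a
configurable maximum (default 10) with a flag. Trees are built by
classical UPGMA — merge the closest pair at height d/2, average distances
over original leaf pairs (size-weighted) — with ties broken
deterministically by the lowest (row, column) pair so results are
reproducible; the implementation is cross-checked against average-linkage
`hclust` in the tests. Node support comes from resampling loci with
replacement and counting, for each internal node of the original tree,
the fraction of replicate trees containing the same clade.

DAPC reduces centered dosages by PCA, discovers clusters by K-means
(k-means++ seeding, 10 restarts under the seed) for K = 1..max_k, and
scores each K with `BIC = n ln(WSS/n) + K ln(n)`. Cluster discovery runs
on the PCs holding 90% of variance: with many retained dimensions the
log-WSS drop from splitting unstructured data is small against the
`ln(n)` penalty, so the null case correctly favors K = 1, while genuine
clusters dominate either way. The discriminant step then retains the
smallest leading-PC count whose held-out assignment accuracy (stratified
80/20 splits, 10 replicates) is within rounding of the best — the usual
cross-validated guard against over-fitting the discriminant space.

## The RDA genome scan

Predictors are screened before the regression: while any pair has
|Pearson r| > 0.7 the later-listed member is dropped (regression-based
GEA is unreliable under strong collinearity), then variance inflation
factors are computed and any above 5 are dropped iteratively, largest
first. Site-level predictor values are broadcast to the individuals of
each site (one soil test per site is the sampling design) and
standardized.

The scan itself: `B = (X'X)^{-1} X'Y` on centered dosages `Y`, fitted
values `Y' = XB`, and a PCA of `Y'` (economy SVD via the n x n
cross-product, since loci far outnumber individuals). The number of
retained axes K is a genuine judgement call in practice; we mechanize it
with a broken-stick default and `fixed:K` / `proportion:x` overrides.
Note the broken-stick rule is conservative on strongly admixed data: the
ancestry gradient concentrates on axis 1 and later axes fall under the
stick, so a scan aimed at multi-predictor adaptation should consider
retaining all p constrained axes (`fixed:p`) — the validation experiments
below do exactly that, and the choice is exposed, not hidden.

Each locus's loading vector on the K axes is scored by a squared
Mahalanobis distance from the center of the locus cloud. Location and
scatter are estimated robustly — FAST-MCD with subset fraction h = 0.75,
the standard 97.5% reweighting step, and normal-model consistency
scaling — so that the outliers being hunted do not inflate the metric
they are judged against (settings are ours; the robust estimator family
follows common GEA practice). For a single axis an exact univariate MCD
(minimum-variance contiguous half) replaces the subsampling algorithm.
A singular scatter receives a 1e-8 ridge with a warning.

Under the null, D^2 is approximately chi-squared with K degrees of
freedom after rescaling by the genomic inflation factor
`lambda = median(D^2) / median(chi^2_K)` (for K = 2 the null median is
exactly `2 ln 2`). p-values are the upper tail of `D^2 / lambda`;
q-values control FDR (Storey's pi0 estimated on a 0.05–0.90 lambda grid
with a df = 3 smoothing spline, fixed at 1 below 50 p-values where the
grid is unstable — reducing to Benjamini-Hochberg; plain BH is available
and is the more stable choice at small locus counts). A locus is an
outlier when q < 0.01, the conventional GEA stringency. Outliers are
assigned the predictor of maximum absolute dosage correlation; the
correlation is computed at the individual level (dosage against the
individual's site value) — a population-frequency variant would be
defensible, but the individual-level version uses all n points and is
what the per-locus regression in the scan sees. SNPs are then localized
against gene intervals (1-based inclusive, both boundaries inside;
`"Intergenic region"` otherwise), read from GFF3 or BED (BED's half-open
coordinates are converted at the boundary; one internal convention
eliminates off-by-one errors in gene mapping). Strand is ignored.

## LD decay

LD is the squared Pearson correlation of dosage vectors (composite
genotypic r^2): phase is unavailable in dosage data, and genotypic r^2 is
invariant to allele relabeling `g <-> 2 - g`. Pairs are formed within
chromosomes up to a distance ceiling, skipping pairs with fewer than 10
shared calls or zero variance. Distances are physical bp throughout (no
genetic map is assumed). The decay summary reports both defensible
readings of "distance at which r^2 drops below 0.2": the first bin
midpoint at which the (3-bin running-mean smoothed) curve falls below the
threshold — the headline number — and the mean distance among
sub-threshold pairs. A curve that never crosses yields an infinite
sentinel, not an extrapolation.

## Phenotype statistics

Thermal time uses growing degree days, `max(0, (Tmax + Tmin)/2 - 5)`
summed daily (base 5 degrees C, the forage-phenology convention;
truncation never subtracts); accumulation starts at the series start
since no other anchor is defined. Group comparisons use fixed-effects
one-way ANOVA with Tukey-Kramer pairwise comparisons (studentized range,
harmonic-mean group sizes) and an insert-and-absorb compact letter
display; `SEM = sqrt(MSE / n_h)`. The field experiment this emulates was
a nested RCBD analyzed with a mixed model; we deliberately simplify to
fixed effects on genotype means — the validation surface here is
synthetic recovery, not field F statistics, and the simplification is
stated in the output header of the pipeline report. Trait-ancestry
association is ordinary least squares of the trait on membership
probability, at the individual level by default (population-mean
regression is a coarser alternative the user can feed in directly).

## The synthetic-data generator

The generator exists so every stage can be validated by parameter
recovery. It emulates: two ancestral gene pools at configurable FST
(Balding-Nichols frequencies around a common ancestral frequency); a
per-population admixture gradient (population mean ancestries spaced on
[0.08, 0.92], individual proportions Beta-distributed around them with
concentration `admixture_alpha = 10`); sites grouped into 4 soil zones
whose offsets structure six environmental predictors (soil K, P, S, pH,
summer/winter extreme temperatures at field-plausible means and SDs); a
minority of planted loci whose *site-level* allele frequency is
`plogis(qlogis(p0) + slope * z_site)` in a standardized predictor —
coupling acts on allele frequency, matching what an allele-frequency
correlation scan can detect, not on individual fitness; block-wise LD;
and phenotypes affine in sativa ancestry plus Gaussian noise.

LD is generated structurally, not by coalescent simulation: each
haplotype of each individual draws block boundaries at exponential
spacings (mean `block_len_bp`) and reuses one latent uniform within a
block, so marginal per-locus frequencies are exact while within-block
alleles are strongly correlated and correlation collapses across
boundaries, giving an exponential-like decay with a controllable length
scale. Two individuals' blocks are independent, so there is no shared
haplotype panel. Ancestral and pool frequencies are drawn through an AR1
Gaussian copula along the chromosome with correlation length 2.5x the
block length: without this, neighboring loci have mismatched frequencies
and the comonotone-coupling bound on r^2 makes the realized decay length
about 3x shorter than the nominal block length; with it, the r^2 = 0.2
first crossing lands within a factor of two of `block_len_bp`, i.e. the
generator actually realizes its own parameter.

The default planted-locus slope (1.5 log-odds per SD) is a calibration
choice: observational GEA correlations in real data are weak-to-moderate
(|r| of order 0.1–0.4), and slope 1.5 puts planted-locus dosage
correlations in that range at ~12 sites while leaving them separable
from the neutral background. No real-data effect-size scale exists to
copy, so this is stated as a choice, fixed once.

What the generator does *not* emulate — and therefore what passing
recovery tests do not establish about real data: tetraploid dosage and
double reduction; genotyping error and allele-dropout structure of GBS;
isolation-by-distance or pedigree relatedness within populations;
selection on genotype (coupling is through site frequency only);
environment-ancestry confounding (predictors are independent of the
admixture gradient by construction, so the scan's null calibration here
is easier than in heavily confounded real landscapes — the genomic
inflation factor absorbs median-level confounding but not its tails).

## Numerical and design notes

- All randomized routines take explicit seeds; the pipeline derives one
  sub-seed per stage from the global seed by stable hashing of the stage
  name, so toggling a stage never shifts another stage's randomness, and
  rerunning a config reproduces outputs byte for byte.
- Mixture frequencies in the EM are clamped to [1e-9, 1 - 1e-9]; the
  clamp can in principle break exact EM monotonicity but is never binding
  in practice (tests assert monotonicity to 1e-6 every iteration).
- UPGMA and the predictor screen break ties by first index, making
  results independent of floating-point vagaries in equal cases.
- The validation experiments run at deliberate desk scale (10-15
  populations of ~10 genotypes, 400–5000 loci, 5 LD seeds, 10
  calibration seeds), sizes chosen so the full suite exercises every
  recovery property while remaining convenient to run routinely.

## Known limitations

Diploid coding of a tetraploid crop; fixed-effects simplification of the
phenotype models; plain (unconditioned) RDA — an ancestry-conditioning
covariate hook is a natural extension but off by default since the
target workflow did not use partial RDA; Storey's pi0 is unstable below
~50 loci (BH offered); the admixture EM finds local optima — restarts
mitigate but do not guarantee the global maximum.
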