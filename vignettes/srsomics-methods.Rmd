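---
title: "Methods: sepsis response signatures, eQTL mapping, and outcome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sepsis response signatures, eQTL mapping, and outcome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

srsomics re-implements, as a tested pipeline over a synthetic cohort
generator, an integrated transcriptomic/genetic analysis of the host
response in sepsis: unsupervised discovery of two sepsis response
signature (SRS) patient groups from blood leucocyte expression,
moderated-t differential expression between them, a sparse gene
classifier for group assignment, a directional rotation gene-set test,
cis/trans expression quantitative trait locus (eQTL) mapping with
SRS-specific calling, enrichment of lead eSNPs in epigenetic-mark
intervals, and survival analysis by group. This vignette documents the
models, the tunable parameters, the design decisions taken where the
construction was genuinely open, and what the synthetic cohort does and
does not establish about real data.

## The synthetic cohort generator

The generator is first-class, tested code: every downstream stage is
validated by recovering structure the generator planted, so its
assumptions are the package's assumptions.

**Genome and annotations.** Four autosomes plus an X chromosome, 120 Mb
each, with probes placed uniformly (5% on X) and SNPs placed uniformly
except where a planted eQTL requires a cis (within 1 Mb of the probe
start) or trans (different autosome) position. Real coordinates are used
so BED/VCF conventions (0-based half-open vs 1-based) are exercised, not
abstract distances.

**Groups.** Each sample is assigned SRS1 with fraction 0.41 (the
discovery-cohort split) by a seeded shuffle followed by a deterministic
cut at `ceiling(n * fraction)`, so planted group sizes are exact for
tests; at n = 265 this gives 109 SRS1 samples (41.1%, printed as 41%).

**Expression.** Probe values are baseline (uniform on log2 6–12) plus a
group effect for the 3080 differential-expression (DE) probes, plus
additive genotype effects over planted eQTL pairs, plus a loading on a
cell-proportion covariate, plus Gaussian noise with gene-wise variance
drawn from limma's scaled inverse chi-square prior
`s0sq * d0 / chisq(d0)` with defaults d0 = 4, s0sq = 0.05. Two
deliberate realism choices:

- DE magnitudes are `log2(1.5) + |N(0, 0.8)|`, i.e. above the
  fold-change calling threshold by construction, because the planted
  program emulates the *called* DE set, which the calling rule defines
  by FC > 1.5. With this choice a default cohort yields ~3000 called
  probes out of 26185, close to the study's 3080, with exactly
  `floor(0.734 * 3080) = 2260` effects negative in SRS1.
- Gene variances are capped at `sigma2_cap = 4` (sd 2 on the log2
  scale; ~0.03% of draws truncated). The raw inverse chi-square tail
  occasionally produces a single probe with variance in the hundreds,
  which no normalized array exhibits and which would dominate Euclidean
  distances in clustering. The cap is a property of realistic data, not
  a tuning knob: without it, isolated replicates fail group recovery
  through one absurd probe.

**Confounding.** The polymorphonuclear cell proportion is
group-dependent (mean contrast scaled by `confound_strength`, default
0.5 of the observed 0.89 vs 0.82 contrast) and feeds back into
expression through per-probe loadings (sd 0.1), because the
covariate-adjusted analyses must have something real to adjust for.

**eQTL plan.** 200 cis and 20 trans pairs by default, with betas uniform
on ±[0.5, 1.5] log2 units per allele copy and Hardy-Weinberg dosages at
MAF uniform on [0.1, 0.5]. Twenty cis pairs are restricted to one group
(beta = 0 in the other), alternating SRS1-only/SRS2-only. A fraction
(36.3%) of cis pairs is flagged condition-only: silenced in the
reference-context expression simulator and placed distally (300 kb–1 Mb
from the probe start, vs under 300 kb for shared pairs), emulating the
distal-enhancer placement of context-specific regulatory variants.

**Survival.** Exponential event times with the SRS2 daily hazard solved
from `1 - exp(-14 * lambda) = 0.10` (10% 14-day mortality) and the SRS1
hazard multiplied by 2.4, reproducing the 22% vs 10% contrast;
administrative censoring at 28 days. Exponential hazards are a
simplification — real sepsis hazards decline after the first week — but
only the early-mortality window is analysed.

**Epigenetic marks.** Four mark tracks (H3K27ac, H3K4me1, H3K4me3,
DNase I) of fixed-width intervals covering 0.8% of the genome at
random, plus dedicated intervals so true cis eSNPs are covered with
probability `enrichment_factor` (default 4) times the background rate,
plus non-covering intervals clustered near eSNPs (exponential gaps,
mean twice the interval width, placed with probability
`(factor - 1)/10`). The clustered intervals shift the
distance-to-nearest-mark distribution — the property the Mann-Whitney
test consumes — without touching the calibrated overlap rate that the
Fisher test consumes.

**Randomness.** All stages draw from one master seed through named
streams (`stream_seed(seed, stage)`), so toggling one stage never
perturbs another and identical configs are bit-identical.

## SRS discovery

The most variable 10% of probes (sample variance, denominator n − 1,
ties broken lexicographically) are clustered by Ward's minimum-variance
agglomeration under the Euclidean metric (samples as objects), the
dendrogram cut at each candidate k, and membership consolidated by
Lloyd's k-means initialized at the hierarchical centroids — no random
restarts, so discovery is fully deterministic. An empty cluster during
iteration is re-seeded at the point farthest from its assigned
centroid.

k is chosen as the smallest value in 2..4 whose relative
within-group-sum-of-squares (WSS) reduction to k + 1 falls below a
threshold. The threshold default is 2%: in high-dimensional data an
extra cluster always buys a small WSS reduction even without structure
(empirically 1–1.5% at cohort scale when real group structure is
present, under 0.5% for pure noise), while splitting a true group buys
5% or more, so 2% sits between the floors and the signal. The
threshold is configurable and scale-sensitive — at much smaller n the
null floor rises — which is why reduced-scale test fixtures pin
`k_range` instead.

SRS1 is identified (the labels being otherwise arbitrary) as the group
in which the majority of DE probes from a quick unmoderated Welch pass
(p < 0.05, |difference| > log2 1.5) are downregulated — the
immunosuppressed, majority-downregulated phenotype. An exact tie or an
empty vote falls back to naming the smaller group SRS1 with a warning.

## Differential expression

Per-probe ordinary least squares against an intercept + group (+
optional covariates) design via limma's `lmFit`; the group coefficient
is the log2 fold change. Variances are moderated by the empirical-Bayes
hierarchical model: the prior (d0, s0sq) is limma's closed-form moment
estimator (trigamma inversion on log variances), the posterior variance
is `(d0*s0sq + df*s2)/(d0 + df)`, and p-values use d0 + df degrees of
freedom. Fixed-prior branches (`d0 = 0` giving the ordinary t,
`d0 = Inf` giving a pooled-variance statistic) are exposed for testing
the limiting behaviour. Probes with zero residual df are excluded with
a logged count; constant covariates are dropped (they carry no
information beyond the intercept, and the adjusted analysis must then
equal the unadjusted one exactly). Calling is `|log2FC| > log2(1.5)`
and BH FDR < 0.05; the fold-change threshold is interpreted on the
anti-log scale in both directions since both directions are reported.

## Sparse classifier

L1-penalized logistic regression (glmnet) over a decreasing penalty
path, penalty chosen by cross-validated deviance with the 1-SE rule;
features are standardized internally and the scaling stored so
reapplication is exact. An optional support cap walks the path to the
best-deviance penalty whose support is within the cap (used for the
seven-gene demonstration; the cardinality is not forced by default).
Leave-one-out cross-validation repeats the entire selection inside
every fold — the only leakage-free reading — so the printed in-sample
misclassification of a fixed panel is not comparable and is not
targeted. Predicted class uses a fixed 0.5 probability cut. With
selection inside folds, permuted-label LOOCV error sits at (or slightly
above, through selection noise) the minority-class prior; only a drop
clearly below the prior would indicate leakage.

## Rotation gene-set test

A directional signature (genes with up/down labels, derived from
reference DE tables by FDR < 0.05 and FC > 1.5, intersected across
references with concordant sign and then with the measured universe) is
tested against the group contrast by rotation. Each gene's data are
projected onto the contrast direction plus the residual space of the
design; the gene statistic is the moderated t (prior estimated from all
probes), sign-flipped for "down" genes so concordance is positive; the
set statistic is the mean. The null rotates a shared uniform unit
vector in the combined contrast + residual space, preserving gene-gene
correlation, and the right-tail p is `(1 + #{rotated >= observed}) /
(B + 1)` — floored at 1/(B+1), never zero. The contrast direction from
the QR factorization is sign-pinned to the design column so gene
t-statistics match the regression convention (the raw factorization
sign is data-dependent). `n_rotations = 0` returns the statistic alone,
which equals the mean signed moderated t exactly. Chi-square set
enrichment uses the Pearson 1-df statistic without continuity
correction (configurable) and a Haldane-corrected odds ratio.

## eQTL mapping

Covariates are the first 30 principal components of the probe-centered
expression matrix for the full cohort and 25 within each SRS group
(components sign-pinned by their largest-magnitude loading), absorbing
group structure and broad confounding. Pairs are classified cis (same
chromosome, |SNP − probe start| < 1 Mb), trans (different chromosome or
beyond 2.5 Mb, autosomes only by default), or excluded (the 1–2.5 Mb
gap zone). The engine residualizes expression and dosages against the
covariates once and correlates residuals — algebraically the
Frisch-Waugh reduction of the per-pair multiple regression, verified
against a per-pair `lm()` oracle to 1e-8 — with t on n − n_cov − 2 df,
r² the squared partial correlation, and BH FDR within the cis and trans
streams separately (the Matrix-eQTL convention; the multiplicity
universe is not stated by the study). Monomorphic SNPs are skipped and
counted. Lead SNP per probe is minimum p, ties broken by larger |beta|
then snp_id. SRS-specific calling requires FDR < 0.01 in one group and
> 0.05 in the other on the intersected pair universe; both-below-0.05
is shared. Context comparison calls a gene condition-specific when its
lead is significant in the condition but not the reference mapping, and
compares |lead − TSS| between condition-specific and shared genes by a
two-sided Mann-Whitney test.

## Epigenetic-mark enrichment

Interval logic is GenomicRanges; marks are merged per track before
analysis so proportions are well defined. A SNP at 1-based p overlaps
[s, e) iff s ≤ p − 1 < e. The background is all SNPs within 1 Mb of any
probe start. Overlap proportions are compared by two-sided Fisher's
exact test and distances to the nearest mark (0 when overlapping; SNPs
on mark-free chromosomes excluded with a log) by Mann-Whitney, exact
only when both arms are ≤ 20.

## Survival

Kaplan-Meier curves with Greenwood variance and log-log CIs, the
standard log-rank test (which equals the Cox score statistic for a
binary covariate without ties — checked numerically), and Cox partial
likelihood with Efron tie handling (day-granularity data tie heavily;
Efron is better behaved than Breslow). The hazard-ratio CI is Wald on
the log scale; the study does not state its method. Fixed-horizon
mortality uses raw proportions when follow-up is administratively
complete to the horizon (the generator guarantees this) and otherwise
falls back to the KM estimate with a warning. Group comparison tables
use Welch t for continuous covariates and chi-square with a Fisher
fallback (any expected count < 5) for categorical ones; a Welch test
from summary statistics is provided for published-table checks. Cox
models are unadjusted by default, matching the printed comparisons.

## Problem sizes and what the tests show

The test suite exercises discovery at the full 265 x 26185 scale (50
seeded replicates; adjusted Rand index vs planted truth ≥ 0.9 in at
least 95%), eQTL recovery at the study's 240-sample setting with 200
planted cis pairs among ~20 000 tested, null calibration of the DE
calling (100 replicates) and the rotation test (200 replicates at 999
rotations), Cox hazard-ratio coverage on 100 cohorts of 1000 with full
follow-up, and classifier support recovery at 265 x 2007 with 3-SD
planted effects. Smaller fixtures (n of tens to low hundreds) are used
where only algebraic properties are at stake. The permuted-label LOOCV
check runs at n = 80 with 300 features, a size at which inside-fold
selection is exercised meaningfully.

What passing does *not* show about real data: the generator plants
independent SNPs (no linkage disequilibrium), Gaussian noise on the
log2 scale, exponential hazards, no batch effects, no coupling between
the DE program and the eQTL targets (so the DE x eQTL enrichment
computed by the workflow is null by construction in the synthetic
cohort), and group structure far cleaner than clinical cohorts exhibit.
Recovery rates here are upper bounds on what the same pipeline achieves
on real arrays.

## Reproducibility

Every stochastic step takes an explicit seed; the pipeline orchestrator
(`run_pipeline()`) writes per-stage manifests of file hashes, and a
rerun with an identical config is bit-identical. The numbered scripts
under `analysis/` run the same package functions over a written-out
cohort, printing what each stage found.
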