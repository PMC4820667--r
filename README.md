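# srsomics

Integrated transcriptomic and genetic analysis of the individual host
response in sepsis, built as a reusable, tested R package over a
synthetic cohort generator.

Patients admitted to intensive care with sepsis differ widely in their
immune response. Clustering blood leucocyte expression separates them
into two sepsis response signature groups: SRS1, an immunosuppressed
phenotype (endotoxin tolerance, T-cell exhaustion, HLA class II
downregulation) with higher early mortality, and SRS2. srsomics
implements the full analysis chain that discovers these groups and
relates them to genetics and outcome:

- **SRS discovery** — Ward hierarchical clustering (Euclidean) of the
  top 10% most variable probes, k chosen by the within-group
  sum-of-squares criterion, k-means consolidation, and orientation of
  the SRS1 label onto the majority-downregulated group.
- **Differential expression** — per-probe linear models with
  empirical-Bayes variance moderation: posterior variance
  s̃² = (d₀s₀² + d·s²)/(d₀ + d), moderated t = β̂/(s̃·u), BH FDR, and
  calling at FC > 1.5, FDR < 0.05.
- **Sparse classifier** — L1-penalized logistic regression with the
  1-SE rule and leave-one-out cross-validation with selection repeated
  inside every fold.
- **Rotation gene-set test** — directional signatures tested against
  the group contrast by random rotation of the contrast + residual
  space; chi-square set enrichment.
- **eQTL mapping** — additive linear models of expression on allele
  dosage, adjusted for 30 expression principal components (25 within
  SRS groups); cis = same chromosome within 1 Mb of the probe start,
  trans = different chromosome or beyond 2.5 Mb (autosomes only);
  per-stream BH FDR; lead SNPs; SRS-specific eQTL called at
  FDR < 0.01 in one group and > 0.05 in the other; context comparison
  against a reference mapping with a Mann-Whitney distance test.
- **Epigenetic overlap** — Fisher and Mann-Whitney enrichment of lead
  eSNPs in histone-mark/DNase BED intervals against all SNPs within
  1 Mb of a probe.
- **Survival** — Kaplan-Meier, log-rank, Cox proportional hazards
  (Efron ties), fixed-horizon mortality, covariate comparison tables.

Patient-level data from the original cohorts are not redistributable,
so the package ships a seeded generator (`sim_config()`,
`simulate_cohort()`) that emulates the study's statistical structure —
a 41/59 group split, a 3080-probe DE program with 73.4% downregulated
in SRS1, scaled-inverse-chi-square gene variances, planted cis/trans
and group-restricted eQTL, 4-fold mark enrichment at true eSNPs, and
hazard ratio 2.4 — together with the ground truth needed to score
recovery.

## Worked example

The numbered scripts under `analysis/` run the whole workflow over one
written-out cohort. `analysis/01_simulate.R` generates the cohort;
discovery then reports:

```
top-variable probes clustered: 2619
WSS by k: 2=225103  3=221742  4=219040  5=217617
chosen k: 2; group sizes: SRS1=109, SRS2=156
adjusted Rand index vs planted groups: 1.000
```

2619 probes is the top 10% of 26185; the WSS criterion stops at k = 2
(further splits reduce WSS by under 2%); the 109/156 split recovers the
planted 41% SRS1 fraction exactly (ARI 1.0). Differential expression:

```
moderation prior: d0 = 4.39, s0sq = 0.0600
3026 probes called (FC > 1.5, FDR < 0.05); 73.5% down in SRS1
```

The estimated prior is close to the generating values (d₀ = 4,
s₀² = 0.05 plus covariate-loading variance); the called count and
down-fraction match the planted program (3080 probes, 73.4% down).
eQTL mapping and survival close the loop:

```
significant at FDR < 0.05: 209 cis pairs, 22 trans pairs
planted-pair sensitivity at FDR < 0.05: 1.000
SRS-specific cis-eQTL: 12 SRS1-only, 13 SRS2-only, 180 shared
context-specific genes: 88, shared: 121; lead-SNP distance Mann-Whitney p = 3.2e-29
Cox: HR 1.91 (95% CI 1.25-2.92), Wald p = 0.00281; log-rank p = 0.00236
```

The 20 planted group-restricted pairs surface among the 25 SRS-specific
calls; condition-only eQTL sit measurably more distal from probe starts
than shared ones; and the Cox confidence interval covers the planted
hazard ratio of 2.4 (a single cohort of 265 estimates log HR with
standard error near 0.3; the acceptance script pools ten replicates,
giving 2.5 at seed 1).

A single in-memory run of the same chain:

```r
library(srsomics)
co   <- simulate_cohort(sim_config(seed = 1))
disc <- discover_srs(co$expr$values)
de   <- de_table(co$expr$values, disc$labels)
cox  <- cox_fit(co$metadata$time, co$metadata$event,
                data.frame(srs1 = as.integer(disc$labels == "SRS1")))
```

## Layout

- `R/` — the implementation (generator, discovery, DE, classifier,
  rotation, eQTL, epigenetics, survival, pipeline orchestration, IO).
- `analysis/01..08_*.R` — narrative drivers writing tables under
  `results/`.
- `tests/testthat/` — unit, property and end-to-end recovery tests.
- `vignettes/srsomics-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, and what the synthetic cohort does
  and does not establish.
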