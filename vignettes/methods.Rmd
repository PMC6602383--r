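---
title: "Models and methods behind methcortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methcortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcortex)
```

methcortex analyses Illumina 450K-style DNA methylation data from
multi-region brain cohorts with three diagnostic groups (control,
idiopathic ASD, dup15q). This vignette explains each model, the tunable
parameters and their defaults, the numerical choices, what the synthetic
generator does and does not emulate, and the package's known limitations.

## Quality control and normalization

Probes are removed when (i) their detection p-value exceeds 0.05 in at
least `max(1, ceiling(0.01 * n_samples))` samples, (ii) they are SNP
fingerprint probes, catalogued cross-reactive probes, or carry a common
SNP within 10 bp of the single-base extension position, or (iii) they map
to sex chromosomes (sex-chromosome probes are retained only for the sex
check). The failure-count floor of one sample means the 1% rule behaves
sensibly below 100 samples — a probe failing in any single sample is
removed — while a probe with no failures is never removed even at
`frac = 0`.

The sex check runs classical multidimensional scaling on Euclidean
distances over sex-chromosome probes and splits the first coordinate with
an exact one-dimensional 2-means; clusters are labelled by majority
reported sex. Donor identity across regions is verified by Pearson
correlation of the 65 SNP fingerprint probes (same-donor pairs are
expected above r = 0.9).

Normalization quantile-normalizes the methylated and unmethylated
intensity channels separately *within each probe design-type stratum*
(types I and II have different dynamic ranges), mapping every sample onto
the stratum's mean sorted vector, and recomputes
`beta = M / (M + U + 100)`. The 100-unit offset is the standard
beta-denominator stabilizer. This is a stratified quantile scheme without
a background-drift spline; it preserves within-sample rank order inside
each stratum, which is the property the downstream linear models rely on.

Batch (brain bank) adjustment is a parametric empirical-Bayes
location/scale model: per-probe standardization on the residuals of
protected covariates (diagnosis, age, sex by default), batch means shrunk
through a normal prior and batch variances through an inverse-gamma prior
with method-of-moments hyperparameters, iterated to convergence, then
rescaling, restoring protected effects and clipping to [0, 1]. With
shrinkage disabled the raw per-batch estimates are used, which equalizes
per-batch means exactly — useful for testing. The protected-covariate set
is a choice this package makes explicitly (the natural default for a
case/control ageing cohort); it is configurable.

## Cell composition and the epigenetic clock

Bulk cortical tissue is modelled as a two-component neuron/glia mixture.
For marker probes with reference profiles $n_i$ (neuron) and $g_i$
(glia), the neuronal proportion is the closed-form least-squares
projection

$$\hat p = \frac{\sum_i (x_i - g_i)(n_i - g_i)}{\sum_i (n_i - g_i)^2},$$

clipped to [0, 1]. This is exact (machine precision against a grid
search) in the noise-free case and requires at least 10 markers.
Cerebellum is excluded: its dominant neuronal population is not captured
by NeuN-based reference panels, so CB samples get no estimate and the
covariate is dropped from CB models automatically.

DNA methylation age evaluates a linear predictor
`raw = intercept + sum(coef * beta)` over clock CpGs and inverts the
standard log-linear age transform with adult-age knot 20 years:
`age = 21 * exp(raw) - 1` for `raw < 0`, else `age = 20 + 21 * raw`. The
transform is continuous and strictly increasing; up to 20% of clock CpGs
may be mean-imputed (more is an error). The package is clock-agnostic —
coefficients come from a CSV — because published clocks are external
data. Age acceleration is the residual of DNAm age regressed on
chronological age within region, compared between groups by a two-sided
t-test; when the residuals are identically zero the p-value is defined
as 1.

## Differential methylation

Within a region, each probe is fit by OLS:
`beta ~ age + sex + bank + neuronal_proportion + diagnosis`, diagnosis
coded 0/1, with listwise deletion of missing values. Effects are reported
on the beta scale (delta-beta) because methylation differences are most
interpretable as percentage points; the M-value scale is a deliberate
non-choice, documented here. Constant probes get effect 0 and p = 1
rather than being dropped, keeping the output aligned with the input
probe set. Pooled multi-region OLS adds a region fixed effect. Singular
designs (e.g. bank confounded with diagnosis) produce flagged rows with
missing p.

The cross-cortex model adds a donor random intercept for the repeated
PFC/TC measurements:

$$y_{ds} = x_{ds}^\top\beta + u_d + \varepsilon_{ds}, \quad
  u_d \sim N(0, \sigma_u^2),\ \varepsilon \sim N(0, \sigma_e^2).$$

It is fit by restricted maximum likelihood profiled down to the variance
ratio $\lambda = \sigma_u^2/\sigma_e^2$: because the donor design is a
block indicator, $V^{-1} = (I + \lambda ZZ^\top)^{-1}$ has a closed
per-donor form, so the whole profile criterion needs only donor-level
sufficient statistics. A 50-point log-spaced grid (vectorized across all
probes) brackets the optimum and a per-probe 1-D optimization refines it,
always re-checking the $\lambda = 0$ boundary; the returned solution
beats any point of a step-1e-3 grid in tests. At $\lambda = 0$ the
estimates coincide with pooled OLS exactly. Inference on the diagnosis
effect uses a Wald z statistic — a documented approximation (no
Satterthwaite degrees of freedom) that is slightly anticonservative at
moderate n; the exact-t OLS path is the reference for null-calibration
checks. The implementation matches `lme4::lmer` REML fits to ~6 digits on
balanced data while running about three orders of magnitude faster per
probe, which is what makes 20,000-probe mixed-model scans routine.

Two significance tiers are used: discovery `p < 5e-05` and
experiment-wide Bonferroni `p < 0.05 / n_probes` (for a 417,460-probe
analysis set this is 1.198e-7). Both comparisons are strict.

## DMR calling

Spatially correlated regions are found by a Stouffer–Liptak procedure:

1. p-values become one-sided z-scores, `z = qnorm(1 - p)`;
2. the z-score autocorrelation is estimated in 50 bp distance bins up to
   300 bp from the same p-value set being corrected (correlation at lag 0
   is 1; sparse bins inherit the nearest smaller-lag estimate);
3. each probe's p is replaced by the Stouffer–Liptak combination of its
   ≤ 300 bp neighbourhood, $T = \sum z_i / \sqrt{\mathbf 1^\top \Sigma
   \mathbf 1}$, with $\Sigma$ from the ACF;
4. regions grow from seeds (`adjusted p < 1e-3`) joining successive seeds
   with gaps ≤ 300 bp (the boundary is inclusive — a gap of exactly
   300 bp joins); regions need ≥ 2 probes;
5. each region gets a Stouffer–Liptak p over its raw p-values, then a
   Sidak correction `1 - (1 - p)^(territory / length)` evaluated in log
   space (`-expm1(k * log1p(-p))`) so p-values down to 1e-300 remain
   accurate. Territory is the span of tested probes ± 300 bp per
   chromosome; region length has a floor of one median inter-probe
   spacing to avoid zero-length single-position regions.

Non-positive-definite correlation matrices are repaired by flooring
eigenvalues at 1e-8 (applied only when needed, so the identity case stays
exact to 1e-12).

## CNV detection

Total intensities (M + U) of the test sample and a control panel are
quantile-normalized together; per-probe ratios
`log2(total_sample / median(total_controls))` are median-centred per
sample (so only relative structure remains — a genome-wide doubling is
deliberately invisible). Recursive binary segmentation splits each
chromosome at the point maximizing the residual-sum-of-squares reduction,
accepting a split when the reduction exceeds `penalty * sigma^2`
(default penalty 25, sigma from the MAD of first differences) with at
least 10 probes per side. A segment is a gain when its mean ratio exceeds
0.3 (a 3-copy gain sits near log2(1.5) ≈ 0.585) over ≥ 20 probes, and a
sample is a dup15q carrier when a gain overlaps the configured 15q11–13
interval. The segmentation is deterministic and shift-invariant; the
thresholds were chosen once for 3-copy gains and are configurable.

## Co-methylation networks

Probes first pass a variability filter — the q10–q90 spread (the middle
80% of samples) must strictly exceed 5% — and are residualized: a joint
OLS on the full covariate set is fit per probe and only the fitted
contributions of the removal set (neuronal proportion and age by
default) are subtracted, so jointly-estimated diagnosis effects survive.

The network is signed: `a = ((1 + bicor) / 2)^7` with biweight
midcorrelation (Tukey weights `(1 - u^2)^2`, `u = (x - median)/(9 MAD)`,
Pearson fallback at zero MAD). Topological overlap is
`(sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`. Modules come
from average-linkage clustering on `1 - TOM` with a static cut at 99% of
the maximum merge height; components under `minModuleSize` (default 100)
are unassigned, and modules merge while any eigengene pair correlates
above `1 - mergeCutHeight` (default 0.9). This static-cut variant
replaces the dynamic-hybrid deep-split tree cut on purpose: the
deep-split internals are not reproducible from their published
description, so the package uses a transparent cut whose single parameter
(`cut_frac = 0.99`) is documented prominently. Consequences: module
counts are not comparable to dynamic-cut analyses (a 61-module result on
real data is not expected to replicate here), though planted block
structure is recovered exactly (adjusted Rand index 1.0 in the test
conditions). Module labels are stable integers ordered by size, not
colour names. Blocks above `maxBlockSize` (default 15,000) are split by
k-means on the leading principal components, with a cross-block eigengene
merge afterwards; test problems stay below the block size so results are
block-free.

Module eigengenes are the leading left singular vector of the
standardized module matrix, unit variance, sign-anchored to correlate
positively with module mean methylation. Eigengene–diagnosis association
reuses the donor-random-intercept REML engine with BH correction across
modules within contrast.

## Pathway enrichment

Genes are attached to probes from the manifest annotation (gene-body
overlap or ≤ 1500 bp upstream of the TSS; intergenic probes drop out,
multi-gene probes contribute every gene). The universe is every gene with
at least one tested probe and at least one pathway. Membership of the
test list is then tested per pathway by logistic regression,

`in_pathway ~ in_test_list + log(n_probes + 1)`,

whose probe-count covariate removes the bias that genes with more probes
are more likely to enter any probe-derived gene list — an uncorrected
Fisher test inflates its type-I error several-fold under a
probe-count-confounded null, while this test stays at nominal level (both
measured by the acceptance script). The log scale tames the skew of
probe counts; a raw-count mode exists. The Wald test is two-sided (the
direction is read off the coefficient sign), and perfect separation falls
back to Firth-penalized IRLS. Pathways outside 10–2000 universe genes are
skipped with a reason. Significant pathways (p < 0.05) are grouped by
iteratively taking the most significant remaining pathway as head and
absorbing any pathway whose test-list coefficient loses significance
(p > 0.05 — the same level, an explicit choice since "no longer
predicts" needs a threshold) once head membership enters the model. Ties
in p are broken by pathway ID, making the output deterministic.

## The synthetic cohort generator

`synth_design()` / `generate_cohort()` emulate the statistical structure
every stage assumes: a probe grid over 22 autosomes plus chrX (positions
strictly increasing, exponential-plus-minimum gaps around a 300 bp mean
so the DMR window is populated), gene annotations in runs (skewed
probes-per-gene counts, which the enrichment bias correction needs), 65
SNP fingerprint probes with donor-level genotypes, a bimodal baseline
beta profile, and additive effects: spiked DMPs/DMRs, planted latent
factor modules, per-bank mean shifts, a neuron/glia mixture at marker
probes, clock CpGs encoding (possibly group-shifted) age, a donor random
intercept shared by cortical samples, and Gaussian noise, clipped to
[0, 1]. Intensities satisfy `M/(M+U+100) = beta` with total intensity
scaled by CN/2 (log-normal noise, sd 0.1) inside the dup15q locus, whose
focal imprinted domain carries hyper- and hypo-methylated sub-blocks.
Every planted effect is returned in truth tables, which is what all
recovery tests consume.

Default cohort structure mirrors a realistic three-bank, three-region
brain study: 33/36/7 control/iASD/dup15q donors, each contributing PFC,
TC and CB samples, ages 2–68. The default probe count is 20,000 — a
desk-scale grid that keeps every stage in seconds while preserving the
geometry of a 450K array; the acceptance analyses state their sizes
explicitly. Within-group noise SD defaults to 0.03 with a 0.01 donor
intercept; published cohorts do not report these directly, so they were
chosen once for realistic per-probe power and kept fixed.

What the generator does *not* emulate — and hence what green tests do not
certify about real data: beta noise is Gaussian-with-clipping rather than
beta-distributed, so boundary-probe heteroscedasticity is
underrepresented; probe-type chemistry differences beyond the
normalization strata, dye bias and background fluorescence are absent;
linkage structure among SNP probes is ignored; and batch effects are pure
mean shifts, not the location-scale-correlation mixtures real scanners
produce.

## Numerical choices and degenerate inputs

p-values are clamped to [1e-300, 1 − 1e-16] before `qnorm`; correlation
matrices are eigenvalue-floored only when non-PD; Sidak uses
`log1p`/`expm1`; constant probes get p = 1; single-batch input passes
through batch adjustment unchanged; a batch with fewer than two samples,
fewer than two sex-chromosome probes, or an empty contrast group are
errors naming the offender. All randomness flows from a single seed, and
identical configuration plus seed reproduces every CSV output
bit-identically.

## Known limitations

* Wald-z mixed-model p-values are mildly anticonservative at small n —
  use the per-region OLS t-tests when exact null calibration matters.
* The static tree cut is not the dynamic-hybrid cut; module granularity
  differs from WGCNA-based analyses by construction.
* Two-component deconvolution only; no ≥ 3 cell-type support.
* CNV calling targets multi-megabase duplications; mosaicism and
  allele-specific copy number are out of scope.
* The GO grouping threshold (0.05) and the TSS window (1500 bp) are
  conventions, not estimated quantities.
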