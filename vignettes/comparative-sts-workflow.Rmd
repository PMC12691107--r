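---
title: "Comparing canine soft tissue sarcoma expression to human sarcoma subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing canine soft tissue sarcoma expression to human sarcoma subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninests)
```

## The scientific problem

Canine soft tissue sarcomas (STS) are spontaneous, immunocompetent tumors
proposed as a translational model for human STS. The molecular half of
that argument asks which human subtype — undifferentiated pleomorphic
sarcoma (UPS), liposarcoma, leiomyosarcoma or synovial sarcoma — canine
STS most resembles on a shared immune-oncology gene panel. Because the two
species' panels differ in chemistry and scale, the comparison must be made
on quantities that are invariant to per-sample and per-platform scaling.
`caninests` does this with within-sample ranks and Spearman correlation,
and wraps the normalization, screening, survival and
immunohistochemistry (IHC) statistics that such a study needs around it.

## Normalization

**Pooled-distribution quantile normalization.** Each sample's value at
within-sample rank $r$ (average convention for ties) is replaced by the
quantile of the *pooled* distribution of all $G \times S$ values at
relative rank $(r-1)/(G-1)$, linearly interpolated between pooled order
statistics. Tie-free inputs therefore end with bit-identical per-sample
value multisets; tied inputs agree up to the tie pattern. This pooled
variant differs from the column-mean-of-sorted scheme common in microarray
work: with a single sample it is exactly the identity, and it never
averages across samples. Rank order within a sample is preserved by
construction. A constant sample (all values tied) maps every value to the
pooled median — the defined limit of the average-rank convention — rather
than erroring.

**Log transforms.** The single-species descriptive arm uses
$\log_{10}(x + 1)$; the cross-species arm uses $\log_2(x + 1)$. A matrix
records its log base and refuses a second transform. The offset defaults
to 1 count so zero counts map to zero.

**geNorm reference genes.** For candidates $j, k$ the pairwise variation
is $A_{jk} = \mathrm{SD}_s\,[\log_2(x_{js}/x_{ks})]$ and the stability
value $M_j = \mathrm{mean}_{k \ne j} A_{jk}$; the gene with the highest
$M$ is excluded and $M$ recomputed until two genes remain (ties broken by
input position, and the ranking is invariant to candidate order). How many
references suffice is decided by the pairwise variation
$V_{k,k+1} = \mathrm{SD}_s[\log_2(\mathrm{NF}_k/\mathrm{NF}_{k+1})]$
between normalization factors (geometric means) of the top-$k$ and
top-$(k+1)$ genes, with the canonical cutoff $V < 0.15$ (configurable).
Normalization divides each sample by the geometric mean of the selected
genes and rescales the factors to geometric mean 1, so the output is
scale-balanced across samples; a zero housekeeping count is an error
naming the sample, since the geometric mean would be degenerate.

Note that per-sample rescaling does not change within-sample ranks, so the
cross-species rank profiles are identical whether they are built from
geNorm-normalized or raw log2 counts; geNorm matters for the magnitude
scale (heatmaps, median splits), not for the Spearman statistics.

## Gene screening and clustering

Each gene is tested by a classical one-way fixed-effects ANOVA across a
clinical grouping factor (default: histologic grade 1/2/3 — the principal
stratifier recorded for every tumor; the factor is an argument). Selection
is the raw rule $p < 0.05$, strict at the boundary; Benjamini–Hochberg is
available behind a flag but off by default, keeping the screen a
sensitivity filter rather than an inferential claim. Degenerate genes are
resolved explicitly: a gene constant everywhere has $F = 0, p = 1$; zero
within-group variance with a real group difference yields the smallest
representable p. Heatmap ordering uses agglomerative clustering with
Euclidean distance and average linkage (both tagged on the result); the
distance and linkage were an open choice and are declared, not inferred.

## Cross-species similarity inference

The common gene set is the uppercase symbol intersection (1:1 matches
only; no ortholog inference). Each sample becomes its within-sample rank
vector. Three design choices were genuinely open and are resolved as
follows:

- **Canine aggregation.** The cohort is summarized by the per-gene
  *median* rank profile: deterministic, robust to outlying tumors, and
  the natural center for rank data. (Averaging per-sample correlations
  over all canine × human pairs gives the same ordering in our
  simulations but couples the statistic to canine cohort size.)
- **Null model.** The permutation test permutes the *target/rest labels
  over human samples*, preserving group sizes. This tests exactly the
  reported contrast — "is the target subtype closer than the rest?" —
  under exchangeability of human samples, without touching the canine
  reference.
- **Sidedness.** One-sided upper tail, because the scientific claim is
  directional (closer to the target); all clinical tests are two-sided.

The p-value uses the add-one correction $p = (1 + \#\{\Delta^* \ge
\Delta_{\mathrm{obs}}\})/(B+1)$, so $p \in (0, 1]$ and the test is exactly
valid at any $B$. Defaults are $B = 10{,}000$ permutations and $2{,}000$
bootstrap replicates — stable to roughly $10^{-3}$ at desk scale — and
every resampling routine takes an explicit seed.

"Closest-subtype confidence" is ambiguous between two readings, so both
are reported from the same stratified bootstrap (canine resampled with
replacement, human resampled within subtype): the frequency with which
each subtype is the argmax of the per-subtype mean correlations, and the
2.5–97.5 percentile interval of the winning subtype's mean correlation
across replicates. With $B = 1$ the interval degenerates to the single
replicate's value.

## Survival and IHC statistics

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package; `km_fit()` defines the median as the smallest time
with $S(t) \le 0.5$ (NA when never attained). MYC dichotomization uses a
strict above-median rule (values at the median are "low"; the cut
quantile is configurable) because no published cutoff exists for this
panel. The Wilcoxon rank-sum test is exact when the pooled size is at
most 12 and tie-free, otherwise the normal approximation with tie and
continuity corrections; identical samples under ties therefore give a p
near, not exactly, 1.

IHC grading averages five positive-cell counts from distinct 50× fields:
grade 0 for a mean below 1 (a tumor without infiltration — an explicit
category because negative tumors occur), grade 1 for $[1, 5)$, grade 2
for $[5, 10]$, grade 3 above 10. The published range endpoints overlap at
5 and 10; the half-open-at-5, closed-at-10 reading is the only one
consistent with grade 3 requiring *more than* 10 cells. The rule is
monotone in every field and invariant to field order, and both properties
are verified exhaustively on small count grids.

## The synthetic cohort generator

No patient-level data accompany this design, so the simulator *is* the
study condition set, and its defaults are fixed once:

| parameter | default | rationale |
|---|---|---|
| cohorts | 30 canine + 60 human | desk-scale two-cohort comparison |
| subtype mix | UPS 0.25, lipo 0.33, leio 0.23, synovial 0.19 | composition of the human comparison cohort |
| panel | 600 genes, 10 housekeeping | typical immune-oncology code-set scale; the real panel size is unpublished |
| signatures | 25 genes/subtype, effect 2 on log2, random sign | clearly detectable but not separable by eye |
| counts | NB, var $\mu + \phi\mu^2$; $\phi$ = 0.1 tumor / 0.01 housekeeping | standard overdispersed probe-count model; housekeeping genes are low-dispersion and carry zero subtype effect |
| baselines | $\log_2 \mu \sim N(5, 2)$ truncated at 0 | spans the nCounter dynamic range |
| canine UPS share | 0.75 | strong but imperfect sharing of the UPS signature (gene-level: same genes, same sign, scaled effect) |
| hazards | castrated male 2.0, FOXP3+ 2.0, MYC-high 2.5 | moderate clinical effects of the kind the survival figures depict |
| survival | Weibull shape 1.2, baseline medians 500–800 d; uniform censoring calibrated to a 30% censored fraction | right-skewed canine STS follow-up |
| IHC | per-sample log-normal latent intensity (CD204 ≈ 12, CD3 ≈ 6, FOXP3 ≈ 2.5 cells/field), zero-inflated; 5 Poisson fields | CD204 nearly ubiquitous, FOXP3 often absent |

Sex status is drawn at the clinical cohort's frequencies (4/1.3/42.7/52%
for intact male/intact female/castrated male/spayed female), sites, grades
and margins likewise. MYC is always on the panel and the `myc_high`
covariate is its simulated expression thresholded at the cohort median;
`foxp3_pos` is the latent IHC positivity — so the survival analyses are
exercisable end to end and parameter recovery is checkable against truth.

The generator deliberately does **not** emulate probe chemistry, lane QC,
background thresholding, batch effects, ortholog divergence, or
informative censoring. Passing tests therefore demonstrate that the
*statistical machinery* is correct under its stated model — not that real
canine data share 75% of the UPS signature. A single seed derives
per-stage seeds (seed, seed+1, seed+2 for expression, IHC, clinical;
pipeline stages offset further) so stages rerun identically in isolation.

## Validation design and problem sizes

The suite couples every nontrivial operation to an independent oracle:
hand-computed pooled quantiles (3×2), a naive double-loop geNorm
recomputation (100 random tables, ≤ 6 candidates), `aov` for the
vectorized F statistics, exhaustive label enumeration for the permutation
p (6 human samples, 20 splits), hand product-limit and log-rank tables,
and exact Wilcoxon enumeration. Calibration checks use 500 exchangeable
null replicates at $B = 999$ for the permutation test and 500
equal-hazard replicates for the log-rank test (rejection rate inside the
binomial 95% band around 0.05); subtype recovery uses 20 simulated
cohorts at full UPS sharing with 200 bootstrap replicates each; the
MYC hazard-recovery check uses 200 cohorts of 75 dogs at hazard ratio
2.5. These sizes keep the whole suite to a few minutes while leaving the
Monte Carlo bands narrow enough to be informative.

## Known limitations

- Gene matching is by symbol equality only; diverged orthologs and
  many-to-one mappings are excluded, which can bias the common set toward
  conserved genes.
- The permutation null assumes human samples are exchangeable across
  subtypes given the gene set; strong subtype-specific technical
  structure would violate it.
- The bootstrap closest-subtype frequency is conditional on the observed
  cohorts; within one dataset it tracks that dataset's noise, so its
  null behavior must be judged across datasets (as the tests do).
- The demographics fixture reproduces published marginal counts; its
  joint covariate structure is a deterministic synthetic layout, suitable
  for validating table machinery but not for inference about covariate
  association.
- No Cox modeling, pathway enrichment, or platform-QC normalization is
  included; they are outside the workflow this package implements.
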