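---
title: "Methods: anchor-centric pleiotropy scans and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchor-centric pleiotropy scans and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

## The model

`pleioscan` analyses the cross-phenotype structure of genetic associations
around one *anchor* disease (Alzheimer's disease, `AD`, in the motivating
application). The pipeline has six stages, each exported on its own:

1. **Variant QC** (`variant_qc()`). Observed minor allele frequency (MAF,
   folded to 0.5), call rate, and the exact conditional Hardy-Weinberg
   test. Retention rules: MAF strictly above `maf_min` (default 0.005 —
   "greater than 0.5%"), call rate at or above `callrate_min` (default
   0.95, i.e. at most 5% missingness, boundary kept), HWE p at or above
   `hwe_p_min` (default 1e-40). The HWE floor is deliberately permissive:
   in cohorts of hundreds of thousands, even biologically negligible
   departures from equilibrium are formally significant, so the filter is
   meant to catch genotyping failures only.
2. **Univariate scan** (`run_ewas()`). One regression per (variant,
   trait): ordinary least squares for quantitative traits, IRLS logistic
   regression for diseases (deviance tolerance 1e-8, at most 50
   iterations), always with an intercept, additive minor-allele dosage,
   and sex + age. Inference is Wald — the reported (beta, se, p) triple is
   exactly what such scans publish. Missing genotypes are dropped
   case-wise per variant; no imputation. If the counted allele turns out
   to be major in the analysis set, the dosage is folded (`2 - g`) and the
   allele labels swapped, so every record's effect allele is the minor
   allele and downstream sign logic never re-infers orientation.
3. **Pair-wise pleiotropy** (`run_pairwise_pleiotropy()`). For each
   variant, Fisher's method combines the anchor p-value with each other
   trait's p-value: `chi2 = -2(ln p_A + ln p_t)` on 4 degrees of freedom.
   Tiers: genome-wide when `p_F < 5e-8`, suggestive when
   `5e-8 <= p_F < 5e-6`, both additionally requiring `p_A < 5e-4` and
   `p_t < 5e-2` (the anchor-centric design is stricter on the anchor).
4. **Signed category matrix** (`build_signed_matrix()`). Rows are SNPs
   with `p_A < 5e-4` and at least one qualifying pair; columns are
   phenotypes with at least two qualifying pairs; the entry is
   `sign(beta_A * beta_t) * cat(p_t)` with the five-level category scale
   (4 for `p < 5e-8`, ..., 0 for `p > 0.05`).
5. **Clustering** (`ward_linkage()`, `cut_tree()`,
   `correlation_cluster()`). Ward's minimum-variance criterion on
   Euclidean distances over both axes, cut at height 5 by default; a
   second clustering with `1 - Pearson` distance validates the main one.
6. **Antagonistic heterogeneity** (`classify_antagonism()`,
   `summarize_antagonism()`). A qualifying pair is antagonistic when
   `sign(beta_A * beta_t)` and `sign(r(A, t))` are both non-zero and
   differ, where `r` is the individual-level Pearson correlation; pairs
   whose correlation is not significant at `corr_alpha = 0.05` are flagged
   not evaluable and excluded, mirroring how such heatmaps restrict
   themselves to traits with significant anchor correlations.

Assumptions worth stating: variants are treated as independent (no LD; one
index SNP per locus is selected by smallest anchor p, ties broken by
position then id); traits are measured once per individual; covariate
adjustment is sex + age only; Fisher's method assumes the two combined
tests are independent, which the weak trait correlations in this setting
approximately justify, and no correlation correction is applied.

## Parameters that matter

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `maf_min` | 0.005 | allele frequency | common-variant scan; strict `>` |
| `callrate_min` | 0.95 | fraction | "missingness better than 5%", boundary kept |
| `hwe_p_min` | 1e-40 | p-value | genotyping-failure screen only (see above) |
| `p_gw`, `p_suggestive` | 5e-8, 5e-6 | combined p | Fisher's method absorbs the 16-trait multiplicity in its df |
| `p_ad_max`, `p_trait_max` | 5e-4, 5e-2 | univariate p | anchor-centric asymmetry |
| `min_trait_pairs` | 2 | count | a phenotype represented by one association carries no clustering signal |
| `height` | 5 | Ward merge height | the scale of category units at which planted blocks separate |
| `corr_alpha` | 0.05 | p-value | evaluability gate for antagonism |

All are constructor arguments (`qc_thresholds()`, `tier_thresholds()`,
`selection_rules()`, `category_scale()`), never hidden constants.

## Numerical choices

* **Log-space tails.** Combined p-values near 1e-12 and exact-test tails
  near 1e-30 lose digits (or underflow) in naive arithmetic. Fisher
  combination evaluates the chi-square tail with `log.p = TRUE` and also
  reports `log10_p`; the HWE and 2x2 exact tests accumulate their
  hypergeometric tail masses with a log-sum-exp. Serialised summary
  statistics carry a `LOG10_P` column next to the 6-significant-digit
  scientific value.
* **Two-sided exact tests.** Both exact tests use the minimum-likelihood
  convention: the p-value sums all outcomes whose conditional point
  probability does not exceed the observed one (with a 1e-7 relative
  tolerance on the point mass, matching `fisher.test`'s convention; the
  HWE test uses 1e-12 since its support is smaller). A mid-p Hardy-
  Weinberg variant exists behind `midp = TRUE`, default off.
* **Ward flavour.** `ward.D2` (squared-distance Lance-Williams update) is
  the default; merge heights are then guaranteed monotone and relate to
  the greedy variance increase by `height = sqrt(2 * delta-SS)`, which is
  what the brute-force test oracle checks. The legacy criterion on
  unsquared distances (`ward.D`) is available behind a flag because
  clustering functions in the wild differ and the choice is rarely
  reported.
* **Boundaries.** The category scale maps `p = 0.05` to category 0
  (conservative toward "no evidence": the open intervals of the published
  scale leave the point unassigned). `maf_min` is strict (`>`),
  `callrate_min` and `hwe_p_min` are inclusive (`>=`).
* **Degenerate inputs.** Saturated linear fits report `se = 0` with
  status `"degenerate"`; monomorphic dosages, one-class outcomes and
  singular designs raise errors that `run_ewas()` converts to explicit
  per-record statuses; logistic coefficients above 15 in magnitude or
  non-convergence are flagged (`"separation"`/`"nonconverged"`) and the
  pair is skipped downstream with a logged reason — rare variants against
  a 0.2%-prevalence disease separate easily. Monomorphic-after-missingness
  variants fail the MAF filter via the fold to 0. A single-row matrix
  yields a trivial single-leaf tree; an all-zero row or column is excluded
  from the correlation-distance validation with a warning.
* **Determinism.** Every stochastic entry point takes a `seed` and runs
  under a saved-and-restored RNG state, so outputs are a pure function of
  (inputs, seed) and pipeline re-runs are byte-identical; dendrogram ties
  are resolved by `hclust`'s deterministic merge order.

## What the synthetic cohort emulates — and what it does not

`effects_spec()` describes a generative model: 17 traits (7 diseases, 10
quantitative) with realistic biobank-style prevalences, means and SDs;
weak anchor-trait correlations and a handful of strong trait-trait
correlations (lipids, blood pressure, anthropometry) induced by shared
latent Gaussian factors (the default matrix is projected to the nearest
correlation matrix, since a patchwork of published marginal correlations
need not be positive semi-definite); age uniform on 40-70 and sex
Bernoulli(0.55); additive planted effects in trait-SD units
(quantitative) or log-odds (diseases). Disease generation is logistic —
not liability-threshold — precisely so planted log-odds live on the same
scale the analysis fits, with the intercept solved by 1-D root finding to
hit the target prevalence; an unreachable target degrades to a warning
plus the realised prevalence.

`planted_demo_spec()` is the reference recovery design: 13 index SNPs
(drawn among common variants, MAF >= 0.2, as published index SNPs mostly
are), anchor effects of |0.5| log-odds at an enriched anchor prevalence of
0.20, and three phenotype blocks — lipids (5 SNPs), blood pressure (4) and
anthropometry (4) — with concordance signs mixed within each block so both
antagonistic and non-antagonistic configurations occur (19 of the 40
planted pairs are antagonistic). Anchor-trait correlations are induced by
a shared age effect (anchor risk rises steeply with age; each trait
correlates with the anchor in the direction of its own age slope), strong
enough (|r| ~ 0.06-0.12) that every planted trait passes the evaluability
gate at the design sample size of n = 5000.

One design decision deserves emphasis: the demo gives diseases **no
latent frailty** (`frailty_scale = 0`), so a disease's generative logit
contains exactly the planted genetics plus modelled covariates. With a
frailty term (or, equivalently, with the other 12 planted SNPs treated as
omitted variables), marginal single-SNP logistic estimates are attenuated
by noncollapsibility — the population-averaged log-odds ratio is smaller
than the conditional one even without confounding. Conditional-beta
recovery is therefore checked with the correctly specified model (sex,
age, and the other planted dosages as covariates) for binary traits;
linear fits are collapsible and are checked with sex + age only. The
general-purpose `effects_spec()` default keeps `frailty_scale = 2` for
realistic disease-disease correlations; users planting disease effects
should be aware that the scan's marginal estimates will sit below the
planted conditional values in exactly the way real scans sit below
conditional family-model effects.

Not emulated, by design: linkage disequilibrium between variants (the
analysis selects one index SNP per locus anyway), population structure and
relatedness, longitudinal measurements, genotyping batch effects, and any
claim that the latent-factor correlation structure is the true generative
process behind the published marginal correlation tables. Passing recovery
tests therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to structure the generator omits.

## Problem sizes used in validation

The test suite validates the exact tests exhaustively against enumeration
oracles for all genotype configurations with up to 200 individuals and all
2x2 tables with totals up to 28 (plus 2,000 random tables with totals up
to 300 — full enumeration of that range is combinatorially out of reach);
Ward linkage against brute-force greedy variance minimisation on all
random instances with up to 7 items; calibration on 1e6 uniform p-value
pairs and on a null cohort of 5,000 individuals x 500 common variants; and
recovery on the planted design at 5,000 individuals x 2,000 variants with
ten replicate cohorts for the +-3 SE beta-recovery rate. The package-level
fixtures use 4,000 individuals x 300 variants to keep the default test run
fast.

## Known limitations

* Fisher's method ignores correlation between the paired tests; with
  strongly correlated traits the combined p is anti-conservative. The
  package deliberately offers no Brown/Stouffer-style correction — out of
  scope.
* The suggestive tier inherits the univariate filters; whether published
  analyses did the same is not always stated (`suggestive_filter = FALSE`
  disables it).
* Summary-statistic correlations use z-scores (`beta/se`) per variant;
  a `method = "beta"` mode exists, and with few variants both are noisy.
* The qualifying-pair rule admits a null trait with probability ~0.05 per
  pair through the univariate filter when the anchor association is very
  strong; the minimum-2-pairs column rule suppresses most, not all, such
  columns. This mirrors the published procedure rather than fixing it.
* Logistic Wald inference degrades for very rare variants (few carriers);
  the scan flags separation rather than applying Firth-type corrections.
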