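---
title: "Methods: quantifying sexual conflict and its genomic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sexual conflict and its genomic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(saconflict)
```

## The scientific question

Intralocus sexual conflict arises when an allele helps one sex and harms
the other. Two genomic mechanisms can resolve it: recombination can
decouple an antagonistic locus from its neighbours so that
sex-differential selection can act on it, and gene duplication can let
paralogous copies specialise, one per sex. This package quantifies
per-locus conflict from sex-specific GWAS effect sizes and tests three
linked predictions:

1. **Balancing selection**: alleles whose benefit to one sex outweighs
   the detriment to the other should segregate at higher frequency.
2. **Recombination**: genes under more intense conflict should sit in
   regions of higher recombination rate.
3. **Duplication**: genes under more intense conflict should more often
   have paralogues.

## Per-SNP statistics

Association `z`-scores are converted to Cohen's *d* through the
correlation `r = z / sqrt(N)`, `d = 2 r / sqrt(1 - r^2)`
(`z_to_cohens_d()`). For a sexually antagonistic SNP (opposite-sign
effects in the two sexes), two summaries are formed:

* the **effect-size ratio** `d_benefit / d_detriment`
  (`effect_size_ratio()`), always negative; a ratio below −1 means the
  benefit exceeds the detriment (`classify_net_effect()` calls this
  `net_beneficial`);
* the **sexual antagonism index**
  `SAI = d_M d_F / sqrt((d_M^2 + d_F^2) / 2)` (`sai()`), negative for
  antagonistic loci, with magnitude growing with the smaller of the two
  effects. The denominator is the root-mean-square of the two effects,
  which makes the index symmetric in the sexes, scale-equivariant
  (`sai(c*a, c*b) = c * sai(a, b)` for `c > 0`) and equal to `-|d|` when
  `d_M = -d_F = d`. A `denominator = "mean_square"` variant is provided
  for sensitivity analyses.

```{r}
sai(0.3, -0.3)
effect_size_ratio(d_benefit = -0.4, d_detriment = 0.2)
classify_net_effect(-2)
```

## Allele-frequency models

Prediction 1 is tested by weighted least squares of minor-allele
frequency on the effect-size ratio, with the supplied per-SNP weights
(typically inverse variances): `fit_weighted_regression()`. Category
structure is handled by a ratio × functional-category interaction model
(`fit_interaction_model()`), whose main-effect and interaction tests are
nested *F*-tests on weighted deviances, and by per-category stratified
fits (`fit_stratified()`, `regression_table()`).

## Conflict tertiles and recombination

Loci (or genes, via the mean SAI of their pooled variants,
`pool_gene_sai()`) are ranked by SAI and split into three equal tertiles
(`assign_tertiles()`): the **most negative** SAI values form the
`high`-conflict tertile, and tertile sizes differ by at most one, extras
going to the higher-intensity tertiles first. Each locus receives the
length-weighted mean rate of the recombination-map windows it overlaps
(`assign_recomb_rate()`); intervals are lifted between assemblies with
an affine block map (`liftover()`, 0-based half-open blocks, 1-based
query positions, invertible via `invert_liftover_map()`).

Tertile rates are compared with:

* the **Brown–Mood median test** (`moods_median_test()`): counts above /
  at-or-below the grand median per group, Pearson chi-square on the 2×k
  table, df = k − 1; ties are counted in the "at or below" row and no
  continuity correction is applied by default;
* **Levene's test** (`levenes_test()`): ANOVA on absolute deviations
  from group means (`center = "median"` gives the Brown–Forsythe
  variant);
* pairwise **post-hoc median tests** with Bonferroni adjustment
  (`pairwise_posthoc_median()`).

The two-group Brown–Mood statistic is also available as a signed `Z`
(`two_sample_median_z()`), satisfying `Z^2 = chi^2 (N-1)/N`.

## Paralogue analyses

Paralogue families are connected components of the scored-pair graph
over the gene universe, keeping pairs with `diopt_score >= min_score`
(`build_paralog_families()`); a gene's paralogue count is its number of
distinct direct partners. Per tertile, the proportion of genes with at
least one paralogue is compared to a genome-wide background by 2×2
Pearson chi-square (`proportion_with_paralogs_test()`); counts among
genes that have paralogues are compared across tertiles by Wilcoxon
rank-sum (`paralog_count_tertile_tests()`). `wilcoxon_rank_sum()`
reports the rank-sum `W` of the first sample (and the Mann–Whitney `u`),
using the exact null distribution when both groups have at most 25
observations and no ties, otherwise a midrank, tie-corrected normal
approximation without continuity correction.

## The synthetic generator

`generate_snp_table()`, `generate_recomb_map()`,
`generate_paralog_pairs()` and `generate_liftover_map()` are pure
functions of a `synthetic_config()` and its seed, emulating the
structure of all required inputs so the full pipeline
(`run_pipeline()`) runs without external data.

Key defaults and their rationale:

* `n_genes = 337`, `snps_per_gene = 2372/337`: a study of roughly 2,400
  antagonistic SNPs in ~340 genes, a realistic scale for a sex-specific
  GWAS follow-up.
* Effect magnitudes are half-normal (`effect_sd = 0.2`) per sex with
  opposite signs, so the effect-size ratio is distributed as −|Cauchy| —
  deliberately heavy-tailed.
* Allele frequency follows `freq_intercept + freq_slope * ratio` plus
  Gaussian noise (`freq_slope = -0.126`, `freq_noise_sd = 0.07`),
  truncated into the minor-allele range (0.005, 0.5]. Because the ratio
  is heavy-tailed, a substantial minority of frequencies hit the
  truncation bound; the truth record flags them (`clamped`), and the
  generated raw frequency is kept alongside.
* Recombination rates are log-normal per window (`rate_log_mean =
  log(2)`, `rate_log_sd = 0.5`, in cM/Mb); windows overlapping
  high-tertile genes are scaled by `sai_recomb_effect = 1.5`.
* Paralogue presence is logistic in the recombination-rate z-score and
  the conflict tertile index (`paralog_base_logodds = -0.32`,
  `paralog_recomb_coef = 0.3`, `paralog_sai_coef = 0.25`); counts among
  owners are zero-truncated Poisson with mean
  `paralog_count_mean * exp(paralog_count_tertile_coef * tertile_index)`.
* `n_background_genes = 2000` non-conflict genes provide the
  genome-wide comparison set; `unmapped_frac = 0.05` of liftover blocks
  are dropped to exercise the unmapped-record accounting.

A note on estimation from the generated data: the truncation of
frequencies at the minor-allele bounds attenuates the fitted slope when
all SNPs are used. Recovery checks in the test suite therefore condition
on the ratio band where a 3-standard-deviation noise excursion cannot
reach either bound; conditioning on the regressor keeps weighted least
squares unbiased, so the generating slope is recovered there.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (draws are independent), more than one source chromosome, non-star
paralogue families (generated families are a gene plus its sampled
partners; the family *builder* handles arbitrary graphs), dominance or
epistasis, and frequency dynamics beyond the linear-with-truncation
model above. Conclusions about those features cannot be drawn from
synthetic runs.

## A small worked example

```{r}
cfg <- pipeline_config(
  synthetic_cfg = synthetic_config(n_genes = 80, n_background_genes = 300),
  seed = 7, two_species = FALSE)
res <- run_pipeline(cfg, file.path(tempdir(), "vignette_run"))
res$regression[, c("functional_category", "n", "slope", "p_value")]
res$paralog_proportions[, c("tertile", "proportion", "p_value")]
```

Every run writes its tables atomically (staged, then moved) together
with a `manifest.tsv` that accounts for every record: SNPs in, SNPs
antagonistic, genes pooled, genes lost to liftover or missing rates,
background counts. Identical configuration and seed give byte-identical
outputs.

## Conventions summary

* Intervals (genes, recombination windows, liftover blocks) are 0-based
  half-open; SNP and query positions are 1-based.
* Ties in the median tests go to the "at or below the grand median" row.
* No continuity corrections by default (`correct = FALSE`,
  `continuity = FALSE`); switches exist on each test.
* Levene centering defaults to the group mean; `"median"` gives
  Brown–Forsythe.
* Multiplicity adjustment for post-hoc tests defaults to Bonferroni.
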