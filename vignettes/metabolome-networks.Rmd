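---
title: "Methods: diet- and age-driven rewiring of the metabolome correlation network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet- and age-driven rewiring of the metabolome correlation network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacoex)
```

`metacoex` analyses untargeted LC-MS metabolomic feature tables from
two-diet (ad libitum, AL, vs dietary restriction, DR), multi-age designs.
This vignette is the package's own account of the models it fits, the
parameters that matter, what the synthetic generator does and does not
emulate, and the design choices made where the design was genuinely open.

## Data model

A *feature table* is a tibble with one row per LC-MS feature, keyed by
`feature_id`, `mz` (Da), `rt` (s) and `column_id` (chromatography column),
followed by one column of intensities per sample. Its measurement scale
(`raw`, `log`, `centered`) travels as an attribute so each preprocessing
step can check its precondition. Sample metadata live in a separate design
tibble (`sample_id`, `bio_id`, `diet`, `age` in days, `tissue`, `batch`,
replicate indices); *technical* replicates re-measure the same extract,
*biological* replicates are independent fly populations.

## Quality control

The chain in `run_qc()` is: log2 transform (pseudocount 1) → sample-outlier
removal → SNR filter → technical-replicate averaging → missingness filter →
imputation → mean-centering.

* **Outliers.** Sample affinity `a_ij = (1 + cor(i, j))/2` over complete
  features; connectivity `k_i = sum_{j != i} a_ij`; samples with
  standardized connectivity `Z_k < -3` are removed. A sample that
  disagrees with every other sample has low connectivity and a strongly
  negative `Z_k`. If the connectivities are all equal (`sd k = 0`) no
  sample is flagged.
* **SNR.** Per feature, `sigma_tech` is the mean over biological samples
  of the sd among that sample's technical replicates; SNR =
  mean intensity / `sigma_tech`; features with SNR < 20 are dropped. Two
  readings of "average standard deviation of each technical replicate"
  are defensible (mean of sds vs pooled sd); the mean is the default and a
  pooled variant is available (`sigma = "pooled"`). SNR is computed on the
  log scale by default, after the transform that precedes it in the chain;
  the raw scale simply requires calling the filter before `log_transform()`.
  A feature with `sigma_tech = 0` is noiseless and kept.
* **Missingness and imputation.** After collapsing technical replicates
  (cells are missing only when all replicates are missing), features with
  more than 10 % missing biological samples are removed; the survivors are
  imputed. The default `knn` method maps each neighbour's value through
  the least-squares line relating the two features and averages `k = 10`
  neighbours with weights `|r|`; an iterated-regression `em` mode
  (regress each incomplete feature on its most correlated complete
  features until the largest change drops below `1e-6`) is available. Both
  are deterministic. Missing cells are excluded pairwise from all
  correlation computations before imputation.
* **Centering.** Features are centered to mean 0 but *not* rescaled, so
  effect sizes and variances remain in log2-intensity units.

The 10 % missingness rule is applied after outlier removal (the removed
samples no longer count in the denominator).

## Per-feature effect models and the reversal analysis

Each feature is fitted by OLS `y = mu + beta x`, one predictor at a time:
diet coded AL = 0 / DR = 1 (positive `beta` = higher under DR), age in days
(slope per day). Fitting one predictor at a time on targeted sample
subsets — diet at a single age, age within the AL arm, by default the
10-vs-40-day contrast — avoids confounding the two. P-values are BH
adjusted; the default FDR is 0.05, with 0.025 for the reversal analysis
and unadjusted P < 0.01 for the per-tissue overlap counts, each a config
parameter.

The reversal analysis joins the two effect tables and classifies each
feature by significance (`none` / `diet-only` / `age-only` / `both`) and
quadrant: opposite slopes (`sign(beta_diet) * sign(beta_age) = -1`) are
*reversals* — DR pushes the feature back toward its young level — and
same-sign pairs are *exacerbations*. Whether "significant for both"
should be a joint FDR across the two tests is open; each test is
thresholded marginally at 0.025, which matches how the two axes are
fitted independently.

Pooling tissues or batches before these models requires batch adjustment:
`batch_adjust()` wraps parametric empirical-Bayes location/scale
adjustment (ComBat from the `sva` package) preserving the design
covariates. `run_full()` applies it right after QC — on synthetic data,
planted batch shifts otherwise induce genuine batch-driven correlations
that contaminate the preserved-network analysis below. With a single
batch it is a no-op; perfect confounding between batch and a covariate is
an error.

## Differential-correlation pair screen

Pairs whose *means* are diet-invariant but whose *correlation* is
diet-dependent are found in two steps: a mean gate (features with
unadjusted diet-effect p > 0.05), then per pair the ANCOVA
`y_j = mu + a y_i + b diet + c (y_i x diet)` with an F test on the
interaction at df (1, n − 4) — with 23 samples this is the F(1, 19)
convention. The model is asymmetric; the convention is that the
larger-variance feature is the covariate, with ties keeping the first
argument as covariate, so results are deterministic under argument
swapping. A Fisher r-to-z difference p-value is reported alongside as a
descriptive cross-check. BH-FDR is applied across all tested pairs.

All-pairs screening is O(p²); the exact screen is the function default,
and the pipeline configuration uses desk-scale caps (pre-filter
`|r_AL − r_DR| >= 0.3`, at most 20 000 pairs by seeded subsampling).

## Difference and constancy networks

Per-condition signed Pearson correlation matrices `C`, `C'` are computed
over identical feature sets (≥ 4 samples per condition; for age
comparisons the samples are quantile-normalized first so distributional
shifts between ages do not masquerade as correlation changes). Two
transforms map a pair of networks to a clusterable adjacency:

* **Difference** (DiffCoEx form):
  `D_ij = (1/2 |sign(c) c² − sign(c') c'²|)^(beta/2)` — large where the
  signed-square correlation changes between conditions.
* **Constancy** (SimCoEx): the default is
  `K_ij = min(|c|, |c'|)^beta` when the signs agree, 0 otherwise. An
  algebraic mirror of the difference form (sum replacing difference,
  `(1/2 |sign(c) c² + sign(c') c'²|)^(beta/2)`) is available via
  `method = "signed_sum"`; it was not made the default because it awards a
  pair correlated in a *single* condition 1/8 of the fully-preserved score
  (at `beta = 6`), which lets condition-specific modules leak into the
  preserved clustering — contradicting what a constancy score should mean.
  The two forms coincide whenever `c = c'`.

The soft power `beta` defaults to 6 and must be even so the signed squares
stay monotone. Both transforms are exchange-symmetric in their condition
arguments, and maximal difference excludes maximal constancy.

Adjacencies are smoothed by the unsigned topological overlap measure
`t_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)` and
clustered on `1 − TOM`.

### Module extraction

`cluster_modules()` is a simplified dynamic-hybrid cut: average-linkage
clustering, a static cut at the greatest merge height not exceeding
`max_height = 0.996` (the conventional ceiling for difference-matrix trees,
whose dissimilarities crowd toward 1; a cut yielding one branch that
swallows the whole tree is skipped and lower heights are tried), then a
medoid-style completion pass — every feature joins the module whose
members it is closest to on average, provided it is closer than the
midpoint between that module's internal cohesion and the background
level. Completion recovers loosely attached members that only merge near
the top of the tree and expels accidental core members; an earlier
design that scanned cut heights for the best silhouette proved unstable
on near-1 TOM trees, where silhouette widths are compressed to the 1e-3
scale. Modules smaller than `min_size = 10` dissolve to grey. Labels
follow the usual size-ranked color palette and are arbitrary.

### Module significance

At modest sample sizes the sampling variance of a correlation estimate
grows with the underlying correlation, so a strongly *preserved* module
also shows mildly elevated difference-matrix entries. The discriminator is
the method's own significance step: per module, the dispersion
`sqrt(mean D_ij²)` over within-module pairs is compared with a null built
by permuting the condition labels across samples — a permutation that
keeps the pooled correlation structure while destroying the condition
split. `p = (1 + #{null ≥ obs}) / (1 + n_perm)`, so p is floored at
`1/(1 + n_perm)`.

Significance alone is not sufficient, however: a preserved module built
on a shared latent factor can have a *realized* correlation level that
genuinely differs between the two condition samples (the empirical
variance of the latent fluctuates), and the permutation test then
correctly — but unhelpfully — flags it. `coex_modules(mode = "diffcoex")`
therefore applies a second, parameter-free screen: a module whose mean
within-module constancy score exceeds its mean within-module difference
score is shared structure whose level happens to differ, not a change in
kind, and is dissolved. The comparison pits the package's two transforms
head to head, so it keeps modules whose correlations flip sign, appear
or vanish while removing strong sign-concordant ones; the boundary case
of a genuine halving of correlation strength (say 0.8 to 0.4) stays —
its difference score dominates — while milder attenuation (0.8 to 0.6)
is treated as preserved. Both screens run by default (`alpha = 0.05`,
200 permutations) and failing modules dissolve to grey; the
preserved-mode clustering needs no analogous screen because the
min-concordant constancy transform already scores single-condition
structure at background level.

### Distribution-level shifts

`correlation_shift_test()` compares mean off-diagonal correlations.
Pairwise correlations are heavily dependent, so significance comes from
permutation. When the underlying sample matrices are supplied, the null
permutes condition labels over the pooled samples and recomputes both
means — the exact exchangeability argument, and the calibrated default
(measured type-I error ≈ 0.02–0.05 at nominal 0.05). A paired sign-flip
over per-feature mean-correlation differences is the fallback when only
correlation matrices are available; it ignores the common sampling
component shared by all features, measured here to inflate type-I error
to ≈ 0.17, and is therefore flagged in the output (`method` column) and
never used when sample data are at hand. A naive t-test is reported as
descriptive only.

### Feature selection for network clustering

Mirroring the practice of clustering only features whose correlations are
condition-informative, `differential_feature_selection()` tests every
pair's correlation per condition (`t = r sqrt(n−2)/sqrt(1−r²)`, default
alpha 0.01) and labels a feature *differential* (≥ 1 pair significant in
exactly one condition, none in both) or *similar* (≥ 1 concordant pair
significant in both). The exact rule behind such counts is a documented
reconstruction, not a claim of equivalence to any particular published
selection; at several thousand features it is noisy (chance double
significance removes true differential features), which is why module
*recovery* is benchmarked on the clustering itself and the selection is
kept as pipeline plumbing.

## Metabolite-set enrichment

Features are annotated by m/z: a feature matches a reference metabolite
when `|observed − (M + shift)| / (M + shift) ≤ 10 ppm` for an allowed
adduct (defaults: M+H +1.007276, M+Na +22.989218, M+K +38.963158,
M−H −1.007276, M+ −0.00054858 Da). Annotation is many-to-many and
monotone in ppm; before counting, features collapse to unique metabolites
to avoid multiplicity inflation. Each named set is tested with an
upper-tail hypergeometric p on the metabolite-level overlap, BH-adjusted
across sets; zero overlap reports p = 1. This replaces activity-network
permutation machinery with a simpler, exactly testable statistic — a
deliberate divergence. The per-condition significance threshold defaults
to q ≤ 0.05. The frequency table marks, for each set, the conditions in
which it was enriched and counts them, sorted by descending frequency.

## The synthetic generator

`simulate_features()` builds log2 intensities additively: per-feature
baseline `N(14, 2²)` (≈ 16 000 counts), diet effect × diet code, per-day
age slope, per-batch shift `N(0, 0.3²)`, correlated biological noise
(sd 0.5), then technical noise per replicate (sd 0.2, or 1.5 for a
low-SNR fraction, giving SNR ≈ 70 vs ≈ 9 around the 20 cutoff), an MCAR
mask, and exponentiation back to intensities. m/z values are uniform in
the printed per-column ranges (anion exchange 86.0605321–1738.34568 Da,
C18 85.0279778–1976.50254 Da) so annotation is exercised realistically.
The design defaults — 2 diets × ages {10, 20, 40} days × 6 biological ×
3 technical replicates — represent a typical dietary-restriction fly
study sampling young, middle-aged and near-median-lifespan animals; ages
are free parameters.

Correlated modules use a latent-factor construction: member features load
`sqrt(r)` on a shared per-condition factor with residual `sqrt(1−r)`,
giving an analytically known expected within-module correlation `r`
(attenuated by technical noise to ≈ `0.95 r` after averaging 3 technical
replicates). Patterns cover DR-only, AL-only, both-same-sign,
both-opposite-sign, and an age-trajectory mode in which `r` varies by
(diet, age) — used to emulate connectivity rising with age under DR and
falling under AL. Module features are drawn preferentially from features
without planted mean effects so correlation structure is not confounded
with abundance shifts. Effect fractions default to 0.15 — the order of
magnitude typically seen for diet-responsive fractions of fly metabolomes
(roughly 10–20 %, varying by tissue) — and the reversal fraction to 0.8,
emulating a strong reversal of ageing changes under restriction at older
ages; effect sizes are `N(0, 1)` in log2 units, with age effects
drawn as a total change over the age span and converted to per-day
slopes.

What the generator does **not** emulate: intensity-dependent missingness
(MCAR only), retention-time drift, adduct/isotope structure within the
feature list, heavy-tailed intensity distributions, and realistic
lifespan structure. Passing tests therefore demonstrate correctness of
the statistical machinery under a Gaussian log-scale model of the design,
not robustness to every artefact of real LC-MS data.

## Numerical choices and degenerate inputs

* log base 2, pseudocount 1 (configurable); negative intensities error.
* Constant response in OLS: `beta = 0, p = 1`; constant predictor errors.
* `sigma_tech = 0` → SNR = ∞ (kept); all-connectivities-equal → no
  outliers; samples with every cell missing are unimputable (error).
* Quantile normalization averages tied ranks; it requires a complete
  matrix.
* Permutation p-values use the add-one convention, flooring at
  `1/(1 + n_perm)`; n_perm < 100 warns, < 10 errors.
* Single-batch input passes through batch adjustment unchanged.
* Hierarchical-merge height ties are monotonised before cutting.
* The pipeline derives per-stage seeds from one global seed by fixed
  offsets, so stages are independently re-runnable and end-to-end output
  is byte-identical under a fixed seed.

## Problem sizes

The shipped tests and the acceptance script run on simulated designs of
150–2000 features and 24–108 samples, with 200–1000 permutations per
test and module-recovery benchmarks at 500 features / 24 biological
samples per condition (medians over three simulation replicates, since a
single realized sample can make a planted preserved module genuinely
differential). These sizes give stable Monte-Carlo estimates for the
properties checked; all scale linearly or quadratically in features if
larger runs are wanted.

## Known limitations

* The constancy transform and the per-pair feature-selection rule are
  reconstructions of sparsely specified methods; both are flagged as such
  above and swappable.
* The module extractor is a deliberate simplification of dynamic tree
  cutting; it recovers planted block structure exactly and single planted
  modules with ARI ≈ 0.8–0.95 at the benchmark sizes, but has no
  deep-split control for nested modules.
* ANCOVA screening treats samples as exchangeable within diet; repeated
  measures or cage effects are out of scope.
* Enrichment ignores retention time and isotope patterns; annotation is
  putative by construction.
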