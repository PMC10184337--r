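---
title: "Models and methods behind poemeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poemeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`poemeth` analyses the parent-of-origin-effect (POE) methylome: CpG sites
whose methylation carries a signature of parental origin, split into a
*typical* class (imprinting-like, POE-mQTL-driven, near-extreme beta
values) and an *atypical* class (no detectable POE-mQTL, intermediate
methylation, sensitive to early environment). This vignette documents the
statistical models, the tunable parameters, the synthetic cohort
generator that the test suite validates against, and the numerical and
design decisions a maintainer should know about.

## Data model

Methylation travels as a samples-by-CpGs matrix with a declared scale:
`beta` (proportions in [0, 1]), `m` (logit2 of beta) or `residual`
(covariate-adjusted). The orientation is fixed everywhere to avoid silent
transposition. Beta-to-M conversion clips betas into
[epsilon, 1 − epsilon] with epsilon = 1e−6 — far inside measurement
precision, so interior values are untouched while the logit stays finite.
Missing methylation cells are rejected at ingestion (array quality
control is assumed to have run already); missing phenotype values are allowed and dropped per
phenotype. CpG coordinates are 1-based base pairs; the lexicographic
(chromosome, position) order, ties broken by CpG id, defines the genomic
ring used by the circular permutation.

## Covariate regimes and adjustment

Three covariate sets drive every analysis:

* `set1` — cell proportions, technical covariates, smoking status and
  pack-years, age, age², sex (the full regime);
* `set2` — `set1` without the smoking variables (used when smoking status
  is the phenotype under test);
* `set3` — `set1` without age and age² (used for age-acceleration
  phenotypes, which are age-adjusted by construction, and for the
  connectivity analyses, where age is the object of study).

Methylation is residualized per CpG by least squares; the operation is
idempotent and projects any CpG lying in the covariate span to exactly
zero. Phenotypes are prepared in the order: log10 transform if the trait
is positive and |skewness| exceeds 1 (the numeric skewness cutoff is a
package decision); a single-pass outlier
rule removing values beyond 4 SD of the post-transform mean (the SD is
never recomputed after removal); then residualization on the technical
covariates only. This asymmetry — biological covariates removed from the
methylation side, phenotypes adjusted only for structural effects — is
deliberate: in family cohorts the phenotype side is classically
pre-adjusted for genetic relationship structure and clinic only. Since the
synthetic cohorts are unrelated by construction, fixed-effect
residualization stands in for the mixed-model genetic pre-adjustment; the
package does not fit genomic or kinship relationship matrices.

## The MOA mixed model

The single-CpG scan fits, per phenotype–probe pair,
$$y_p = w_m b_m + g + e,\qquad g \sim N(0, \sigma^2_g\,\mathrm{ORM}),\quad
e \sim N(0, \sigma^2_e I).$$
The omic relationship matrix is built from population-SD-standardized
probes, $\mathrm{ORM} = Z Z^\top / M$, so its diagonal averages exactly 1;
zero-variance probes are excluded with a warning. The REML profile in the
variance ratio $\lambda = \sigma^2_g/\sigma^2_e$ is maximized on the
log scale over [1e−6, 1e6] after a one-time eigendecomposition of the
ORM; the $\lambda = 0$ boundary is evaluated exactly, and when it wins
the fit reduces *exactly* to ordinary least squares (the test suite
asserts this identity). The fixed effect uses a Wald z test; the
CpG-outcome validation model — methylation as outcome, phenotype and
covariates as predictors — uses a t reference with residual degrees of
freedom. A `ratio` argument fixes the variance ratio, which is how the
zero-variance-component oracle check is run: on a finite null dataset the
free REML estimate lands on a small interior ratio about half the time
(an ordinary boundary-score fluctuation), so exact OLS agreement is a
property of the $\lambda = 0$ limit, not of every null fit.

The ORM in this package includes all probes, the target included;
excluding the target (or its chromosome) can be done by passing
`probe_ids` to `build_orm()`. With hundreds of thousands of probes the
difference is negligible; on small synthetic methylomes it is visible but
does not change calibration, which the type-I-error tests check directly.

The discovery → replication → validation workflow applies
Benjamini–Hochberg FDR (the package's reading of "FDR"; it is the field
default) at q = 0.05 within each stage: all pairs in discovery, the
discovery survivors in replication, and the CpG-outcome model on the
replicated pairs in both batches. Pairs passing all filters are the
high-confidence set.

## Co-methylation modules

Networks are unsigned: adjacency $a = |r|^\beta$. The topological overlap
measure
$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}$$
is clustered by average-linkage on $1 - \mathrm{TOM}$ with a static
branch cut. The cut height defaults to 0.995: weakly co-methylated
modules in the regime the aging analyses target (mean |r| around
0.15–0.3 at power 3) sit at TOM dissimilarity ≈ 0.992–0.994, while noise
CpGs merge above ≈ 0.999, so 0.995 separates the two; the original
dynamic tree cut is an unpublished heuristic and is deliberately not
reproduced branch-for-branch — planted-block recovery, not WGCNA
identity, is the acceptance standard. Branches with ≥ 8 CpGs become
modules.

The soft power is chosen as the smallest candidate in 1..20 whose
slope-signed scale-free fit R² reaches 0.85 (the WGCNA convention; on
sets of a few hundred CpGs the binned log–log fit is noisy and a 0.8
target is occasionally reached by a clearly non-scale-free power-2
network). The recursive construction proceeds as specified by the
protocol: detect tight modules at the currently picked (typically high)
power; within each module keep only the index CpG — maximal summed |r|
with the other members, ties to the smaller coordinate — per 10-kb
window (`floor(position / 10000)` per chromosome, anchored at 0); repeat
until nothing is removed; re-pick the power on the pruned set; and build
the final network on *all* group CpGs with that power. A
`soft_power_override` (the protocol's optimized value is 3) bypasses the
search; the bundled end-to-end runs use it.

Cross-batch matching ranks all discovery–replication module pairs by
intersection/union overlap and greedily accepts pairs strictly above
60%, consuming both sides; unmatched replication modules then attach to
a discovery module when |intersection|/|replication module| strictly
exceeds 90% (several replication modules may attach to one discovery
module). Matched pairs are "consistent modules"; their intersections are
the constituent CpGs. Both thresholds are strict inequalities, so an
overlap of exactly 6/10 does not primary-match (though a fully nested
module still attaches through the secondary rule).

Module PCs use correlation-matrix PCA (standardized CpGs, the common
convention of PCA toolkits in this field; covariance PCA is available behind
`standardize = FALSE`) trained on the discovery samples and projected
everywhere with the training centring/scaling. The "SS loading" of a
component — the sum of squared loadings after scaling by the singular
value — equals the correlation-matrix eigenvalue, so the retention rule
(SS loading > 1 AND > 5% variance explained) is a Kaiser-style rule.
Three PC variants are kept per module, one per covariate regime, and the
phenome scan picks the regime by phenotype class (set2 for smoking
status, set3 for age acceleration, set1 otherwise), with Bonferroni
control over the discovery scan and again over the replication of its
survivors.

## Connectivity dynamics

Samples are stratified into six inclusive age bins (18–27, 28–37, 38–46,
47–56, 57–65, 66–94 years); connectivity is the pairwise Pearson
correlation of `set3` residuals (age deliberately not removed) within
each bin, stored signed and absolute. Three tests are offered:

* `test_connectivity_shift()` — the protocol's test is described as a
  paired rank-sum test, which mixes two different tests; the package
  implements the
  Wilcoxon *signed-rank* (paired) test on per-pair |r| between two bins,
  matching the "paired" qualifier, with `paired = FALSE` available.
* `test_connectivity_trend()` — a bin-level linear trend of mean |r| on
  bin midpoints. This exists because the pair-level paired test treats
  the k(k−1)/2 pairs as independent evidence, but in a factor-structured
  module all pair estimates co-move within a bin, making the paired test
  anticonservative for a global null — a truly flat module triggers it
  far above nominal rates at any sample size. The bin-level trend uses
  the bin as the unit, stays calibrated under that dependence (the
  test suite checks both properties), and retains ample power for real
  trends. Pair-level p values should be read as descriptive strength,
  not calibrated evidence.
* `test_connectivity_variance()` — median-centred (Brown–Forsythe)
  Levene test of |r| dispersion across bins, via `car::leveneTest`.

Trajectory subclusters use Ward-linkage hierarchical clustering of each
pair's |r|-across-bins vector (Euclidean distance; linkage and metric are
genuinely open choices here and are recorded in the output metadata), cut at k = 3 and labelled c1..ck by ascending last-minus-first
change, matching the flat / modestly increasing / sharply increasing
taxonomy. Hubs are the top-degree CpGs in the graph keeping edges with
|r| strictly greater than 0.4 (the figure-caption wording "larger than"),
evaluated by default in the oldest bin, ties broken by summed |r|.

## Entropy and drift

Per sample and CpG, the binary Shannon entropy of the beta value,
$E(m) = -m\log_2 m - (1-m)\log_2(1-m)$, in bits, after the shared
epsilon clip. Class comparisons use per-CpG mean entropy (CpGs as
observations, two-sided rank-sum, BH across comparisons) because the
comparisons are between CpG groups; drift regressions use per-sample
mean entropy on age (samples as observations), with a set-by-age
interaction in a stacked regression for slope contrasts. Both
aggregation units are decisions of this package, chosen so that each
comparison's sampling unit matches the population it generalizes to.

## Clock circular permutation

The connectivity between a POE group and a clock CpG set is the mean
|Pearson r| over all cross pairs, excluding self-pairs (a CpG may belong
to both sets). The null rotates the group's membership mask around the
genomically ordered ring of all methylome CpGs by a uniform offset in
[1, N−1] — preserving the mask's circular run structure, which is the
operational meaning of keeping the set's internal correlation structure —
and the one-sided p is (#{null ≥ observed} + 1)/(n + 1). Offsets are
drawn with replacement; chromosomes are concatenated in sorted label
order into a single ring (per-chromosome rotation is deliberately not
offered: a single ring keeps the null exchangeable across the whole
methylome, including sets that straddle chromosome ends).
10,000 permutations is the default; scaled-down runs set
`n_permutations` in the config.

## The synthetic cohort generator

`simulate_cohort()`/`simulate_pair()` draw beta-valued cohorts with the
structure the analyses assume, and return the realized truth for
parameter-recovery tests. Its defaults are the package's study
conditions:

* **Modules.** One atypical module whose within-module correlation ramps
  from 0.15 at age 18 towards 0.30 at age 94 (implemented by scaling the
  shared-factor loading with each sample's age, so cross-sectional
  binning recovers the trend), one dense atypical module and one typical
  module at constant 0.6. Each module is one shared factor; a
  consequence documented above is that pair-level connectivity tests see
  dependent pairs, exactly as with real co-methylated blocks.
* **Planted effects.** CpG–phenotype effects with R² = 0.025 each (three
  CpGs on DNAmTL acceleration, two on intelligence, two on maternal
  smoking exposure), plus module-factor effects on the two
  age-acceleration phenotypes (variance explained 0.06 and 0.04). With
  n = 1000 per batch these are detectable at phenome-wide thresholds in
  most runs, i.e. the regime of a moderately powered EWAS.
* **Classes and entropy.** Baseline logits are drawn per class: atypical
  at ±1.2 (intermediate methylation — high entropy with room to drift),
  typical at ±2.2 (imprinting-like extremes), the bulk methylome mostly
  extreme, clock CpGs in between. Baselines shrink towards logit 0 with
  age (atypical fastest at 0.6%/year), producing class-ordered entropy
  and class-ordered drift.
* **Clock coupling.** Each of the four clocks has its own latent factor
  correlated 0.5 with a global atypical factor carried by the
  non-module atypical CpGs; typical CpGs carry no such factor, so the
  permutation test should fire for the atypical group only.
* **Covariates.** Sex, granulocyte proportion, smoking and a technical
  covariate hit a random 30% of unstructured CpGs with N(0, 0.25²)
  coefficients, so residualization has real work to do; ages are uniform
  over the configured bins; two batches are independent draws sharing
  one annotation and truth, with recorded sub-seeds.

The Gaussian latent signal maps to betas through a logistic transform
around the per-CpG baseline; because the M-value transform inverts that
map exactly, planted correlations are exact on the M scale and only
mildly attenuated on the beta scale. What the generator does *not*
emulate: genetic relatedness and POE transmission itself (POE class
labels are taken as given), probe-level technical artefacts and QC
failures, cell-type interactions with age, and non-factor co-methylation
geometries. Green tests therefore certify the statistical machinery on
data with the assumed structure, not robustness to array artefacts.

## Numerical choices and degenerate inputs

REML tolerance 1e−9 on the log-ratio scale with an exact boundary
evaluation; perfect fits (zero residual) return p = 0 rather than NaN;
rank-deficient covariate designs and collinear predictors are reported
by column name; constant CpGs abort PCA and the soft-threshold search;
bins with fewer than 3 samples are dropped from connectivity profiles
(warned below 30); single-pair CpGs yield NA in the radiated-shift table
with a warning; empty stage-1 survivor sets propagate as empty results,
not errors; module and cluster labels are assigned by deterministic
rules (size then lexicographic id; ascending slope) so all outputs are
order-invariant and byte-reproducible under a fixed seed.

## Problem sizes used in the validation suite

The acceptance tests and `scripts/acceptance.R` run at sizes chosen to
make every recovery property measurable on a desktop: 500 samples × 900
CpGs for end-to-end runs (1,000 permutations, soft power 3), 1,000
samples per batch for the 50-replicate module-recovery study, about 300
samples per age bin (sampled to equal bin sizes, avoiding differential
small-sample |r| bias across bins) for 20-replicate connectivity
recovery, 1,000 null replicates for type-I error, and 500 replicates for
drift-slope unbiasedness. These are the package's validation conditions;
analyses of real cohorts simply scale the same code.

## Known limitations

Fixed-effect residualization replaces mixed-model genetic pre-adjustment,
so family structure in real data is out of scope. The static branch cut
trades WGCNA's adaptive cluster shapes for determinism and can split or
absorb borderline modules if the cut height is moved. Pair-level
connectivity tests are descriptive under factor-structured modules (see
above). Cross-sectional age stratification cannot separate aging from
cohort or survival effects; the generator builds the age trend
cross-sectionally by design, so recovery tests validate estimation, not
the causal reading.
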