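---
title: "Genomic prediction from sequence-density marker panels: models and methods"
author: "wgsblup developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction from sequence-density marker panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`wgsblup` implements the standard workflow for whole-genome-sequence
genomic prediction of quantitative traits in a livestock cohort: marker
quality control and panel design, genomic relationship matrices (GRM),
REML variance components and heritability, GBLUP and MultiBLUP breeding
values with cross-validated accuracy and bias, genotype-imputation
accuracy metrics, and population-structure diagnostics. A synthetic-data
module generates an admixed crossbred population with known truth so that
every stage is testable without access to any proprietary cohort.

# Models

## Phenotype correction

Raw trait values are adjusted for environmental fixed effects - by default
farm, sex and slaughter batch - before any genomic analysis:
$Y_c = y - X\hat\beta + \bar{X\hat\beta}$. Restoring the grand mean keeps
$Y_c$ on the trait scale; accuracy (a correlation) and bias (a slope) are
location-invariant, so this choice is cosmetic but fixed. Two estimators of
$\hat\beta$ are offered: ordinary least squares (`fixed_only`) and
generalized least squares under a fitted animal model (`animal_model`,
the default when a GRM is available, mirroring standard animal-model
pre-correction). Only the fixed part $X\hat\beta$ is subtracted in both
cases: random animal effects are deliberately left in $Y_c$, because the
downstream mixed models re-estimate them; subtracting them here would
leak genomic information into the "phenotype".

Factors are unordered categoricals with reference-level coding - only the
fitted values matter. A rank-deficient design (confounded factors) is an
error naming the aliased levels rather than a silent drop.

## Genomic relationship matrix

With dosages $m_{ij} \in \{0,1,2\}$ counting the alternate allele and
$p_i$ its in-sample frequency, columns are centered by $2p_i$ and

$$G = \frac{MM^\top}{2\sum_i p_i(1-p_i)}$$

(the first VanRaden construction; a single shared denominator). Notes on
the numerical conventions:

* $p_i$ is the frequency of the *counted* allele, estimated from the
  non-missing dosages of the analysis set. Centering must use the counted
  allele's frequency to zero the column means; the denominator
  $p(1-p)$ is identical under allele relabeling, so this is equivalent to
  the minor-allele formulation.
* Missing dosages are mean-imputed as $2p_i$ (zero after centering),
  after QC, which keeps $G$ well defined under the $\le 10\%$ missingness
  QC admits.
* Monomorphic columns are excluded (their contribution is identically
  zero but they would inflate the marker count).
* Centering makes $G$ positive semidefinite in exact arithmetic and gives
  row sums of exactly zero; both are asserted in tests.

A per-marker standardized variant (`vanraden2`) is provided for
comparison, and GRMs can be written/read in the binary triplet layout
used by common GREML tooling.

## Variance components: AI-REML

For $y \sim N(X\beta,\; \sum_k \sigma^2_k G_k + \sigma^2_e I)$ the
restricted likelihood
$\ell_R = -\tfrac12(\log|V| + \log|X^\top V^{-1}X| + y^\top P y)$
is maximized by average-information iterations with
expectation-maximization fallback:

* the first 3 iterations are EM (robust far from the optimum), as is any
  iteration where the AI system is unusable;
* a singular or ill-conditioned AI matrix (relative condition below
  `1e-10`, e.g. on the likelihood ridge of two identical components) is
  handled by a pseudo-inverse step, which updates only the identifiable
  directions;
* negative proposals are truncated to a floor of $10^{-8}\,\mathrm{var}(y)$,
  keeping $V$ invertible while allowing effectively-zero components, and
  the fit is flagged as a boundary solution;
* convergence requires max relative parameter change $< 10^{-6}$ *and*
  log-likelihood change $< 10^{-8}$.

Standard errors come from the inverse AI matrix; heritability standard
errors by the delta method. Fixed effects inside REML default to an
intercept only, because phenotypes are pre-corrected to $Y_c$ upstream
(the two-stage convention).

Single-component fits are computed in the eigenbasis of the GRM
(rotating $y$ and $X$ once), which makes each iteration $O(n)$ after one
eigendecomposition. This is algebraically identical to the dense path -
the test suite asserts equality - and is what keeps thousand-sample REML
sweeps and cross-validation affordable on one CPU. The dense path serves
multi-component (MultiBLUP-type) models. `restricted_loglik()` is exposed
separately so that brute-force grid-search oracles in the tests share one
likelihood definition with the optimizer.

## GBLUP and MultiBLUP

GBLUP solves $y = 1\mu + Zg + e$, $g \sim N(0, G\sigma^2_g)$,
$e \sim N(0, I\sigma^2_e)$. The default solver uses Henderson's equations
premultiplied by $G$ so that no explicit $G^{-1}$ is formed - exact BLUP
projection even for singular $G$, and unphenotyped individuals get
predictions from the same joint system. The closed form
$\hat g = \sigma^2_g G Z^\top V^{-1}(y-1\hat\mu)$ is retained as an
independent cross-check; the two agree to $10^{-8}$ and both are kept so
the equivalence is continuously verified (a dual-route check, not one
library call).

MultiBLUP adds a second random genomic component, here conventionally one
GRM from INDELs ($g_f$) and one from SNPs ($g_r$), under
$V = \sigma^2_{gf}G_f + \sigma^2_{gr}G_r + \sigma^2_e I$; the total
genomic value is $\hat g_f + \hat g_r$. Nested reductions (one component
floored equals GBLUP; duplicated GRMs equal GBLUP at the summed variance)
are asserted in the acceptance tests.

## Cross-validation, accuracy, bias

`cross_validate()` performs $k$-fold CV with repetitions (defaults
$k = 5$, 5 repetitions, 25 rounds). Per repetition the ids are freshly
shuffled with seed `seed + repetition` and split into folds differing in
size by at most one. Accuracy is the Pearson correlation between $Y_c$
and GEBV in the validation fold; bias is the slope of the regression *of
$Y_c$ on GEBV* (1 = unbiased, above 1 deflated, below 1 inflated).
Variances are re-estimated within each training set by default - the
no-leakage choice - with a fixed-variance mode for faster sweeps.
`percent_increase()` implements the reporting convention
$100(\mathrm{new}-\mathrm{base})/\mathrm{base}$, two decimals.

## Imputation accuracy

Given a truth/imputed genotype pair, `impute_accuracy()` reports the
per-variant concordance rate (exact hard-call agreement among pairs with
a non-missing truth call; a missing imputed call counts as a mismatch)
and the squared Pearson correlation of dosages (undefined below 3 pairs
or at zero variance, excluded from means with counts reported), binned in
MAF windows of width 0.01 over $[0, 0.5]$ (half-open bins, last closed).
The genome-wide value is the *unweighted mean over variants* with a
defined statistic - the per-variant averaging convention - with a
call-weighted alternative also reported. MAF for binning is taken from
the truth matrix. Only hard calls are in scope; posterior dosages are not.

## Structure diagnostics

PCA is the eigendecomposition of the VanRaden GRM (numerically equivalent
to PCA of standardized genotypes and reusing the GRM module); component
signs are fixed so each component's largest-magnitude loading is positive.
IBS similarity is $\mathrm{mean}(1 - |x_i - x_j|/2)$ over shared
non-missing variants - a similarity, not a metric, so no triangle
property is asserted. LD decay bins squared dosage correlations of
intra-chromosomal pairs in 50 log-spaced distance bins by default (log
spacing resolves the short-range decay; the exact binning of the common
decay tools is not standardized). Phenotype distance is pairwise-complete
Euclidean distance over standardized traits.

# The synthetic cohort

`simulate_genotypes()` emulates the statistical features the analysis
relies on, with defaults chosen once to mirror a crossbred commercial pig
cohort:

* **Population structure** - three subpopulations (one per sire line) with
  Balding-Nichols allele-frequency divergence, default $F_{st} = 0.10$: a
  one-parameter emulation that makes PC1/PC2 separate the lines.
* **LD** - a latent equicorrelated-Gaussian threshold model per block
  (default 20 variants per block, latent correlation 0.7, blocks
  independent, 1 kb spacing, 18 autosomes). This gives controllable
  within-block $r^2$ without coalescent machinery; it does not produce
  the smooth distance-dependent decay, allele-age effects, or
  recombination hotspots of real genomes.
* **Variants** - uniform ancestral MAF spectrum on $[0.05, 0.5]$ by
  default (so QC keeps most variants); INDELs are simulated exactly like
  SNPs and only labelled differently, matching their treatment as
  ordinary biallelic markers in $G$.
* **Traits** - additive polygenic: standard-normal causal effects rescaled
  so each component's realized breeding-value variance hits its target
  *exactly in-sample* (target phenotypic variance
  $\sigma^2_e/(1-h^2_{snp}-h^2_{indel})$), which makes
  parameter-recovery tests sharp at moderate $n$. Fixed effects default
  to a 4-farm / 2-sex / 13-batch design. Traits are simulated
  independently - the real correlation structure among meat-quality
  traits is not published, so none is invented.
* **Imputation pairs** - `corrupt_genotypes()` replaces a fraction of
  entries with fresh Hardy-Weinberg draws; the `maf_weighted` mode makes
  the per-variant error rate proportional to MAF, reproducing the
  characteristic concordance drop at high MAF (common variants are
  simply harder to call correctly by chance: the HWE-match probability
  $\sum_g f_g^2$ is minimal at $p = 0.5$, where it equals 0.375).

A green test on this cohort establishes that the estimators recover the
generative parameters under an additive, block-LD, admixed world. It does
*not* establish robustness to dominance/epistasis, pedigree structure
beyond admixture, genotyping batch effects, or real LD topology - all
deliberately out of the generator's scope.

# Design decisions on open points

* **Strict QC inequalities** - call rate and MAF thresholds are exclusive
  (`> 0.9`, `> 0.01`), following the usual "higher than" phrasing of WGS
  QC; a variant exactly at a threshold is removed.
* **LD-prune determinism** - common pruning tools do not pin down
  tie-breaking. Here, within a violating pair the lower-MAF variant is
  removed; at equal MAF the later-positioned one. Pairs are scanned in
  position order, and full sliding-window passes are repeated until no
  removal occurs, so the output is a fixpoint: re-pruning it removes
  nothing. (A single pass does not guarantee this, because removals shift
  which variants share a window.)
* **Exact-count thinning as the default for density sweeps** - published
  panel sizes of `--thin`-style sweeps are near-but-not-exact
  (e.g. "1,017" for a 1K panel), indicating Bernoulli thinning; both
  modes are implemented, with exact counts preferred for reproducible
  experiments and the Bernoulli semantics kept for fidelity.
* **Per-variant averaging of imputation metrics** - the genome-wide CR/r²
  are means over variants, matching the "per SNP basis, averaged"
  convention; the call-weighted total is available behind a field.
* **Two-stage REML** - heritability is estimated on $Y_c$ with intercept
  only, not jointly with the fixed effects; the `animal_model` adjustment
  covers the case where the correction itself should account for
  relatedness.
* **Variance floor instead of parameter elimination** at the REML
  boundary: simpler, keeps the AI machinery uniform, and the boundary
  flag records which components collapsed.
* **Seeds** - every stochastic operation takes an explicit seed and uses
  an isolated RNG scope, so outputs are bit-identical given the seed and
  independent of ambient RNG state. Pipeline repetitions derive their
  seeds as `seed + repetition`.

# Known limitations

* REML and the BLUP solvers are dense ($O(n^3)$): appropriate for cohorts
  of a few thousand, not for biobank scale.
* No dominance or epistatic components; no single-step (pedigree + GRM)
  matrices; no Bayesian-alphabet models.
* Imputation itself (phasing/HMM) is out of scope - only its accuracy
  evaluation against a truth set.
* The LD generator's block structure is a stylized stand-in for real
  haplotype structure; LD-decay diagnostics on simulated data reflect the
  block span, not a recombination map.
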