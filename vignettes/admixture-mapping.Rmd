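---
title: "Admixture mapping of blood-pressure traits: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture mapping of blood-pressure traits: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

## The problem

Hispanic/Latino cohorts are admixed between three ancestral populations —
European, African and Amerindian. At any genomic segment, each of an
individual's two chromosome copies descends from one of those populations;
local ancestry inference assigns each copy an origin, summarized per
*local ancestry interval* (LAI) as a count in {0, 1, 2} of copies from each
ancestry. **Admixture mapping** regresses a trait on those counts. It
localizes trait loci whose causal alleles differ in frequency — or in
effect size — between ancestral populations, with a far smaller multiple-
testing burden than single-variant association testing (thousands of
intervals instead of millions of variants).

`admixscan` implements the full workflow for quantitative blood-pressure
(BP) traits: simulation of admixed cohorts with known truth, phenotype
preparation, mixed-model interval scans, region detection, candidate-variant
fine-mapping with conditional analysis, ancestry-specific allele-frequency
estimation, analytic power theory, and one-sided replication testing.

## The estimand

In the simplest two-ancestry setting, let a chromosome be of ancestry 1
with probability $q$, carry the effect allele with frequency $p_1$ or $p_2$
according to its ancestry, and contribute $\beta_1$ or $\beta_2$ per allele
to the trait. Enumerating the joint law of (ancestry count, genotype) under
independent chromosomes, the population regression slope of the trait on
the ancestry-1 count is

$$\beta_{\text{adm}} \;=\; \beta_1 p_1 - \beta_2 p_2,$$

which reduces to $\beta\,(p_1 - p_2)$ for a shared effect size: the causal
effect *down-weighted by the ancestral frequency difference*. Two
consequences drive the package design:

* interval-scan effect sizes are not biologically interpretable on their
  own — they mix effect size, frequency differentiation and ancestry
  frequency; and
* admixture signal can exist at *equal* frequencies when effect sizes
  differ between ancestries ($\beta_1 \ne \beta_2$), which is why the
  fine-mapping ladder does not always require frequency differentiation.

`admixture_effect()` computes the slope by exact enumeration;
`power_compare()` turns the enumerated moments into noncentrality
parameters ($\mathrm{NCP} = n\,\beta^2\,\mathrm{Var(predictor)}/
\mathrm{Var(trait\mid predictor)}$) and two-sided normal power for both the
interval test and the single-variant test. When the causal variant is
untyped and no proxy is modeled, association power is reported as zero —
the regime where admixture mapping is the only test available.

## Phenotype preparation

Four traits are analyzed: SBP, DBP, pulse pressure (PP = SBP − DBP) and
mean arterial pressure. MAP is computed as DBP + PP/3, the physiological
standard (a `map_standard = FALSE` flag gives DBP − PP/3 for comparison
with sources that print the subtraction form, which places MAP below DBP
and is treated here as a typographical variant, not a real definition).

Preparation applies, in a fixed documented order, with each dropped record
receiving the *first* failing rule as its single reason code:

1. measurement inconsistency — device summary and raw-measure mean differ
   by ≥ 5 mmHg for either SBP or DBP (either trait, inclusive bound);
2. missing outcome or covariate (including the anti-hypertensive
   medication flag);
3. implausible range — SBP < 80 or DBP < 50, read strictly as printed, so
   exactly 80/50 is retained;
4. negative PP.

Treated individuals get +10 mmHg (SBP) and +5 mmHg (DBP) before analysis,
the standard additive medication correction. PP values above
mean + 6 SD — with the statistics computed on the *post-exclusion* analysis
sample — are winsorized to exactly that limit, never dropped, so
winsorization conserves the sample size. Exclusion order, bounds and the
winsorization multiplier are all configurable (`prep_config()`), with the
values above as defaults.

## The mixed model

All tests use the linear mixed model
$$y = X\alpha + Z g + u_{\text{house}} + u_{\text{block}} + \varepsilon,$$
with fixed covariates (sex, age, center, sampling weight, five ancestry
PCs), and random effects with covariances
$\sigma^2_{\text{kin}}K$, $\sigma^2_{\text{house}}H$,
$\sigma^2_{\text{block}}B$ and $\sigma^2_e I$, where $K$ is a kinship
correlation matrix and $H$, $B$ are within-cluster indicators for
household and census block. Design choices:

* **Sampling weights enter as a fixed covariate**, not as observation
  weights — they are an adjustment against selection bias, not a
  precision weight.
* **REML by bounded quasi-Newton on the log-variance scale** with a
  deterministic start (equal split of the residual phenotypic variance)
  and box bounds at $[10^{-8}, 10^{3}]$ times the phenotypic variance.
  The optimizer tolerance is the L-BFGS-B `factr` (default `1e7`, i.e.
  ~2e-9 absolute on the criterion); the fit is exactly reproducible given
  its inputs, and `reml_loglik()` re-evaluates the criterion from the
  stored estimates to the same value.
* **Computation.** The trait covariance is held sparse; every REML
  evaluation combines the component matrices on a precomputed union
  sparsity pattern and updates a cached sparse Cholesky factorization.
  With household/block-structured cohorts this makes a 5,000-individual
  fit a few seconds on one core.
* **Variance components are estimated once per trait under the null**
  (no focal term) and reused for every interval and variant test — the
  standard mixed-model genome-scan practice. `test_fixed_effect(...,
  refit = TRUE)` re-estimates them per marker for comparison.
* **Wald statistics** are reported (effect, SE, chi-square with 1 or 2
  df), matching the effect/SE columns of the output tables; score tests
  would not supply those columns.

Degenerate inputs are handled explicitly: singular fixed designs and
collinear focal columns are errors naming the offending column (the three
ancestry counts sum to 2, so testing all of them jointly is rejected);
monomorphic intervals are emitted with `NA` and a flag rather than
dropped, so scans always have one row per interval per tested ancestry.

## Scans, regions and multiplicity

`scan_ancestry()` tests each interval's count of one ancestry against the
pooled baseline of the others (1 df); `scan_joint()` models two count
columns and tests the 2-df null that both effects vanish. The tested-
ancestry frequency is reported per interval with denominator $2n$
chromosomes. Genome-wide significance uses the admixture-mapping threshold
`5.68e-5` established for this cohort design by the autocorrelation of
local ancestry; the package takes it as a configured constant and does not
re-derive it. Significant intervals merge into regions only when strictly
adjacent — no gap of non-significant intervals is bridged, the
conservative reading when no merge rule is printed — and each region
reports its most significant (lead) interval, ties going left.
`effective_num_tests()` implements the simpleM eigenvalue rule at its
published 99.5% variance fraction for counting effectively independent
traits.

## Fine-mapping ladder, pruning, conditional analysis

Within a significant region, candidate variants are nominated by a
step-wise ladder over association p-values $10^{-6}, \dots, 10^{-2}$ from
any of three analyses (all groups, Mainland-only, Caribbean-only — effect
sizes can differ between strata). At the two most lenient rungs a variant
must also show an absolute effect-allele-frequency difference between the
analysis groups with the highest and lowest proportion of the tested
ancestry (the computable proxy for ancestral frequency differentiation),
with the required difference relaxed through 0.2, 0.15, 0.1, 0.05. The
last value follows the "at least 5%" most-lenient rule used in this
literature; a printed 0.5 in one source is inconsistent with its own
decreasing sequence and is treated as a misprint. Two genuinely open
choices are resolved as follows and exposed as flags:

* the search **stops at the first rung that admits a candidate**
  (`accumulate = TRUE` walks all rungs instead), with admission
  cumulative so that anything passing a stricter rung stays admitted;
* correlated candidates are grouped by **single-linkage connected
  components at |r| > 0.4**, keeping the smallest-p variant per component
  (ties to the smaller position) — the only reading under which the
  retained leads are pairwise weakly correlated.

`conditional_scan()` re-runs the interval scan with the lead dosages as
fixed covariates (variance components held at the null fit). The package
deliberately does **not** assert that conditional p-values exceed primary
ones — conditioning can sharpen a signal — only row alignment and
covariate bookkeeping. Because "completely/partially explained" has no
standard numeric rule, `classify_explained()` quantifies it with two
configurable cutpoints: *full* if the conditional p is no longer even
nominally significant (≥ 0.01), *partial* if attenuated above the
genome-wide level but below 0.01, *none* otherwise; raw p-values are
always reported alongside.

## Ancestry-specific allele frequencies

With unphased genotypes, an individual whose two copies have different
ancestries and genotype 1 leaves the carrying copy latent.
`estimate_ancestry_eaf()` treats local ancestry as known (point estimate),
initializes every ancestry at the pooled frequency, distributes
heterozygous alleles across ancestral copies in proportion to the current
frequency odds (E-step), re-estimates each frequency as expected allele
count over that ancestry's chromosomes (M-step), and iterates to a
log-likelihood change below 1e-8 (cap 1000 iterations). Monotone ascent
is asserted at every iteration. Imputed dosages are rounded to integers by
default (the likelihood is defined for allele counts); a flag excludes
them instead. Ancestries with zero chromosomes at the variant get `NA`.

## Replication

Replication uses one-sided p-values with the side fixed by the discovery
direction — the two directional p-values of a statistic are exact
complements — against a Bonferroni threshold `family_alpha / m`
(0.05/6 ≈ 0.008 for a six-test family). A normal reference is used for
the replication z-statistic, appropriate for large replication cohorts; a
t-reference would matter only at small n and can be applied upstream by
the caller supplying the effect and SE.

## What the simulator emulates — and what it does not

`simulate_local_ancestry()` draws each haplotype's ancestry switch-points
as a Poisson process at `generations` per Morgan and assigns tract
ancestries independently from the individual's admixture proportions,
themselves Dirichlet-distributed around the group profile (concentration
30 by default, giving realistic between-individual spread and the PC
structure the model adjusts for). Intervals are equal-width in genetic
distance, 0-based half-open in emitted tables, at a uniform 1 cM/Mb.
Genotypes are Bernoulli draws per haplotype given its local ancestry;
phenotypes add covariate effects, ancestry-specific per-allele effects,
a sibling-pair kinship effect, shared household and block effects, and
noise. Medication status follows a logistic model in latent SBP, and
treated individuals' *measured* pressures sit 10/5 mmHg below the latent
scale, so the downstream adjustment exactly recovers it. Device and raw
measurement summaries are both emitted, with a configurable fraction of
planted inconsistencies and missing flags to exercise the exclusion rules.

Deliberately **not** modeled: background linkage disequilibrium,
drift-induced frequency spread within ancestries, genuine genotype sharing
between relatives (the kinship effect is a polygenic random effect with
correlation 0.5 between siblings, not shared haplotypes), recombination
maps, and phased output for external tools. Consequently, passing tests
show that the estimators recover the generative model they target — the
down-weighted estimand, the variance components, the EM frequencies — not
that they are robust to LD structure or ancestry-inference error in real
cohorts.

Default study conditions follow the modeled cohort design: two analysis
groups contrasting Mainland-like (European/African/Amerindian expected
proportions 0.45/0.08/0.47) and Caribbean-like (0.70/0.22/0.08)
admixture; households of two with half the pairs full siblings, ten
households per block; variance components (kinship 30, household 16,
block 4, residual 130 mmHg²) giving a realistic ~13.5 mmHg SBP standard
deviation; eight generations since admixture over a 2-Morgan chromosome.

## Problem sizes used by the test suite

The suite chooses sizes that make each statistical check sharp at desk
scale: estimand recovery uses n = 5,000 with unit residual variance so the
interval-slope standard error is ~0.02 around the 0.4 target; calibration
uses 2,000 permutation replicates of the 1-df test and 1,000 of the 2-df
statistic; variance-component coverage uses 100 replicates at n = 1,500;
the end-to-end fine-mapping check uses 20 seeded replicates of a
1,200-individual cohort with a strongly differentiated planted variant
(per-allele effect 6 mmHg, frequencies 0.9 vs 0.1) so that the discovery
scan is essentially always genome-wide significant and the interesting
question is whether the ladder, pruning and conditional stages behave.

## Known limitations

* Stratified analyses are plain per-group fits; meta-analysis across
  groups is out of scope (stratified results can be supplied externally).
* Joint testing of local ancestry and genotypes is not implemented.
* The genome-wide threshold is a constant, not re-derived from the local
  ancestry autocorrelation of the data at hand.
* Local ancestry is consumed as known; uncertainty in ancestry inference
  is not propagated.
* Binary traits and group-specific residual variances are not supported.
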