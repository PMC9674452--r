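---
title: "Methods: dominant-marker and quantitative genetics of fragmented populations"
author: "fragpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-marker and quantitative genetics of fragmented populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragpop)
```

`fragpop` implements the full analysis chain used in studies of recently
fragmented plant populations that combine dominant molecular markers
(RAPD/AFLP band phenotypes) with a common-garden quantitative-genetic
experiment: within-population diversity and among-population structure from
band data, heritability/evolvability/Q~ST~ from nested family data, and
distance-based tests that separate genetic drift from diversifying
selection.  This vignette is the package's own account of the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

The package is organised as an analysis workflow: the numbered scripts under
`analysis/` are thin narrative drivers over the exported functions, so every
computation those scripts report is also unit-testable; there is no shell
wrapper beyond them.

## Dominant markers and the inbreeding phenotype model

A dominant marker shows a band unless the individual is homozygous for the
null (band-absent) allele.  With null-allele frequency $q$ and inbreeding
coefficient $F_{IS}$, band absence has probability

$$\varphi(q) = q^2 + F_{IS}\,q(1-q),$$

the Hardy–Weinberg homozygote frequency inflated by inbreeding.  $F_{IS}$ is
a plug-in parameter (default 0.643, a typical value for a strongly selfing
mixed-mating herb); estimating it from dominant data requires a separate
ABC machinery that is deliberately out of scope.  Because band counts carry
limited information about $q$ at realistic sample sizes (10–15 plants), the
estimator is Bayesian: given $x$ band-absent plants of $n$, the posterior
under a $\mathrm{Beta}(a,b)$ prior is proportional to
$\varphi(q)^x (1-\varphi(q))^{n-x} q^{a-1}(1-q)^{b-1}$, and
`estimate_null_freq()` returns its mean and variance by adaptive quadrature
(`stats::integrate`, relative tolerance $10^{-10}$; endpoint singularities
are handled by zeroing the integrand where $\varphi \in \{0,1\}$ would make
the likelihood vanish).

The nonuniform prior follows a two-pass scheme (`estimate_allele_freqs()`):
a first pass with the uniform prior produces preliminary per-locus estimates
within each population; a beta is fitted to those across loci by method of
moments (`fit_beta_prior()`, falling back to $\mathrm{Beta}(1,1)$ on
degenerate moments); a second pass re-estimates every locus under the
fitted prior.  Within one population and pass, loci sharing the same
$(x, n)$ share a posterior, so results are cached by count.

## Diversity and structure

*Nei's gene diversity* is $H_{eN} = \overline{2q(1-q)}$ over loci
(`gene_diversity()`), bounded by 0.5 for biallelic loci, and the
*percentage of polymorphic loci* counts loci with
$0.05 < q < 0.95$ (`ppl()`; the level is an argument).  Both use the
estimated allele frequency, not the raw band frequency, matching the
semantics of the classical AFLP toolchain.

*Global F~ST~* (`global_fst()`) is a variance-components ratio per locus —
the sample-size-weighted among-population variance of $q$ over
$\bar q(1-\bar q)$ — combined across loci as a ratio of sums, which keeps
near-monomorphic loci from destabilising the estimate and retains negative
per-locus numerators.  A design point deserves emphasis: the classical
correction for frequency-estimation noise subtracts the mean sampling
variance from the among-population variance.  That correction is appropriate
for unshrunken method-of-moments estimates; the posterior means used here
are already shrunken toward the fitted prior, and their among-population
variance empirically recovers the generating differentiation without
further adjustment (on simulations of the study design the subtraction
variant under-recovers a true $F_{ST}=0.08$ by more than half).
`bias_correction = "subtract"` exposes the classical correction; the
default is `"none"`.  The across-locus SD of the per-locus ratios is
reported as a dispersion measure alongside the permutation interval, since
the two answer different questions.

Significance uses label permutations (`fst_permutation_test()`):
individuals are shuffled among populations preserving sizes, frequencies
are re-estimated and the statistic recomputed; p-values use the add-one
estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$ and are never
exactly zero.  All permutation routines take explicit integer seeds.

*Pairwise F~ST~* applies the same estimator to each population pair (using
the already-estimated per-population frequencies), and *distinctness* is a
population's mean pairwise F~ST~ to all others — under drift, distinctness
rises as diversity falls.  Pairwise values can be slightly negative; the
non-negativity expected of true distances is therefore not enforced for
F~ST~ matrices.

*AMOVA* (`amova()`) partitions squared Euclidean distances between 0/1 band
profiles (mismatch counts; pairs with missing scores are rescaled to the
full locus count) into among- and within-population components with the
standard unequal-$n$ coefficient $n_0$, clamping negative among-components
to zero for reporting while retaining raw values, and tests $\Phi_{ST}$ by
the same permutation scheme.  F~ST~ from allele frequencies and
$\Phi_{ST}$ from band phenotypes are different estimators and are reported
side by side without reconciliation.

## Clone screening

Scoring error is estimated from re-scored sample × marker combinations as
the mismatch proportion over comparably scored entries
(`estimate_error_rate()`).  Two plants whose band profiles differ at no
more loci than expected from scoring error alone —
$e \times L$, rounded half up (`clone_threshold()`; half-up reproduces the
conventional "3.6 → 4") — are putative clones.  Pair mismatches count only
loci scored in both plants, and groups are connected components of the
match graph, so chained matches are well defined (`detect_clones()`).  One
random member per group is kept under a mandatory seed (`deduplicate()`).
Note the threshold sits at the *mean* of the clone-pair mismatch
distribution $\mathrm{Bin}(L, e)$, so roughly a quarter of true clone
pairs escape detection at realistic $e$; this is a property of the rule
itself, visible in the closure tests.

## Quantitative genetics under mixed mating

The common-garden model for each trait is the two-level nested random model
$y = \mu + \mathrm{pop} + \mathrm{fam(pop)} + \varepsilon$.  REML fits use
`lme4::lmer` — the standard tool for exactly this model — and a
method-of-moments solution of the nested-ANOVA expected mean squares (with
unbalanced-design coefficients, negative estimates clamped to zero) is
implemented independently as a cross-check; on balanced interior fixtures
the two coincide, and the tests assert it.

Open-pollinated seed families of a mixed-mating plant are a mixture of
selfed and full-sib progeny, so the family variance converts to additive
variance through the kinship weight
$\theta = 0.5\,s + 0.25\,(1-s)$ (`mixed_mating_theta()`; $s$ = selfing
fraction, default 0.55, giving $\theta = 0.3875$).  Derived quantities:

* heritability $h^2 = (V_{fam}/2\theta)/(V_{fam}+V_{error})$, clipped to
  $[0,1]$;
* additive genetic SD $\sqrt{V_{fam}/2\theta}$ and evolvability
  $CV_{genetic} = \sqrt{V_{fam}/2\theta}/\bar y$ (a proportion; multiply by
  100 for the conventional percentage);
* $Q_{ST} = V_{pop}/(V_{fam}/\theta + V_{pop})$.

$\theta$ is applied globally: family-level mating status is unobserved, so
a single weighted $\theta$ is the defensible choice.  Flower counts are
square-root transformed before fitting (a per-trait flag), and means are
reported on both scales.  Q~ST~ confidence intervals jackknife over
populations: delete-one refits give pseudo-values
$P\,\hat Q - (P-1)\hat Q_{(-i)}$ and a $t$-interval with
$\mathrm{df} = P - 1$ (reduced if a refit fails).  Per-population
heritability and evolvability come from one-way family fits *within* each
population — variance, residual and mean all from that population's data —
matching the within-population meaning of evolvability.

## Distance matrices and inference

Geographic distances are haversine great circles (Earth radius 6371.0 km).
Climate is reduced by PCA on standardized variables (correlation-matrix
convention, which is what reported variable–component correlations imply);
component signs are fixed by forcing the largest-magnitude loading
positive, and climatic distances are Euclidean on the retained scores.
Quantitative distances are Mahalanobis distances between population mean
vectors of family-mean traits, under the df-weighted pooled
within-population covariance of family means — family means because the
population signal under test lives above the family level, pooled within
populations because between-population separation is the signal itself.
Distances are reported as $D$ (not $D^2$; a flag exposes $D^2$), and the
construction is invariant to invertible affine trait rescaling, which the
tests verify.

Isolation by distance (`ibd_test()`) correlates the off-diagonal entries of
two distance matrices and permutes under one of two modes: `"pairwise"`
shuffles the response pairs directly — replicating the classical use of raw
pairs, which ignores the dependence of pairs sharing a population — while
`"matrix"` permutes population labels jointly over rows and columns
(Mantel-style) and is the recommended mode when that dependence matters.
`sequential_perm_regression()` fits the response pairs on predictors in a
stated order and reports sequential (type-I) sums of squares, so each term
is adjusted only for those before it; per-term significance is the add-one
proportion of permuted sequential $F$ statistics at or above the observed
one.  The sequential SS sum to the total model SS whatever the order; the
per-term split depends on the order, deliberately.

`compare_qst_fst()` renders one verdict per trait from interval overlap:
divergent if the Q~ST~ CI lies entirely above the F~ST~ interval,
stabilizing if entirely below, drift-consistent otherwise.  The F~ST~
interval is a convention — the 2.5–97.5% quantiles of the permutation null
re-centred on the estimate — since no standard definition exists for the
dashed-line intervals such comparisons are usually drawn with.  No
multiple-testing correction is applied by default, matching the field's
practice for these few planned tests.

## The synthetic-data generator

The generator exists so that every stage is testable end to end without any
external download, with defaults that mirror the study design the analyses
assume: 19 populations × 13 individuals × 52 dominant loci, target
$F_{ST} = 0.08$, $F_{IS} = 0.643$, scoring error 6.6%, 3 clone pairs,
~20% replicate re-scoring; 14 families per population averaging 5.7 plants;
sites in a ~30 km × 60 km box with ten bioclimatic variables driven by two
latent gradients (so two principal components dominate); log-normal census
sizes spanning a few plants to tens of thousands.

Population allele frequencies follow the Balding–Nichols model
$q_{pl} \sim \mathrm{Beta}(\bar q_l (1-F)/F,\ (1-\bar q_l)(1-F)/F)$ with
ancestral $\bar q_l \sim \mathrm{Beta}(2, 2)$ — chosen once as a
high-diversity spectrum appropriate for polymorphic band positions.
Genotype scores flip with a per-scoring probability $\epsilon$ solved from
$2\epsilon(1-\epsilon) = e$, so the announced error rate *is* the
replicate-disagreement rate (what an error experiment measures and the rate
at which clone-pair scores mismatch).  Clones are injected before scoring
error and placed within 1 m on the transect.  Trait variance-component
defaults put each trait near $h^2 \approx 0.4$ and $Q_{ST} \approx 0.08$ —
differentiation at the molecular level, i.e. a drift-consistent world —
with an optional climate-coupling coefficient that shifts population means
along the longitude gradient to create quantitative isolation by distance.
Flower counts are generated on the square-root scale and back-transformed,
keeping the variance model exact on the analysis scale.

What the generator does **not** emulate: linkage between loci, within-
population spatial genetic structure along the transect, population-
specific drift intensities (all populations share one $F$, so the
empirical coupling of distinctness with reduced diversity seen in real
fragmented systems is absent), missing marker scores, germination and
early-mortality selection in the garden, and genotype-by-environment
interaction.  Passing recovery tests on this generator therefore shows the
estimators are consistent under the stated model, not that real data meet
that model.

## Numerical choices and test scale

Tolerances and conventions, in one place: posterior integrals at relative
tolerance $10^{-10}$ with a $10^4$-cell midpoint-grid oracle in the tests
(agreement to $10^{-4}$); REML vs expected-mean-squares agreement asserted
to $10^{-3}$ on balanced fixtures; clone threshold rounds half up; negative
variance components clamp to zero for reporting with raw values retained;
PCA signs fixed by the largest loading; permutation p-values use the
add-one estimator; every stochastic routine takes an explicit seed and the
generators are pure functions of configuration plus seed.

The simulation-based checks run at deliberately chosen sizes: F~ST~
recovery at the full study design over 20 seeds (median within ±0.03 of
truth), Q~ST~ recovery at truth 0.5 over 20 seeds (±0.1), jackknife
coverage over 25 seeds (≥80%), IBD power at coupling 1.0 over 25 seeds
(≥80% at p < 0.05) and null calibration over 30 seeds — sizes at which the
asserted medians and rates are stable while a full suite run stays in the
minutes range.

## Known limitations

$F_{IS}$ and the selfing fraction are plug-ins, not estimates; errors in
them propagate multiplicatively into $H_{eN}$, $h^2$ and $Q_{ST}$.  The
Bayesian frequency estimator is biased toward the prior mean at small $n$,
inflating $H_{eN}$ and PPL somewhat on weakly informative data (visible on
synthetic data; the ranking across populations is preserved).  The pairwise
permutation mode inherits the non-independence of population pairs, which
is why the matrix mode exists.  Outlier-locus detection and hierarchical
(region/population) AMOVA are out of scope; non-neutral loci enter only as
an exclusion list.
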