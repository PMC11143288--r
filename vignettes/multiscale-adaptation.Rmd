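---
title: "Methods: multi-scale local adaptation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale local adaptation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscape)
```

adaptscape asks one question at two scales: does performance in a
common-garden experiment depend on where a plant came from?  Between
taxa, the answer is adaptive divergence; among populations within a
taxon, it is local adaptation.  This vignette documents the models, the
synthetic-data generator, the tunable parameters, and the numerical
conventions, in enough detail that every number the package produces is
reproducible from this description.

## The divergence model

For each fitness trait the package fits

```
trait ~ taxon * garden + (1 | population) + (1 | population:genotype)
```

with a binomial-logit family for binary traits (herbivory escape,
survival), Poisson-log for counts (flowers, fruits), and a Gaussian
linear mixed model on the natural log of biomass.  Estimation is
Laplace-approximate maximum likelihood for the GLMMs and REML for the
Gaussian path (via `lme4`; the method is recorded in the fit metadata).
Clonal replicates of a genotype — the rare taxon is planted twice per
garden to boost its sample size — are absorbed by the genotype-level
intercept rather than modeled separately; with only two replicates per
genotype per garden there is no information to separate a
replicate-level variance from the residual.

The evidence for adaptive divergence is (i) a Wald chi-square test of
the joint taxon-by-garden coefficient block, Type II by default
(`test_interaction()`; Type III is selectable — with treatment contrasts
the two differ for the main effects, and the package does not guess
which convention downstream users prefer), and (ii) linear contrasts
among the taxon-by-garden cell means on the link scale
(`cell_mean_contrasts()`).  The contrast sign convention is pinned so
that positive = the pattern predicted by adaptation: local minus foreign
within a garden, home minus away within a taxon.  The contrast set is
adjusted with the single-step method over its joint normal distribution
(`multcomp`), falling back to Holm if the joint covariance is unusable;
the method used is recorded on the result.  Because binary traits can
produce complete separation in a taxon-by-garden cell (e.g. every local
plant surviving), cells with a constant response are detected before
fitting and listed in `separation_cells` — the fit proceeds, flagged,
rather than failing silently.

## Population effects and provenance regressions

Within a taxon, `extract_population_effects()` fits the intercept-only
model with random intercepts for garden and for population nested in
garden, and returns the conditional modes (BLUPs) of the nested term:
the estimated average effect, on the link scale, of coming from each
population in each garden.  The default is one model per species with
gardens nested (the formula as stated); a `per_garden` mode fitting one
model per garden is provided because per-garden effects are how
provenance results are usually displayed, and the two parameterizations
are not identical.  A trait with no variation within a species (every
plant survived, say) cannot support population effects; the function
returns a structured `insufficient_variation` result instead of erroring,
and the pipeline logs it.

`provenance_regression()` is ordinary least squares of those effects on
one of three distances, with the model F-test p-value and R²
(algebraically the squared Pearson correlation, which the tests verify).
The local-adaptation flag is `slope < 0 & p < alpha` with `alpha = 0.05`
by default.  Two caveats are inherent to the design and worth stating:
conditional modes are shrunken toward zero, so recovered distance-decay
slopes are biased toward zero by the shrinkage factor (about 15–20% at
the default design, which the acceptance checks quantify); and the
per-garden regressions use as many points as there are populations, so
single-garden p-values are low-resolution.

### Distances

* **Geographic**: the Haversine great-circle distance, default sphere
  radius 6378.137 km (the WGS84 equatorial radius, the default of common
  geodesy libraries), overridable to the mean radius 6371.0088 km.
* **Environmental**: both sites are projected with the stored centering,
  scaling and eigenvectors of the environmental PCA and the Euclidean
  distance is taken over PC1/PC2 only.  The distance is invariant to
  eigenvector sign flips.
* **Genetic**: Weir–Cockerham θ between the source population and the
  garden-adjacent population *of the same taxon* (genetic distance to a
  conspecific reference is the quantity that makes sense in a provenance
  design; the reference defaults to the nearest same-taxon population to
  the garden and can be overridden).

### The F_ST estimator

`wc_fst()` implements the 1984 variance-components estimator for
biallelic diploid loci directly from sample sizes, allele frequencies
and observed heterozygosity: per locus the components a (among
populations), b (among individuals within populations) and c (within
individuals), with the multi-locus estimate as the ratio of sums
Σa / Σ(a+b+c) — the standard multi-locus convention for this estimator
family.  Loci with an undefined or non-positive denominator
(monomorphic across both populations, or fewer than two usable
individuals) are excluded and counted.  Negative per-locus and
multi-locus estimates are retained as-is; they are part of the
estimator's sampling distribution and clipping them would bias means of
θ across pairs.  The implementation is checked to 1e-10 against an
independently coded oracle that recovers the same components through
the nested random-effects ANOVA (gametes in individuals in populations)
from which the estimator is derived, and against parameter recovery on
Balding–Nichols simulations.

## Niche comparison

`fit_env_pca()` is a correlation-matrix PCA (each variable centered and
scaled to unit variance).  Before it, `filter_collinear()` greedily
removes collinear variables: while any pair has |r| at or above the
threshold (default 0.8), the member of the worst pair with the larger
mean absolute correlation to everything else is dropped; constant
columns are dropped first with a warning since their correlation is
undefined.  Retained names come back in input order.

`permutation_niche_test()` compares the observed absolute
between-species difference in median and in breadth (95th minus 5th
percentile) along each axis with a null built from the pooled records.
The default null is a label permutation — group sizes fixed, points
reassigned without replacement — because the hypothesis being tested is
exchangeability of the pooled occurrence points; a bootstrap mode
(resampling each pseudo-group with replacement) is provided for users
who prefer the resampled variant, and the mode is recorded in the
output.  P-values use the add-one rule `(1 + #{null ≥ obs}) / (1 +
n_perm)`, which cannot return zero from a finite number of permutations.

## Selection gradients and reconstitution

Leaf traits enter as length, width, length/width ratio, area,
chlorophyll and SLA (= area cm² / dry mass g; `derive_leaf_traits()`
computes the two derived traits exactly).  `fit_trait_pca()` is again a
correlation-matrix PCA.  Relative fitness is `w / mean(w)` over the
analyzed set.  The coefficient vector **A** comes from a multiple
regression of relative fitness on the first k z-transformed PC scores
(k = 3 by default for reconstitution, 2 for the per-axis scope models),
and the reconstituted trait-space gradient is the exact matrix product
**β = E·A**.  Conventions that matter for reproducing any specific β:

* Scores are z-transformed (mean 0, SD 1) before the A regression; the
  removed SDs are stored so the scaling can be undone, and every result
  records whether its coefficients refer to scaled or raw scores.  At
  full rank with *raw* scores, β equals the direct OLS gradient of
  relative fitness on the unit-variance traits — an identity the test
  suite verifies to 1e-8, and the reason the z-convention must be
  explicit.
* When the analysis is subset to one taxon, the default order is
  subset-then-transform: scores are re-standardized and fitness
  re-normalized within the subset (`rescale = FALSE` gives the other
  order).  Normalizing within the analyzed subset makes within-taxon
  gradients comparable across taxa of different mean fitness.
* Eigenvector signs are fixed by making each component's
  largest-magnitude loading positive; β is invariant to paired sign
  flips of an eigenvector and its coefficient, so this choice only
  stabilizes output across platforms.

`compare_scales()` reports, per trait, the pooled-taxa and within-taxon
β, sign agreement, absolute difference, and the angle between the two
β vectors — the one-number summary of whether selection acts along the
same axis at both scales.  Selection models are linear only: directional
gradients, no quadratic or correlational terms.

## What the synthetic-data generator emulates

`simulation_params()` defaults encode the reference design: three
gardens within ~120 km of each other, three taxa with 8/3/9 source
populations and 122/37/125 genotypes spanning ~900 km, every genotype
cloned into every garden, the rare taxon twice per garden (321 plants
per garden), five fitness traits with binomial/Poisson/log-normal
responses from a shared linear predictor, and ~5 sequenced individuals
per population.

* **Transplant**: η = μ(trait) + taxon + garden + taxon:garden + pop +
  genotype, with pop = −b·d(pop, garden) + N(0, σ_pop), d the Haversine
  distance in km.  Defaults: local advantage 1 on the link scale (the
  order of the significant contrasts a reciprocal transplant of this
  size reports), b = 0.001 per km (a fitness-unit per 1000 km, the
  magnitude at which biomass declines about a milligram per kilometer),
  σ_pop = σ_genotype = 0.2, σ_resid = 0.4.
* **Genotypes**: Balding–Nichols — ancestral p ~ U(0.1, 0.9), population
  frequency ~ Beta(p(1−F)/F, (1−p)(1−F)/F), genotypes Binomial(2, ·);
  the expected θ among populations is F, which is what makes estimator
  recovery testable.  F = 1 is rejected (degenerate Beta).  No linkage:
  loci are independent.
* **Traits and fitness**: a two-axis latent landscape.  Axis 1 separates
  the taxa (taxon means −1.2 / −0.8 / +1.2, within-taxon SD 0.5) and
  loads on the shape traits; axis 2 is standard normal within every
  taxon and loads on the size traits.  The loadings matrix must have
  orthogonal columns (a warning, not an error, otherwise) and its ratio
  row must equal length − width on the log scale, because the ratio is
  derived exactly.  Fitness is log-linear with γ1 on the *taxon-typical*
  value of axis 1 and γ2 on axis 2 — each axis under selection at its
  own scale.  Residual axis-1 variation within a taxon is therefore
  selectively neutral, which is what makes the within-taxon PC1 slope a
  true null.  Defaults γ1 = 0.6 (≈3–4-fold fitness differentials
  between the extreme taxa, the order reciprocal transplants report)
  and γ2 = 0.25 (moderate, field-typical directional selection).  For
  the dedicated orthogonal-landscape checks the scenario is sharpened to
  γ1 = 0.8, γ2 = 0.25: for the two scales to exhibit *distinct* axes the
  between-scale response must dominate the axis-2 response that both
  scopes share — γ1·sd(taxon means) must clearly exceed γ2 — and this
  scenario is fixed once from that geometric requirement.
* **Geography and environment**: population coordinates are uniform in
  per-taxon bounding boxes; site environmental vectors are a smooth
  deterministic lat/lon gradient, so environmental distance co-varies
  with geographic distance as in field data and a site co-located with
  a garden has environmental distance exactly zero.
* **Reproducibility**: every generator seeds its own substream derived
  from the master seed, so changing, say, the number of loci never
  perturbs the transplant draw, and identical parameters give
  bit-identical outputs.

What the generator does **not** emulate — and what passing tests
therefore do not establish about field data: within-garden spatial
structure (plot effects), overdispersion or zero-inflation in the count
traits, linkage among loci, genotype-by-environment interactions below
the taxon level, measurement error in the leaf traits, and any
correlation between the latent trait axes and the provenance distance
effect.  Calibration and recovery results here say the estimators are
correct under their assumed models, not that field data meet those
assumptions.

## Numerical conventions and degenerate inputs

* Quantiles use linear interpolation between order statistics (R type
  7), recorded in the niche outputs.
* Permutation p-values use the add-one rule; they lie in (0, 1].
* PCA eigenvector signs: largest-magnitude loading positive.
* Earth radius 6378.137 km by default, overridable.
* Monomorphic loci: excluded from θ and counted.  Negative θ retained.
* Zero-variance traits: error in PCA (naming the variable), structured
  flag in population-effect extraction.
* Non-convergent mixed models: flagged on the fit and warned about at
  test/contrast time, never silent.
* All-equal distances in a provenance regression: error (no design
  variation), as is a regression with fewer than 3 points.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run everything at sizes chosen
to make Monte-Carlo error small relative to the tolerances they assert:
θ recovery at 5000 loci and 2×25 diploids (±0.02 around F), permutation
calibration at 500 null replicates of n = 50 + 50 with 200 permutations
(rejection rate within [0.03, 0.07] at α = 0.05), interaction-test size
at 300 null replicates of the full 3×321 design, contrast power at 20
replicates of the injected +1 advantage, provenance recovery at 50
replicates (mean slope within 30% of −0.001/km), and the two-scale
angle at 50 replicates of the orthogonal landscape (above 60° in at
least 90%).

## Known limitations

GLMM inference is Wald-based; likelihood-ratio or parametric-bootstrap
tests are not provided.  The F_ST estimator is pairwise only.  Count
models have no overdispersion term, so real fruit/flower counts with
extra-Poisson variance will show anticonservative interaction tests —
check residuals before trusting the χ² scale on field data.  The niche
test treats occurrence points as exchangeable and ignores spatial
autocorrelation; thinning records before testing is the user's
responsibility.  Field datasets in the documented shapes can be run
through the same entry points (`read_genotypes()`, the CSV readers in
`run_pipeline()`), but no field data ship with the package.
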