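---
title: "Methods: association strength, shoal configurations and Tweedie foraging models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association strength, shoal configurations and Tweedie foraging models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mixshoal` analyses mixed-species shoaling in assemblages where native and
range-extending (tropicalizing) fishes meet: which species shoal together
more often than chance, how shoal size depends on the biogeographic mix of
a shoal, and whether individuals forage faster in larger or mixed groups.
This vignette documents the statistical machinery, the choices behind it,
and what the synthetic-data generator can and cannot stand in for.

## Pairwise association strength

Shoal surveys are reduced to a binary species-by-shoal presence–absence
matrix. For each unordered species pair we count the shoals containing
both, `O`, and standardize it against a null model that keeps each
species' total number of occurrences (row totals) fixed while assigning
those occurrences to shoals uniformly at random, independently across
species. Column totals are deliberately left free, so shoals can gain or
lose species — including becoming empty — under the null; this is the
operational definition behind the index and it matters for the null
standard deviation. The association strength is the standardized effect
size (SES)

\[
\alpha = \frac{O - \mu}{\sigma},
\]

with `mu` and `sigma` the mean and SD of `O` under the null. Positive
values mean the pair co-occurs more often than chance (association),
negative values avoidance, zero neutrality.

Two routes to the null moments are provided and cross-checked against each
other:

* **Monte Carlo** (`method = "montecarlo"`, default 1000 null matrices,
  matching standard practice): moments are the empirical mean and SD of
  `O` across randomized matrices.
* **Analytic** (`method = "analytic"`): under this null the overlap of two
  rows with totals `r_a`, `r_b` over `n` shoals is hypergeometric, so
  `mu = r_a r_b / n` and
  `sigma^2 = r_a r_b (n - r_a)(n - r_b) / (n^2 (n - 1))` exactly. This is
  both a fast substitute and the oracle the Monte-Carlo engine is tested
  against.

Pairs with `sigma = 0` (a species present in every shoal or none) are
flagged `degenerate` and get `NA` rather than an infinite index. The SES
interpretation relies on the null being correct, not on any distributional
assumption about the data.

## Shoal configurations

Each shoal is classified by the origin of its members (`native_only`,
`range_extending_only`, `mixed_origin`) and by richness (`mono_specific`
vs `multi_specific`); a mixed-origin shoal is necessarily multi-specific.
Whether the two single-origin groups differ in their propensity to form
multi-specific shoals is tested on the 2×2 table of origin × shoal type
(built by `multispecific_origin_table()`, which excludes mixed-origin
shoals by construction — the table-construction rule is exposed as a
function precisely because the choice of denominator is a modelling
decision, not a fact of the data). The exact test uses probability
ordering for its two-sided p-value and reports the conditional-MLE odds
ratio with a test-inversion CI — the dominant convention — alongside the
sample cross-product ratio.

Shoal size is right-skewed, so the size model is ordinary least squares on
`log(shoal_size)` with the three-level configuration factor as the only
fixed term. Random location and observer terms are deliberately absent:
for these data they explain negligible variance, and the reduced fixed-
effects model is the final model of record; the AIC of the richer
configuration × type model is reported alongside for transparency. All
three pairwise contrasts are Tukey-adjusted (studentized range), and a
compact letter display is built greedily from the largest mean, ties
broken alphabetically.

## Foraging rates: Tweedie GLM by IRLS

Per-minute bite and bout rates are non-negative with exact zeros, which
rules out gamma and log-normal models. We use the Tweedie family with
power index `1 < p < 2` — a compound-Poisson–gamma law with variance
`phi * mu^p` and positive mass at zero — fitted by iteratively reweighted
least squares with a log link: working weights `mu^(2-p)`, Pearson-based
dispersion, covariance `phi (X'WX)^(-1)`. The canonical model is

```
bite_rate ~ origin * shoal_size * shoal_type + length_cm
```

with reference levels `range_extending` and `mono_specific`, so ratios for
natives land below 1 when natives forage more slowly. Species identity can
be added as a fixed covariate (`species_term = TRUE`); random effects are
intentionally out of scope — the fixed-effects approximation is documented
in the output metadata and is the package's deliberate simplification of
the original mixed-model formulation.

The power index defaults to 1.5, the midpoint of the compound-Poisson
range, because bite-rate data rarely pin it down; `profile_power()` scores
a grid of candidate `p` by extended quasi-likelihood
(`sum d_i / phi + sum log(2 pi phi max(y_i, eps)^p)`, with `eps = 1e-6`
guarding exact zeros) when an estimate is wanted. Convergence is declared
when the relative deviance change drops below `1e-8` (default), which for
these models takes well under the 100-iteration cap; a non-converged fit
is returned with a warning rather than an error.

From a fitted three-way model, `group_slopes_and_contrasts()` derives the
shoal-size slope of each origin × type cell as a linear combination of
coefficients (built numerically from model-matrix differences, so it is
robust to term ordering), all pairwise slope differences, and between-cell
rate ratios at a reference shoal size (default 3, about the smallest
groups encountered). Standard errors come from the delta method; p-values
are adjusted over the four-cell family by the studentized-range method,
the same adjustment as the size-model contrasts.

## The synthetic-data generator

The generator exists so every stage can be validated against known ground
truth without the field dataset.

**Shoal assembly.** Compositions are drawn from a log-linear model over
non-empty species subsets:
`P(x) proportional to exp(sum_i theta_i x_i + sum_{i<j} theta_ij x_i x_j)`.
With at most 15 species the distribution is enumerated exactly
(`composition_distribution()`), which is the oracle the sampler is tested
against. Shoal sizes are log-normal per origin configuration, rounded,
floored at the number of member species (and 2) and capped at 50, so
generated data never trip the analysis filters; individuals are allocated
to member species by a symmetric multinomial — a modelling choice, since
no within-shoal abundance law is available to copy. Default parameters
were calibrated once, through the exact composition distribution, to the
field pattern: ~30% native-only, ~43% range-extending-only, ~27% mixed
shoals, native–native multi-specific shoals rare (~2.5%), rabbitfish
pairs attractive and the remaining pairs avoidant, native-only shoals
drawn smaller than the rest.

**A caveat that matters for calibration tests.** Conditioning compositions
on being non-empty couples the species: with empty-subset mass `q`, two
otherwise-independent species acquire covariance
`-p_a p_b q / (1-q)^2`. At field-like occupancies this is large enough to
drag every pairwise SES strongly negative even with all affinities zero —
a property of the generator, not a bug in the index. SES-calibration
checks therefore run at high occupancy (`theta_single = 2.5`, occupancy
~0.92, `q ~ 3e-5`), where presences are independent to well within the
tolerance of the checks and the index is verifiably mean-0, variance-1.

**Foraging.** Expected rates follow the same three-way linear predictor
the model fits, with default coefficients chosen to reproduce the field
pattern: per-individual slopes 0.017 / 0.015 (range-extending mono/multi)
and 0.021 / −0.008 (native mono/multi), length effect −0.020 per cm, and
origin contrasts placing native rates at 65.1% (mono) and 72.9% (multi) of
range-extenders' at shoal size 3. Realized rates are drawn from the exact
compound-Poisson–gamma sampler (`rtweedie()`: Poisson number of gamma
jumps — no density evaluation, exact for `1 < p < 2`), converted to integer
bite counts over a uniform 30–120 s observation window, and thinned
binomially into bouts with origin-specific fractions (0.24 native, 0.15
range-extending) so both origins average ~5 bouts/min while bite rates
differ — mirroring the field contrast. Dispersion defaults to
`phi = 1.5` at `p = 1.5`, giving a bite-rate SD of ~15 at a mean of 30,
the right order for individual foraging data.

What the generator does **not** emulate: spatial structure and
location-level heterogeneity (locations are cycled, not modelled),
observer effects, fission–fusion dynamics within an observation,
correlation between a shoal's composition and the foraging rates of its
members, and within-shoal abundance structure beyond the symmetric
multinomial. Passing tests on synthetic data therefore validate the
estimators and their calibration under the stated model, not the field
conclusions themselves.

## Numerical choices and degenerate inputs

* Filters are strict inequalities for duration (> 20 s) and length
  (> 10 cm) and inclusive for the shoal-size cap (<= 50), following the
  wording of the study protocol; each dropped record carries exactly one
  primary reason, checked in the order duration, length, size.
* Exact-test probability ties use the customary `1e-7` relative
  tolerance, so floating-point-equal tables count as ties.
* Fisher with a zero margin: p is returned (1), the odds ratio is
  flagged undefined. Chi-squared with a zero margin is an error.
* The IRLS start is `mu = (y + mean(y))/2`, strictly positive even with
  zero responses; zero rates are retained throughout (the Tweedie zero
  mass is the point of the family), never dropped or offset.
* Shoal size enters the predictor untransformed (slopes are per added
  individual); it is not centred.
* All Monte-Carlo stages take explicit seeds and are bit-reproducible;
  the pipeline derives fixed per-stage offsets from one root seed.

## Problem sizes used in the validation suite

The shipped checks run, on one CPU in a few minutes: the Monte-Carlo
engine against the closed form on 50 random matrices (4–8 species ×
20–100 shoals, 10,000 nulls each); SES calibration on 1000 replicate
surveys of 250 shoals; exact-test agreement with full enumeration on all
135,750 tables with total ≤ 40; coefficient recovery on 1000 replicates
of n = 2000 foraging observations; and familywise-error calibration of
the Tukey contrasts on 1000 simulated size datasets. Replicate counts
were set so that each check's tolerance sits several standard errors from
the property it verifies.

## Known limitations

* Random-effect structures (location, observer, species identity) are not
  estimated anywhere; this is a fixed-effects package by design.
* The Tweedie fit is quasi-likelihood: no exact density, hence no exact
  AIC and no simulated-residual diagnostics; `profile_power()` uses
  extended quasi-likelihood, adequate for choosing `p` but not a true
  likelihood profile.
* The association index is pairwise only; community-level co-occurrence
  metrics are out of scope.
* With very common or very rare species the null SD shrinks and the SES
  becomes coarse (the overlap distribution is discrete); degenerate pairs
  are flagged rather than interpreted.
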