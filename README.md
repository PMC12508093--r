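# mixshoal

Tools for analysing **mixed-species shoaling** in reef fish assemblages
where native species meet range-extending (tropicalizing) ones — e.g.
Mediterranean rocky reefs where the native herbivores *Sarpa salpa* and
*Sparisoma cretense* co-occur with the Lessepsian rabbitfishes *Siganus
luridus* and *S. rivulatus*. The package answers three questions from
shoal-composition surveys and focal-individual foraging observations:

1. **Which species associate?** Shoal surveys become a binary
   species × shoal presence–absence matrix; each pair's co-occurrence
   count *O* is standardized against a null model that fixes each
   species' occurrence total and places it uniformly across shoals
   (columns free). The association strength is the standardized effect
   size

   *α* = (*O* − *μ*) / *σ*,

   with *μ*, *σ* the null mean and SD of *O* — estimated by Monte Carlo
   (default 1000 null matrices) or taken from the exact hypergeometric
   closed form (*μ* = *r*<sub>a</sub>*r*<sub>b</sub>/*n*,
   *σ*² = *r*<sub>a</sub>*r*<sub>b</sub>(*n*−*r*<sub>a</sub>)(*n*−*r*<sub>b</sub>)/(*n*²(*n*−1))).
   Positive *α* = association, negative = avoidance.

2. **How do shoal configurations differ?** Shoals are classified by
   member origin (native-only / range-extending-only / mixed) and
   richness (mono-/multi-specific); frequencies, exact and χ² 2×2 tests
   of same-origin multi-specific shoaling, and a log-scale shoal-size
   model with Tukey-adjusted contrasts and compact letter display.

3. **Who gains foraging benefits?** Per-minute bite and bout rates —
   non-negative with exact zeros — are modelled with a **Tweedie GLM**
   (variance *φμ*<sup>*p*</sup>, 1 < *p* < 2, log link) fitted by
   iteratively reweighted least squares, with the three-way
   `origin × shoal_size × shoal_type` interaction plus body length.
   Per-cell shoal-size slopes, slope contrasts and between-origin rate
   ratios at small shoal size come with delta-method SEs and
   studentized-range (Tukey) adjusted p-values.

A synthetic-data generator — a log-linear pairwise-affinity assembly
model with an exactly enumerable composition distribution, and an exact
compound-Poisson–gamma rate sampler — gives every stage a ground-truth
test bed. See the methods vignette
(`vignettes/mixed-species-shoaling.Rmd`) for the statistical details.

## Worked example

```r
library(mixshoal)
cat4 <- default_catalog()   # the four study species with their origins

# --- shoal surveys -> association strengths -------------------------
shoals <- simulate_shoals(assembly_params(cat4), n_shoals = 250, seed = 42)
m      <- build_presence_matrix(shoals, cat4)
association_strength(m, n_null = 1000, seed = 42)
#>            species_a          species_b observed null_mean null_sd  alpha
#> 1        Sarpa_salpa Sparisoma_cretense       10      18.9    3.06 -2.904
#> 2        Sarpa_salpa    Siganus_luridus       20      44.5    3.76 -6.519
#> 3 Sparisoma_cretense    Siganus_luridus        2      20.7    3.05 -6.132
#> 4        Sarpa_salpa  Siganus_rivulatus       49      46.1    3.85  0.752
#> 5 Sparisoma_cretense  Siganus_rivulatus        8      21.5    3.03 -4.437
#> 6    Siganus_luridus  Siganus_rivulatus       45      50.3    3.98 -1.340
```

*S. rivulatus*–*S. salpa* co-occur more often than chance (α > 0); the
parrotfish avoids everyone (strongly negative α).

```r
# --- configurations and shoal size -----------------------------------
cls <- classify_shoals(shoals, cat4)
configuration_frequencies(cls)$by_origin
#>          origin_config   n  pct
#> 1          native_only  71 28.4
#> 2 range_extending_only 112 44.8
#> 3         mixed_origin  67 26.8

fit_shoal_size_model(cls)
#>         origin_config   n log_mean mean_size letters
#>           native_only  71    1.340     3.818       b
#>  range_extending_only 112    2.008     7.450       a
#>          mixed_origin  67    2.103     8.189       a
```

Native-only shoals are significantly smaller (letter *b*) than
range-extending or mixed shoals.

```r
# --- foraging rates ---------------------------------------------------
forage <- simulate_foraging(foraging_sim_params(catalog = cat4),
                            n = 294, seed = 42)
kept <- filter_foraging_records(forage)$kept   # >20 s, >10 cm, shoals <= 50
dat  <- prepare_foraging_data(kept, cat4)
bite <- fit_tweedie_glm(dat, foraging_formula("bite_rate"), power = 1.5)
gsc  <- group_slopes_and_contrasts(bite, at_shoal_size = 3)
gsc$rate_ratios[, c("contrast", "ratio", "p_adj")]
#>                                                  contrast ratio    p_adj
#> 1     range_extending.mono_specific - native.mono_specific 1.669 5.92e-05
#> ...
#> 4    native.mono_specific - range_extending.multi_specific 0.683 1.96e-03
```

At shoal size ~3, range-extenders in mono-specific shoals bite ~1.7×
faster than natives in mono-specific shoals (equivalently, natives run
at ~60% of the range-extenders' rate in this simulated draw).

The whole analysis — classification, tests, associations, foraging fits,
contrasts, manifest — also runs as one call:

```r
bundle <- run_full_pipeline(pipeline_config(simulate = TRUE, seed = 42),
                            out_dir = "out")
```

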