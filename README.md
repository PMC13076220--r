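# isoniche

Trophic-niche statistics for soil animal communities from paired stable
isotope values (δ¹³C, δ¹⁵N), with mixed-model effect sizes for land-use and
climate comparisons.

In consumer tissue, δ¹³C reflects the basal resource and δ¹⁵N the trophic
level, so the spread of a community's samples in the δ¹³C–δ¹⁵N plane
measures its **trophic diversity**. `isoniche` is for ecologists analysing
multi-site isotope compilations of soil fauna (springtails, mites,
earthworms, spiders, ...) who want reproducible, tested versions of the
standard measurement chain:

* **Niche area.** For each site × functional group (and each taxon within
  it) with ≥ 5 samples, the standard ellipse area
  `SEA = π √det(Σ)` of the 1-SD covariance ellipse, with the small-sample
  correction `SEAc = SEA (n−1)/(n−2)`.
* **Expansion vs partitioning.** Group-level diversity is decomposed into
  within-taxon niche breadth (mean taxon SEAc) and between-taxon centroid
  separation (mean pairwise centroid distance, the trophic dissimilarity).
* **Effect sizes.** Linear mixed models on log SEAc / log dissimilarity
  with a site random intercept; estimated-marginal-mean contrasts
  (agriculture − woodland, tropical − temperate) back-transformed to
  percent effects `100(e^β − 1)` with delta-method SEs.
* **Diagnostics.** Permutation Moran's I on site-level residuals with
  5-nearest-neighbour great-circle weights.
* **Synthetic communities.** A seeded generator with analytic ground truth
  (`π √det(τ²I + Σ_w)`) whose knobs separately control expansion (Σ_w),
  partitioning (τ²), treatment multipliers α and site effects — so every
  stage of the pipeline is testable end to end.

## Worked example

Simulate a two-stratum study in which agricultural land use multiplies
niche area by 1.35, then recover that effect:

```r
library(isoniche)

cfg <- community_config(
  tibble::tibble(climate_zone = "temperate",
                 land_use = c("woodland", "agriculture"),
                 n_sites = 100),
  alpha_landuse = c(agriculture = 1.35), target = "both", seed = 1)
sim <- generate_records(cfg)

metrics <- compute_site_metrics(sim$records, threshold = 5)
fit <- fit_lmm(metrics, "log_group_seac",
               fixed = c("functional_group", "land_use"))
emm_contrast(fit, "land_use")
#> # A tibble: 1 x 7
#>   contrast               estimate     se    lo    hi percent percent_se
#>   <chr>                     <dbl>  <dbl> <dbl> <dbl>   <dbl>      <dbl>
#> 1 agriculture - woodland    0.349 0.0483 0.255 0.444    41.8       6.85
```

The contrast is the log-response ratio (truth: ln 1.35 ≈ 0.300; the 95% CI
[0.255, 0.444] covers it), and `percent` is the multiplicative effect —
here agriculture's niche areas are estimated ~42% larger, with the true
+35% inside the interval. The same `metrics` table feeds the decomposition:

```r
d <- decomposition_table(metrics)
decomposition_models(d)$expansion$slopes[1, ]
#> # A tibble: 1 x 5
#>   group  slope      se    lo    hi
#>   <chr>  <dbl>   <dbl> <dbl> <dbl>
#> 1 pooled 0.181 0.00623 0.169 0.193
```

a positive pooled slope of log group SEAc on mean taxon SEAc: here
group-level diversity tracks within-taxon niche breadth.

Real data enter through `read_records()`, which validates a CSV of
sample-level records (`record_id, site_id, climate_zone, land_use, taxon,
family, genus, species, d13C, d15N`; column aliases supported), rejects
rows with missing isotope values, annotates the 28 built-in high-rank taxa
with their functional group, and reports everything it excluded.

A thin command-line wrapper over these functions is in
`inst/scripts/isoniche.R` (subcommands `simulate`, `metrics`, `effects`).

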