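---
title: "Isotopic trophic-niche metrics and their statistical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopic trophic-niche metrics and their statistical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoniche)
```

## The scientific problem

Soil animal communities process most of the carbon fixed by plants, and the
diversity of their trophic roles — which basal resources they eat and at
which trophic level they feed — underpins decomposition, nutrient cycling
and food-web stability. Stable isotope ratios summarize those roles in two
numbers per animal sample: δ¹³C tracks the basal resource (fresh plant
material versus microbially processed organic matter) and δ¹⁵N tracks
trophic level. A community's *trophic diversity* can then be measured as
the spread of its samples in the δ¹³C–δ¹⁵N plane.

`isoniche` implements that measurement chain for multi-site comparative
studies: per-site niche metrics for functional groups (herbivores,
detritivores, microbivores, predators, mixed feeders) and for the taxa
within them, a decomposition of group-level diversity into *niche
expansion* (wider niches within taxa) versus *niche partitioning* (greater
separation between taxa), and a mixed-model layer that turns site-level
metrics into land-use and climate effect sizes with confidence intervals.
A synthetic community generator with analytic ground truth makes every
stage testable without field data.

## The niche metrics

For a group of $n$ samples with 2×2 sample covariance $\Sigma$ (denominator
$n-1$; fixed, not configurable), the **standard ellipse area** is

$$\mathrm{SEA} = \pi \sqrt{\det \Sigma},$$

the area of the 1-standard-deviation ellipse whose semi-axes are the square
roots of $\Sigma$'s eigenvalues. It is the bivariate analogue of the
standard deviation: for a bivariate normal it contains a fixed fraction
$1 - e^{-1/2} \approx 39.35\%$ of the distribution, which gives an exact
analytic check used in the tests. We deliberately use the 1-SD ellipse, not
a 95%-coverage ellipse; no coverage rescaling appears anywhere.

SEA is biased low at small $n$; the **corrected area**

$$\mathrm{SEA_c} = \mathrm{SEA} \cdot \frac{n-1}{n-2}, \qquad n \ge 3,$$

removes most of that bias and is the trophic-diversity statistic used
throughout. Requesting the correction below $n = 3$ is an error, never a
silent fallback. To further limit small-sample noise, ellipses are only
computed for groups with **at least 5 samples per site** (the `threshold`
argument; its floor is 3 because SEAc is undefined below that).

**Trophic dissimilarity** — the niche-partitioning indicator — is the mean
pairwise Euclidean distance between taxon centroids within a functional
group at a site, in raw ‰ units (δ¹³C and δ¹⁵N are not standardized
relative to each other before distances or areas are computed; the analysis
operates on uncalibrated isotope values). With a single taxon the statistic
is undefined and propagates as `NA`, never as 0. Centroids entering the
dissimilarity require at least 2 samples per taxon (`centroid_min`): two is
the minimum that defines a mean independently of the stricter ellipse
filter, which still governs taxon-level SEAc. Both thresholds are exposed
because reasonable analysts could couple them.

Group-level SEAc pools all individual records of a functional group at a
site (rather than averaging taxon-level areas); this measures the
heterogeneity across individuals *and* taxa, which is what the group-level
statistic is meant to capture. The per-taxon mean of SEAc
(`mean_taxon_seac`, unweighted across taxa) is reported alongside as the
niche-expansion indicator.

Degenerate (collinear) point clouds give SEA = 0. The downstream log-scale
models exclude such rows with a warning instead of adding an arbitrary
epsilon; a zero area carries no usable information about multiplicative
effects.

## The statistical layer

Per-site metrics are compared across strata with linear mixed models on the
natural-log scale (`log(SEAc)`, `log(dissimilarity)`), fitted by REML via
`lme4`, with a site random intercept absorbing the non-independence of
several functional groups measured at one site; taxon-level responses add a
taxon-within-group random intercept. The main contrasts (agriculture vs
woodland, tropical vs temperate) are estimated on the
temperate/tropical × woodland/agriculture subset, the strata with robust
sample sizes; all strata survive reading and are only excluded by
`subset_for_contrasts()`.

Contrasts are formed from estimated marginal means — model predictions
averaged over a balanced grid of the remaining factors with equal cell
weights (proportional weighting is available by flag) — via `emmeans`, and
back-transformed to multiplicative percent effects:

$$\%\Delta = 100\,(e^{\hat\beta} - 1), \qquad
  \mathrm{SE}_{\%} = 100\, e^{\hat\beta}\, \mathrm{SE}(\hat\beta),$$

the only back-transform consistent with interpreting the log-scale
difference as a log-response ratio. Contrasts are formed on the log scale
first and back-transformed afterwards. Confidence intervals use the normal
approximation: at the site counts these designs involve (hundreds of
site-level rows) the difference from finite-df corrections is negligible,
and the normal approximation is exactly reproducible across optimizers;
Satterthwaite-type df are left as an extension. No multiple-testing
correction is applied across per-group contrasts — each is reported with
its own CI, which is a documented limitation, not an oversight.

The covariate model re-fits the main model with sampling number and taxon
richness as numeric covariates, to check that stratum effects are not an
artifact of sampling effort. The decomposition models regress log group
SEAc on each mechanism indicator (mean taxon SEAc; dissimilarity) with a
site random intercept, reporting pooled and per-group slopes plus
marginal/conditional variance explained (fixed-effect variance over total,
and fixed-plus-random over total).

Residual spatial autocorrelation is checked with Moran's *I* on site-level
residuals using row-standardized 5-nearest-neighbour weights from
great-circle distances. The null distribution is obtained by permutation
(999 permutations by default, two-sided around the expectation
$-1/(n-1)$, seed required) rather than the analytic normal approximation,
which is unreliable for irregular site geometries at moderate $n$.

## The synthetic generator

`generate_records()` draws the statistical structure the analysis assumes,
not mechanistic isotope ecology (no fractionation chains, baselines or
food-web topology):

* per functional group, a base centroid $\mu_g$ and a within-taxon
  covariance $\Sigma_w$ (the **expansion** knob);
* taxon centroids scattered around $\mu_g$ with isotropic dispersion
  $\tau^2 I$ (the **partitioning** knob) — isotropy keeps the knob
  one-dimensional and the expected pooled area closed-form,
  $\pi\sqrt{\det(\tau^2 I + \Sigma_w)}$;
* treatment effects as multiplicative area factors $\alpha$ applied to
  $\Sigma_w$ and/or $\tau^2$ (a factor $c$ on a 2×2 covariance multiplies
  the ellipse area by exactly $c$);
* a site effect as a covariance multiplier $e^{N(0,\sigma_{site}^2)}$ —
  log-additive on areas, so the log-scale LMM is *correctly specified
  under the generator*. That is a statement about the generator matching
  the analysis model, not about nature.

Default geometry (chosen once as field-realistic values: centroids a few ‰
apart, within-taxon variances of 1–2 ‰², $\tau$ of 1–1.5 ‰, site SD 0.3 on
the log-area scale, 4 taxa per group with 6–10 samples each) lives in the
scenario presets. The validation designs use 100 sites per treatment
stratum and an area multiplier of 1.35 for the land-use effect and 1.41
for the climate effect — the magnitudes of the multiplicative stratum
effects the method is meant to resolve (on the percent scale, +35% and
+41%). Taxon names are drawn from the real per-group taxon lists so the
functional-group mapping is exercised end-to-end, and all draws come from
one seeded stream in a fixed order (strata as listed, then sites, groups,
taxa), so a seed fully determines the community.

What the generator does **not** emulate — and therefore what passing tests
do not certify about field data: non-normal and skewed isotope clouds,
unbalanced and correlated sampling effort across strata, taxon-specific
(anisotropic) dispersion, missing taxonomy, and spatially structured site
effects. The Moran's *I* diagnostic exists precisely because the last of
these is expected in real data.

## Numerical and design choices

* Covariance symmetry is enforced exactly (`(S + t(S))/2`) and positive
  semi-definiteness is checked to a 1e-10 relative tolerance; tiny negative
  determinants from floating point are clamped to zero area.
* Nearest-neighbour ties in the Moran weights break by site index, making
  the weight matrix deterministic.
* Permutation p-values use the add-one convention $(1 + \#\{\cdot\})/(B+1)$.
* The resolution argument (`taxon`, `family`, `genus`, `species`) re-runs
  the identical pipeline at finer ranks, dropping records that lack the
  rank — the robustness check across taxonomic scales.
* Models with quadratic isotope terms are not fitted by default; the
  linear specifications are the supported models, and any information-
  criterion comparison is left to the user's own model set.
* Validation problem sizes (100 sites per stratum, 100 replicates for
  coverage checks, 5,000 replicates for the SEAc bias study, 1,000 for the
  Moran size study) were chosen so Monte-Carlo error is small relative to
  each tolerance.

## Worked example

```{r example, eval = FALSE}
library(isoniche)

# a two-stratum community with a 1.35x land-use effect on niche area
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
#> contrast: agriculture - woodland, estimate ~ log(1.35), percent ~ 35

decomp <- decomposition_table(metrics)
decomposition_models(decomp)$expansion$slopes
```

## Known limitations

* The analytic SEAc is the only niche-area estimator; Bayesian posterior
  ellipses, convex-hull metrics and ellipse overlap are out of scope.
* The percent back-transform assumes the log-scale contrast is the
  estimand; averaging percent effects across groups *after*
  back-transformation would give different numbers (contrasts here are
  always formed on the log scale first).
* Weights for the Moran diagnostic are k-nearest-neighbour only; distance-
  band or graph-based weights are not implemented.
* With very few taxa per group the dissimilarity is a high-variance
  statistic; its models should be read with the per-site taxon counts in
  hand (`taxon_richness` is in every metrics row).
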