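---
title: "Methods: stand biomass and species dominance from the largest trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stand biomass and species dominance from the largest trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(largetrees)
```

This vignette documents the models behind `largetrees`, the assumptions they
make, the numerical choices taken where several were defensible, and what
the synthetic-stand generator does and does not emulate.

## The scientific setting

In closed-canopy moist tropical forest, stem size distributions are strongly
right-skewed: most stems are small, but the biomass integral is dominated by
the rare large trees. Two consequences are exploited here. First, the
above-ground biomass (AGB) of the few largest trees of a 1-ha plot carries
most of the information about the plot total, so a power law linking the two
can replace a full census. Second, a small number of tree species
concentrate a disproportionate share of the biomass stock of an entire
region — "biomass hyperdominance" — which matters both for carbon accounting
(several such species are logged commercially) and for monitoring design.

## Tree-level biomass

The with-height allometry is a power form on the compound variable
$\rho D^2 H$:

$$\mathrm{AGB} = a\,(\rho D^2 H)^{b}, \qquad a = 0.0673,\; b = 0.976,$$

with $D$ the diameter at breast height (cm, census threshold 10 cm), $H$
total height (m) and $\rho$ wood specific gravity (g/cm³); the result is dry
mass in kg. The height-free variant replaces $H$ with an environmental
stress covariate $E$ (dimensionless; near 0 in wet Central Africa):

$$\ln \mathrm{AGB} = c_0 + c_E E + c_r \ln\rho + c_d \ln D + c_{d2} (\ln D)^2.$$

Both sets of constants are calibration data, not code: every fitting and
prediction function accepts a `coef` override, which is also how the
robustness of downstream model parameters to the allometry choice is
checked (the test suite verifies that the fitted top-20 exponent moves by
less than 0.05 between the two modes on synthetic stands). The two forms
agree within 5% over $D \in [10, 150]$ cm when the height model implied by
$E$ is used, which the suite also asserts.

**Wood density.** Stems are assigned $\rho$ by exact species match, then
genus mean, then family mean, then the dataset-wide mean, recording the
provenance level. The terminal global-mean fallback is a design choice:
dropping unmatched stems would silently bias plot AGB totals downward,
whereas a mean-density large tree still contributes a sensible mass.
Plausibility bounds (0.05–1.5 g/cm³) are enforced at ingestion.

**Height–diameter allometries** are site-specific, as stature varies
strongly among sites. Three monotone forms are supported — power
$H = aD^b$, Michaelis–Menten $H = aD/(b+D)$, Weibull
$H = a(1-e^{-bD^c})$ — because no single form suits every site; `"auto"`
keeps the form with the smallest log-scale residual sd. The power form is
fitted by log-log least squares and stores median-scale coefficients; the
lognormal half-variance correction $e^{\sigma^2/2}$ is applied at
prediction time (switchable via `correct_bias`) so that predicted heights
target the conditional mean while parameter-recovery comparisons remain
unbiased. Fits require ≥ 20 height observations; fitted curves are rejected
if they are non-positive or decreasing anywhere on $D \in [10, 300]$ cm.

## Accumulation curves

Within a plot, trees are ranked by decreasing AGB with deterministic
tie-breaks (larger DBH first, then stem id), so curves are invariant to
input order. For each $N$ the curve reports the cumulative AGB of the $N$
largest trees, its fraction of the plot total, and the species richness of
those $N$ trees as a fraction of the plot's total richness. Unidentified
stems are pooled under the sentinel taxon `indet`: they carry biomass
(excluding them would corrupt AGB fractions) but never count as species —
the treatment of morphospecies in richness tallies is genuinely ambiguous
in field data, so the choice is explicit and flagged rather than implicit.
Site summaries average across plots on an N grid (default 1–100, matching
the validity window of the generic model below); for a plot with fewer than
$N$ stems the curve is flat at 1, and a site with a single plot reports
sd = 0 with a `sd_degenerate` flag rather than `NA`, keeping downstream
tables rectangular.

## The top-N power model

Across the plots of a region, total AGB is modelled as an intercept-free
power law in the top-N AGB (both kg/ha):

$$\mathrm{AGB_{TOT}} = \alpha \, (\mathrm{AGB_{topN}})^{\beta}.$$

Numerical choices:

* **Error scale.** The fit is nonlinear least squares on the natural scale,
  so the residual standard error is in kg/ha and its ratio to the mean
  observed response (RSEr) is directly interpretable. A log-log ordinary
  regression provides start values only.
* **Identity limit.** When $N$ reaches every plot's stem count,
  $\mathrm{AGB_{topN}} \equiv \mathrm{AGB_{TOT}}$ and the model must be the
  identity. Least squares on zero-residual data is ill-posed, so when the
  predictor equals the response (or the log-log start already interpolates)
  the start is returned directly — making $\alpha = \beta = R^2 = 1$ exact,
  not approximate. A constant predictor (another degenerate input) pins
  $\beta = 1$ and estimates only $\alpha$.
* **$R^2$ about the mean.** Although the model has no intercept, $R^2$ is
  computed against the observed mean (not uncentred), so values are
  comparable across $N$ and with standard regression reporting.
* **Goodness-of-fit fields.** Each fit stores $R^2$, RSE (kg/ha), RSEr,
  coefficient standard errors and the number of plots, and serializes to
  JSON via `model_to_json()`.

**The generic model over N.** Fitting one power model per $N$ from 5 to 100
gives coefficient trajectories $\alpha(N)$ (decreasing) and $\beta(N)$
(rising towards 1). These are summarized by $\alpha(N) = aN^b$ and a
three-parameter saturating Weibull growth curve
$\beta(N) = k_1(1 - e^{-k_2 N^{k_3}})$ with start values $(1, 0.1, 1)$. The
Weibull form was chosen for its saturating shape matching the asymptotic
rise of $\beta$; the exact variant is configurable through `beta_start`
and the stored per-N table. The fit uses the Levenberg–Marquardt residual
interface directly because a near-flat $\beta(N)$ series converges with
$k_2$ at its saturation limit, where a singular Jacobian is expected and
harmless. Predictions outside the fitted range of $N$ (by default
$[5, 100]$) are refused: the meta-model is an interpolation, not a law.

**Cross-validation.** Transferability is assessed site-wise: each site is
held out in full, the model refitted on the remaining plots, and the
held-out plots predicted. Per site the package reports Pearson's $r$ and
two bias summaries: the mean absolute relative error (headline, since
"bias" of a prediction model is most conservatively read as magnitude) and
the mean signed relative error (diagnostic for directional site offsets).
Sites with fewer than 2 plots cannot support a correlation and are excluded
from hold-out with a warning; fewer than 3 sites is an error.

**Species richness** is predicted linearly ($\mathrm{species_{TOT}} = a + b
\cdot \mathrm{richness_{topN}}$) per site and pooled; a site whose predictor
does not vary is flagged degenerate rather than fitted.

## Biomass hyperdominance

Species contributions are standardized by site — species AGB summed over the
site's plots, divided by the site's area in ha and converted to t/ha — so a
site's plot count does not weight the region. The regional contribution of
a species is the unweighted mean of its site values (absent = 0); this is
the natural arithmetic reading of "each site contributes equally", and it
coincides with pooled totals only when site areas are equal, which is why
the choice is documented rather than assumed. Species are ranked by
decreasing contribution, ties broken alphabetically for determinism.

The hyperdominant set is the *minimal prefix* of that ranking whose
cumulated share reaches the threshold (default 50%), with an inclusive
boundary: a prefix summing to exactly the threshold stops. `indet` biomass
stays in the denominator but the pooled pseudo-taxon can never be selected
(toggle by editing the `eligible` column); if the identified species cannot
reach the threshold the full eligible set is returned. Local dominance
applies the same rule within one site, and `classify_overlap()` partitions
each site's local dominants into regionally-hyperdominant and local-only
subsets. A transcribed published reference table for Central Africa
(`regional_reference_table()`) anchors the ranking and cumulation
arithmetic against printed values to within their 2-decimal rounding
(±0.02); its last two rows tie at printed precision, so order comparisons
are tie-aware.

## The synthetic stand generator

`synthetic_config()` defaults describe a Central-African-like network and
are fixed once, not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| sites × plots | 8 × 20 (1 ha) | a multi-site regional network |
| stems/ha | 450 (Poisson) | typical ≥ 10 cm DBH density in moist forest |
| DBH law | Pareto slope 2 on 10–250 cm | the metabolic-scaling size structure; slope configurable to emulate reported deviations for the largest trees |
| SAD | log-series-like ranks, 300 species | dominance-skewed abundances |
| wood density | N(0.6, 0.15) g/cm³, clamped 0.15–1.3 | community means in this region |
| H–D | $2.8D^{0.57}$, lognormal sd 0.1 | ~10 m at 10 cm, ~49 m at 150 cm |
| site effects | lognormal sd 0.1 on density and stature; sd 0.5 species turnover | among-site heterogeneity |
| monodominance | 1 site, dominant share 0.6 | a near-monodominant stand in the network |

Determinism is total given the seed. Species are assigned independently of
size by default (a `dominant_min_dbh` above the census threshold restricts
the dominant's share to large stems, mimicking large-statured dominants);
wood density is species-level; heights come from the site's H–D law; and —
deliberately — AGB is *computed through the allometry module*, never drawn
directly, so every generated region exercises the full pipeline including
wood-density fallback.

What the generator does **not** emulate: spatial structure within plots and
autocorrelation between neighbouring plots (so dominance estimates on real
clustered networks can be optimistic relative to synthetic results), crown
or buttress measurement error, taxonomic misidentification, demographic
dynamics, and the empirical departures of real size distributions from a
clean truncated Pareto. Passing tests on synthetic stands therefore
demonstrate the correctness and internal consistency of the estimators, not
the field values of $R^2$ or dominance percentages, which depend on the
real network's structure.

## Problem sizes and tolerances in the test suite

The suite favours small, seeded simulations: module tests use 3–4 sites of
a few plots; the acceptance-level properties use a 175-plot region (7 sites
× 25 plots) with 20 replicates for parameter recovery (multiplicative
lognormal noise, sd 0.15; median absolute error of $\beta$ below 0.05),
200 random 100-species compositions against a brute-force minimal-prefix
oracle, 1000 random plots for accumulation monotonicity/conservation, and
5000 diameter draws against the closed-form truncated-Pareto CDF
(Kolmogorov–Smirnov distance below 0.03). Exact assertions (identity limit,
forced arithmetic) use machine tolerance; simulation-based assertions use
bands wide enough to hold across seeds (verified on several) without being
vacuous.

## Known limitations

* The generic meta-model is fitted to this package's own per-N
  trajectories; published meta-coefficients for specific regions are not
  reproduced here and predictions outside $N \in [5, 100]$ are refused.
* Equal site weighting makes the regional ranking sensitive to the set of
  sites supplied; adding a site changes all percentages.
* The LOOCV bias definitions are relative errors; for plots with very small
  AGB_TOT a relative error can be large even when absolute error is modest.
* No uncertainty propagation from the allometry into the top-N model:
  allometric error is treated as part of the residual.
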