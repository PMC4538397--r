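# largetrees

Forest inventories are expensive: a single 1-ha census of every stem ≥ 10 cm
DBH in a moist tropical forest means measuring several hundred trees. Yet in
these forests a handful of big trees hold most of the above-ground biomass
(AGB), and a handful of species hold most of the regional biomass stock.
`largetrees` turns those two regularities into a quantitative toolkit for
forest ecologists and carbon-monitoring programs working with tree inventory
tables: it predicts whole-plot AGB from only the largest trees, and
identifies the "biomass hyperdominant" species that cumulate half of a
region's AGB.

## What it computes

**Tree AGB.** Each stem's dry biomass (kg) comes from the moist-forest
allometry on the compound variable ρD²H,

    AGB = 0.0673 (ρ D² H)^0.976,

with wood specific gravity ρ (g/cm³) assigned from a reference table by a
species → genus → family → dataset-mean fallback, and height H (m) either
measured or predicted from a site-specific height–diameter allometry (power,
Michaelis–Menten or Weibull form). A height-free variant driven by an
environmental stress covariate E is also provided; the constants live in
config, not code, so alternative calibrations can be swapped in.

**Accumulation curves.** Trees are ranked in each plot by decreasing AGB;
the package tracks the cumulative AGB fraction and species richness of the N
largest trees (N = 1 … all stems).

**The top-N model.** Across plots, total AGB follows an intercept-free power
law in the AGB of the N largest trees,

    AGB_TOT = α · (AGB_topN)^β        (kg/ha),

fitted by natural-scale nonlinear least squares. Two meta-models make the
family generic over N ∈ [5, 100]: α(N) = a·N^b (power) and
β(N) = k₁(1 − e^(−k₂ N^k₃)) (saturating Weibull). Site-wise leave-one-out
cross-validation (hold out a whole site, fit on the rest) reports per-site
Pearson r and relative bias.

**Biomass hyperdominance.** Species contributions are standardized by site
(t/ha over the site's plots) so every site weighs equally; the regional
hyperdominant set is the minimal prefix of the contribution ranking that
cumulates 50% of total AGB, with the same rule applied per site for local
dominance and an overlap classification between the two scales.

**Synthetic stands.** A deterministic generator builds multi-site inventories
with truncated power-law diameters, dominance-skewed species abundances,
species-level wood densities, noisy height–diameter allometry, lognormal
site effects and optional near-monodominant sites — so the entire pipeline
is testable without field data. A packaged transcription of a published
Central African biomass-hyperdominance table serves as a printed-arithmetic
fixture.

## Worked example

```r
library(largetrees)

cfg <- synthetic_config(seed = 1, n_sites = 4, plots_per_site = 15)
region <- generate_region(cfg)
inv <- region$inventory
#> forest_inventory: 28298 stems, 60 plot(s), 4 site(s)

tab <- plot_topn_table(inv, 20)          # per-plot AGB_top20 and AGB_TOT
fit <- fit_power_model(tab$agb_topn, tab$agb_tot, n = 20)
fit
#> power_model (no intercept): AGB_TOT = alpha * AGB_top20^beta
#>   alpha = 5.097, beta = 0.91313  (n_plots = 60)
#>   R2 = 0.8640, RSE = 1.179e+05 kg/ha, RSEr = 7.4%

loocv_by_site(tab)
#> site-wise leave-one-out cross-validation
#>  site n_plots pearson_r   bias_abs bias_signed
#>   S01      15 0.9763698 0.04099902 -0.03435939
#>   S02      15 0.9507315 0.08103329  0.07842500
#>   S03      15 0.9594563 0.08954254 -0.08954254
#>   S04      15 0.9606490 0.08088279  0.07312903
#>   mean Pearson r = 0.962, mean |bias| = 7.3%, mean signed bias = 0.7%

rc <- regional_contributions(inv)
head(as.data.frame(rc)[, c("rank", "species", "agb_t_ha", "pct", "pct_cum")], 3)
#>   rank     species  agb_t_ha       pct  pct_cum
#> 1    1 Species 001 395.49235 24.648810 24.64881
#> 2    2 Species 002 169.12541 10.540634 35.18944
#> 3    3 Species 003  99.15491  6.179767 41.36921
length(hyperdominant_set(rc))
#> [1] 5
```

Reading: measuring only the 20 largest trees of each 1-ha plot (a few
percent of the stems) predicts the plot's total biomass with a relative
residual error of ~7% on this synthetic region, the relationship transfers
across sites (mean hold-out r = 0.96), and 5 of ~300 species cumulate half
of the regional biomass. Real inventories enter the same pipeline through
`read_inventory()`, `wood_density_table()` + `assign_wood_density()` and
`compute_agb()`.

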