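# luccarbon

Ecosystem carbon-stock accounting driven by land-use and land-cover change
(LUCC), with Markov/cellular-automata projection of future land-use maps.

`luccarbon` is for researchers who track how transitions among categorical
land-use classes (cropland, forest, grassland, water, construction, unused
land) redistribute terrestrial carbon, and who want those analyses
reproducible from plain tables and rasters rather than GIS point-and-click.
It bundles the published tables of a provincial case study (Yunnan,
1990–2030) as fixtures, so every headline quantity of that analysis can be
recomputed from scratch.

## The model

**Carbon bookkeeping.** Each land-use class *i* has a carbon density that is
the sum of four pools (t/hm²):

    C_i = C_above + C_below + C_soil + C_dead

and the regional stock is the density-weighted area sum (reported in 10⁶ t,
with 1 km² = 100 hm²):

    C_total = Σ_i C_i · S_i

**Change analysis.** Two epoch maps cross-tabulate into a transfer matrix
`T[i, j]` (km² moving from class *i* to class *j*); its off-diagonals are
conversions, its marginals recover each epoch's class areas, and row
normalization gives a row-stochastic Markov matrix `P` (`0 ≤ P_ij ≤ 1`,
`Σ_j P_ij = 1`).

**Projection.** Class areas advance as `S_{t+1} = S_t P` (area-conserving);
the spatial arrangement advances with a cellular-automata rule: a cell's
suitability for class *k* is the fraction of class-*k* cells in its
neighborhood window plus a persistence bonus, and growing classes claim the
most suitable cells released by shrinking classes until the Markov targets
are hit exactly (largest-remainder rounding). Simulated maps are validated
against held-out epochs with Cohen's kappa.

## Worked example

```r
library(luccarbon)

dens  <- yunnan_density_table()          # four-pool densities, t/hm2
areas <- yunnan_area_table()             # class areas for five epochs, km2

r1990 <- stock_by_class(areas[["1990"]], dens)
r2020 <- stock_by_class(areas[["2020"]], dens)
r1990
#> carbon stock report [1990]: total 8284.23 x 10^6 t
#>              class area_km2 density_t_hm2 stock_Mt contribution_pct
#>           cropland    69371        138.41   960.16            11.59
#>        forest_land   218881        258.12  5649.76            68.20
#>          grassland    87732        185.29  1625.59            19.62
#>         water_area     2805         71.08    19.94             0.24
#>  construction_land     1788         73.91    13.22             0.16
#>        unused_land     2105         73.98    15.57             0.19

chg <- stock_change(r1990, r2020)
round(chg$table$delta_Mt, 2)
#> [1] -31.36  24.31 -32.18   7.34  22.08  -4.18
```

Forest holds ~68% of the provincial stock; between 1990 and 2020 cropland
and grassland lose 31.36 and 32.18 × 10⁶ t while forest, water and
construction gain 24.31, 7.34 and 22.08 × 10⁶ t — a near-flat total
(−13.99 × 10⁶ t over 30 years).

Transition analysis and projection work the same way from the transfer
matrix:

```r
tm <- yunnan_transfer("1990_2020")
round(net_change(tm), 1)                     # net inflow (+) / outflow (-)
p  <- to_probabilities(tm, step_years = 30)  # row-stochastic Markov matrix
project_areas(areas[["2020"]], p, steps = 1) # projected class areas
```

For spatial work, `synthetic_scenario()` + `make_series()` generate
multi-epoch landscapes with a known transition process, `simulate_landuse()`
runs the CA-Markov allocator, and `kappa_agreement()` scores simulated
against observed maps. `run_pipeline()` drives the whole chain from one
YAML/list config, in either table-only or raster mode.

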