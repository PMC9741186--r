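---
title: "Carbon accounting under land-use change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon accounting under land-use change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luccarbon)
```

`luccarbon` couples three classic pieces of land-change science: four-pool
carbon-density bookkeeping on categorical land-use maps, Markov-chain
projection of class areas, and cellular-automata (CA) spatial allocation of
projected change. This vignette explains each model, the assumptions
behind it, the parameters that matter, and the design choices made where
the methods literature leaves room.

## Carbon bookkeeping

Each class $i$ carries a fixed carbon density (t/hm²) summed over four
pools — aboveground biomass, belowground biomass, soil, and dead organic
matter:

$$C_i = C_{above} + C_{below} + C_{soil} + C_{dead},$$

and the regional stock aggregates density times area over classes:

$$C_{total} = \sum_{i=1}^{n} C_i \, S_i .$$

Assumptions worth stating plainly: densities are constant over time and
uniform within a class, so all temporal change in $C_{total}$ is driven by
area change. That is the standard inventory-style simplification; it cannot
capture succession, degradation gradients, or climate-driven density
trends. A zero pool entry (water has no belowground or dead pool) is an
ordinary zero, not missing data.

Units are isolated deliberately: areas are km² everywhere except in the
one bookkeeping step, where the 100 hm²/km² constant converts to the
density basis; stocks are reported in 10⁶ t. All arithmetic is full
precision — rounding to the conventional 2 decimals happens only at print
time, because change decompositions (differences of ~10⁴-scale numbers at
0.01 resolution) do not survive premature rounding.

The `stock_change()` decomposition reports per-class deltas plus each
declining class's share of the gross decrease (and rising class's share of
the gross increase). When there is no decrease the shares are reported as
zero rather than NaN.

`adjust_density_table()` is an explicit preprocessing hook for
climate-correcting a density table between regions: each pool is scaled by
the ratio of a user-supplied monotone climate proxy evaluated at the study
versus reference climate (`biomass` scales the above/below/dead pools,
`soil` the soil pool). The defaults are identity relations, so the hook is
inert unless a proxy is supplied — bundled tables are treated as already
corrected, and the package never applies a correction silently.

## Transfer matrices and transition probabilities

`cross_tabulate()` counts cells jointly valid in both epochs, scaled by the
cell area. Cells that are nodata in either epoch are excluded, which is why
a transfer matrix's grand total can fall short of the mapped region's
nominal area — boundary cells rarely survive both epochs. Marginals then
recover per-epoch class areas over exactly that joint support.

`conversion_fraction()` divides a matrix entry by the *full* origin row
total, persistence included. Published conversion percentages in the
land-change literature are almost always quoted on this base (even when
the prose says "of the transferred-out area"), and it is the only
convention under which a matrix, its marginals and its quoted percentages
stay mutually consistent.

`to_probabilities()` normalizes rows; an origin class with zero area gets
an identity row. Keeping the matrix row-stochastic without inventing mass
is the only defensible treatment, and it makes the class persist — the
natural null behavior.

Map agreement uses Cohen's kappa on the joint contingency:
$\kappa = (p_o - p_e)/(1 - p_e)$, with $p_e$ from marginal products. The
degenerate case $p_e = 1$ (both maps constant) is defined as $\kappa = 1$
when the maps agree and $0$ otherwise.

## Markov projection

`project_areas()` multiplies the area row-vector by $P$ for a whole number
of steps. One step means one calibration interval (`step_years` metadata
travels with the matrix), and the package deliberately does not offer
fractional steps: matrix roots of stochastic matrices need not be
stochastic, so "half an interval" is not well defined. Total area is
conserved exactly and non-negativity is preserved for any row-stochastic
matrix.

`stationary_distribution()` is a power-iteration diagnostic for the
long-run class mix (tolerance 1e-10 on the L1 step change, capped at 10⁶
iterations). Periodic chains that oscillate from the uniform start are
reported as non-convergent rather than silently averaged.

## CA allocation

The CA step turns aspatial Markov targets into a map. Suitability of class
$k$ at a cell is the fraction of class-$k$ cells in the
`neighborhood_size` × `neighborhood_size` window (default 5 × 5, the
conventional contiguity-filter size), truncated at edges — no wraparound,
since region boundaries are real — plus a `persistence_bonus` (default
0.2) if the cell already holds $k$, clipped to [0, 1].

Targets in km² become integer cell counts by largest-remainder rounding,
so per-class counts are hit *exactly*. Allocation is claim-driven: growing
classes claim cells in globally descending suitability from the cells of
shrinking classes, each shrinking class releasing at most its surplus;
cells of classes that are stable or growing are never touched. Exact
suitability ties — common, because window fractions are rationals with a
small denominator — are broken uniformly at random under the
configuration seed, so runs are bit-reproducible.

Each Markov step is spread over `iterations_per_step` rounds (default 10)
that move equal fractions of the step's net change, with suitability
recomputed every round; this lets growth accrete along patch edges rather
than teleporting to the single best cell of the initial map. The defaults
are configuration-exposed, not load-bearing: the package's guarantees
(exact count matching, determinism, coherence above random placement) hold
for any legal configuration.

## Synthetic landscapes

The generator exists so that every pipeline stage is testable without any
external raster. `generate_landscape()` draws one Gaussian noise field per
class, smooths it with repeated box blurs (radius = `correlation_length`,
three passes — a simple, dependency-light stand-in for a spectral random
field), and assigns cells by sequential quantile cuts: each class in turn
claims its largest-remainder quota of the remaining cells in descending
field order. Realized class counts therefore match the target proportions
exactly, and patches inherit the fields' correlation length.

`evolve_landscape()` moves each cell to its next class by sampling from
$(1-w)\,P_{i\cdot} + w\,q$, where $q$ is the row $P_{i\cdot}$ reweighted
by the 5 × 5 neighborhood composition and renormalized (falling back to
$P_{i\cdot}$ where the reweighted row has no mass) and $w$ is the
`clustering` weight. At $w = 0$ cells are independent Markov draws, so
cross-tabulating consecutive epochs recovers the generating matrix up to
binomial noise — the basis of the parameter-recovery tests. At $w = 1$ on
a uniform map the process is degenerate and the map is invariant.

The default scenario mimics a forest-dominated provincial landscape
(shares ≈ 0.18 cropland / 0.57 forest / 0.23 grassland with three minor
classes, correlation length 3 cells, clustering 0.3, strong-persistence
transition matrix with 0.90 diagonal). What synthetic landscapes do *not*
emulate: terrain and climate drivers, road-network effects, mapping error,
or any real region's geography — passing tests on them demonstrates
algorithmic correctness and statistical calibration, not fidelity to a
particular province.

The Markov-recovery check runs on a balanced six-class 300 × 300 scenario
(diagonal 0.9, off-diagonals 0.02). Balance matters: with realistic
skewed proportions a 0.5%-share class has only a few hundred cells, whose
binomial noise alone exceeds an elementwise ±0.01 recovery bound; with
15,000 cells per class the bound sits at more than four standard errors.

## Numerical and degenerate-input choices

- Grid files are ESRI ASCII (plain text, km map units); codes round-trip
  bit-exactly and the nodata sentinel is declared in the header.
- Unknown codes are rejected at construction with their count and first
  location, not coerced.
- `check_alignment()` is report-only; cross-epoch operations require
  shape, cell size and georeference to agree but tolerate differing nodata
  masks (the joint-validity rule handles those).
- Zero-area classes: zero stock and zero contribution; identity rows in
  transition matrices; excluded gracefully from conversion fractions
  (error with the class named).
- All stochastic components (tie-breaks, synthetic fields, evolution
  draws) consume an explicit seed and restore the caller's RNG state.

## Problem sizes

Unit and property tests use grids between 4 × 4 and 150 × 150; the
Markov-recovery check uses one 300 × 300 series; the CA coherence property
uses fifty 24 × 24 trials. These sizes put the binomial error bounds and
join-count contrasts comfortably inside their thresholds while keeping the
whole suite a few seconds long.

## Known limitations

- Densities fixed in time and uniform within class; no process-based
  carbon dynamics or valuation.
- No reprojection, resampling or vector clipping — inputs must already be
  aligned single-band categorical rasters.
- Suitability uses neighborhood composition and persistence only; no
  external driver layers (slope, roads, zoning scenarios).
- No annualization of transition matrices (see above).
- The bundled case-study transfer tables are printed at 2 dp, so
  marginal-derived statistics inherit up to ~0.03 km² of print rounding;
  the package computes full precision from whatever it is given.
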