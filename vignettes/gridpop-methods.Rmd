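---
title: "Methods: harmonised covariate grids and dasymetric population mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonised covariate grids and dasymetric population mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridpop)
```

## The problem

Census population counts are reported for administrative units that differ
in size, shape and vintage across countries, while most health and
development applications (denominators for disease prevalence, exposure to
conflict, service accessibility) need population on a regular grid. gridpop
implements the standard top-down answer at desk scale: harmonise a set of
geospatial covariate layers onto one shared grid ("mastergrid"), interpolate
two-date census counts into an annual series per unit, fit a model that
relates unit-level population density to unit-level covariate summaries,
predict that density at every grid cell, and use the prediction as a
weighting surface to share each unit's count among its cells. The package
also ships the two demonstration analyses this kind of data supports:
population at risk under a prevalence threshold, and population living close
to clustered conflict events.

## The mastergrid and its conventions

Every layer lives on a `mastergrid`: a north-up lat/lon grid with a cell
size in decimal degrees and an origin snapped to the global anchor
(-180, 90), so that any two grids at the same resolution align cell-for-cell
regardless of where they were defined. The production-scale convention this
mirrors uses 3 arc-second cells (0.00083333333 degrees); the toy worlds in
this package default to 0.01 degrees to keep everything interactive.

Cells are half-open: cell (r, c) covers
`[origin_lon + (c-1)s, origin_lon + cs)` in longitude and
`(origin_lat - rs, origin_lat - (r-1)s]` in latitude. All point-to-cell
assignments (rasterisation, resampling, event binning) sample at cell
centres under this convention. The source material for grids of this kind
never states its sampling convention, so centre-point burning was chosen and
is applied consistently; a point exactly on a shared cell edge belongs to
the east/south neighbour, which makes every assignment deterministic.
Overlapping admin polygons claiming one cell centre resolve to the lowest
polygon ID — deterministic and independent of input order — with a warning.

## Census interpolation

For a unit with counts `P1` at decimal year `y1` and `P2` at `y2`, the
annualised exponential growth rate is

    r = ln(P2 / P1) / (y2 - y1)

and the count in target year `y` is `P2 * exp(r * (y - y2))`. The series
therefore reproduces both censuses exactly and extrapolates beyond the
latest census with the same rate; no floor or cap is applied to negative
growth. Units whose two counts cannot be matched inherit `r` from their
parent (state/province) record, with the provenance recorded. Units with a
zero count at either date have no defined rate; they are kept alive with
`r = 0` and a warning rather than dropped, since dropping would silently
destroy population.

Units smaller than a pixel can fail to receive any cell at rasterisation.
Their counts (both dates) are added to the unit that owns the cell under the
lost unit's representative point — an interior point computed as the
midpoint of the widest horizontal chord at mid-bounding-box latitude, which
survives concave shapes where a centroid would fall outside. National totals
are conserved exactly under this merge.

## Covariate layers

The static module derives the layers a population model conventionally
consumes, each on the mastergrid:

* **Pixel area** (m^2) from the spherical band formula
  `R^2 * dlon * (sin(lat_top) - sin(lat_bottom))`, with the authalic radius
  R = 6,371,007.181 m by default. The areas are constant along rows and any
  full global grid sums to `4*pi*R^2` to 1e-9 relative — that closure is the
  module's standing test.
* **Slope** (degrees) via Horn's 3x3 stencil with metric spacing
  `R cos(lat) dlon` east-west (per row) and `R dlat` north-south. Border
  cells and the 8 neighbours of any no-data cell are no-data, and an input
  no-data cell stays no-data even though Horn's stencil ignores the centre.
* **Land cover** reclassified from detailed source codes to nine aggregate
  classes. The shipped mapping is a stand-in with the conventional class
  semantics (cropland, tree cover, grass/shrub, sparse, wetland, built,
  bare, water, snow/ice); any table with columns `source_code`,
  `aggregate_code` replaces it.
* **Binary and presence layers** for any class set, and great-circle
  **distance to feature** via the haversine formula on cell centres.
* **Climate annualisation**: mean of 12 monthly rasters for temperature,
  sum for precipitation; a cell missing in any month is missing annually.
* **Roads**: per-cell maximum priority over the ways whose geometry touches
  the cell square, retaining classes 8-30 (tertiary to motorway, plus
  bridge/tunnel "links" at the reserved value 30). Links located off land
  are written back after coastal standardisation so coastal roads stay
  contiguous. Intersections are emitted where two ways in classes 8-17
  touch or cross while differing in name, reference, junction or priority;
  crossings involving a bridge or tunnel are suppressed because no at-grade
  junction exists there.

The temporal module covers the annual series: two-satellite night-lights
years are averaged cell-wise with polar no-coverage set to zero radiance;
monthly-composite night-lights years are summed over the months with at
least one cloud-free observation and divided by the number of such months
(the monthly inputs are already month-averaged), never-observed cells being
filled afterwards from surrounding values; protected areas become a
cumulative series (a feature designated in year y appears from y onward, the
first year absorbing all earlier designations) stratified by IUCN group and
terrestrial/marine domain — 18 years x 2 groups x 2 domains = 72 rasters,
mosaicked across domains to 36; and the built-settlement series fuses the
2000/2012/2014 sources with the radar layer back-filtering the optical one.

### Coastal no-data filling ("nibble")

Layers whose native coastline disagrees with the admin coastline have gaps
at the shore. Land cells that are no-data receive the value of the nearest
data cell by Euclidean distance in cell units; ties go to the smallest row,
then the smallest column. The GIS tools this emulates require integer
rasters and therefore scale values by 10^6 before filling; computing in
floating point directly is numerically equivalent and avoids the round
trip, so that is what the package does. Filling never alters an existing
data cell and terminates with zero no-data land cells whenever at least one
donor exists.

## The dasymetric model

Unit-level training rows hold the mean of each continuous covariate, the
class proportions of each categorical covariate, the unit's land area and
its density `count / area` (persons/m^2). A random forest (ranger, 500
trees, default feature subsampling, no depth cap) regresses
`log(density)` — floored at 1e-12 persons/m^2 so zero-count units remain
usable — on those features. The forest is seeded, single-threaded and fitted
on rows sorted by unit ID, which makes the weight surface bit-reproducible
and independent of input row order. A degenerate, zero-variance response
short-circuits to a constant model with a warning: the correct prediction is
that constant, and fitting a forest to it would only obscure that.

Prediction evaluates the forest on each land cell's covariate vector
(categorical layers become class indicators) and exponentiates, giving a
strictly positive weight on land. Redistribution assigns
`count(u) * w(cell) / sum(w over u)`; a unit whose weights sum to zero falls
back to a uniform split, because its population has to go somewhere. The
baseline surface for comparison is areal weighting — weight equal to cell
area, i.e. constant density within each unit.

### Exact conservation

Floating-point shares do not sum exactly to the unit count, so a correction
closes each unit: the residual `count - sum(pop)` is absorbed into a single
cell, chosen as the first (smallest-value first) cell for which the
recomputed sum equals the count exactly. Trying small cells first matters
because the residual is usually below one ulp of the largest cells, where
adding it is a no-op. In rare units the reachable sums straddle the target
in two-ulp steps; a half-residual nudge breaks that parity and the search
repeats. The result is machine-exact per-unit conservation (audited in the
per-unit output), not merely 1e-9-relative agreement.

## Applications

`population_at_risk` sums gridded population over cells whose prevalence
strictly exceeds a threshold (default 0.10) per reporting zone; change
metrics report log10 counts at both dates, their difference (the log10 of
the ratio, so either reading is recoverable) and the percentage-point
change, with zero counts flagged as undefined rather than fabricated.
`conflict_zones` partitions the extent into fixed grid-aligned square
blocks of 9 km side (the east-west span in cells is converted from km at
each block row's central latitude) and flags blocks containing at least two
events. A fixed partition was chosen over a moving window: "zone" phrasing
suggests disjoint areas, a partition is deterministic, and flagged area is
then monotone in the event set. `population_near_conflict` reports the
population share of flagged cells per region.

## The synthetic world

Because the real global inputs are out of reach at desk scale, a seeded
generator produces toy worlds with known truth. Administrative units are the
Voronoi tessellation of uniformly seeded points clipped to the extent
(countries are unions of the unit tiles nearest each country seed, so both
levels partition the extent exactly). One deliberately sub-pixel unit is
planted by surrounding an extra seed with four satellites 0.4 cells away:
its Voronoi tile fits inside a square of circumradius ~0.28 cells and can
never capture a cell centre, so the merge path is exercised on every
default world. Covariates include one layer of each kind the pipeline
consumes: a smoothed random elevation field and its slope, clustered binary
settlement blobs, night-lights decaying with distance from settlement plus
noise, a nine-class land cover cut from elevation bands with settlement
burnt in, and distance to a random toy road.

True population is the intensity surface
`lambda = exp(beta0 + sum(beta_i cov_i) + eps)`, `eps ~ N(0, sigma^2)`, on
min-max-normalised covariates, with defaults `beta0 = 3`,
`beta = (settlement 1.5, nightlights 0.8, elevation -0.5, dist_road -0.8)`
and `sigma = 0.2` — a settlement-dominated density with realistic smooth
confounders, about 1.7e5 persons on the default extent. Using the intensity
itself (not a Poisson draw) as truth makes zonal conservation checks exact;
a Poisson variant sits behind `poisson_truth = TRUE` for realism tests.
First-date census counts are exact zonal sums of the truth; second-date
counts apply per-unit growth rates drawn from [-0.02, 0.05] per year over a
2000-2010 inter-census interval, spanning decline through fast growth.
Prevalence is the logistic transform of a smooth field, steepness 6 and
shift -2 so the field straddles the 10% threshold the way an endemic
setting would (most area low, coherent hotspots above threshold). Events are
Poisson (mean 8 per hotspot unit and year, 5 hotspot units, years
2000/2012/2014) placed uniformly within hotspot-unit cells.

What the generator does not emulate: the empirical spatial autocorrelation
of any specific country, registration error between layers, census
undercount, or multi-temporal settlement growth. Passing tests on these
worlds therefore demonstrates that the machinery is correct — conservation,
determinism, oracle agreement, and that covariate-driven weighting recovers
covariate-driven truth — not that any particular accuracy level transfers
to real data.

## Problem sizes and runtime choices

The default world is 1 degree x 1 degree at 0.01 degrees (100 x 100 cells)
with 4 countries x 25 units — large enough that units average ~100 cells
and the forest has 100+ training rows, small enough that the full test
suite, including two complete world builds and forest fits, runs in well
under a minute. Oracle comparisons (rasterisation, resampling, the monthly
night-lights compositor) run on instances up to 32 x 32 where brute force
is exact and fast. The recovery check uses a noiseless world whose unit
log-density is an exact linear function of mean elevation — the smooth,
well-spread covariate — and requires held-out R^2 above 0.9 on 30 of the
~104 units; the model-versus-baseline check requires the forest-weighted
surface to beat areal weighting in cell RMSE against the known truth on the
default noisy world.

## Known limitations

* Geographic coordinates only; no projected CRS support, and no tiled or
  out-of-core processing for production-scale grids.
* Raster exchange uses ESRI ASCII grids plus a JSON grid config — text
  formats any GIS reads — rather than GeoTIFF.
* The nine-class land-cover mapping is a placeholder legend; real source
  products need their own table.
* Intersection detection uses geometric touch/cross of tagged ways; shared
  topological nodes are not required, so digitisation slivers can create
  near-duplicate points (deduplicated only when exactly coincident).
* The growth model is a two-point exponential per unit: no cohort
  structure, no UN-total calibration, no floor on negative growth.
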