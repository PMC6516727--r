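---
title: "Methods: spatiotemporal tradeoffs for siting offshore wind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal tradeoffs for siting offshore wind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tradewind)
```

# The decision problem

Offshore wind farms impact different taxa through different mechanisms and
on different clocks. Seabirds interact with operating turbines for the whole
20+ year life of a farm, through collision with rotors and displacement from
habitat; that exposure is fixed the moment a site is chosen. Cetaceans are
impacted mostly during short pre-operational windows — pile driving and
seismic surveying inject acoustic energy that can injure or displace animals
tens of kilometres away — and, on a migratory coast, their presence at any
one site varies strongly by month. The two impacts therefore admit two
different levers: choose the *site* to protect seabirds, choose the *month*
to protect cetaceans. `tradewind` quantifies both levers on one analysis
grid and ranks candidate sites accordingly.

All layers live on a congruent equal-area grid of square cells (10 km by
default, the native resolution of widely used cetacean density surfaces).
Any operation handed layers of mismatched shape, cell size or projection
stops with an error; nothing is ever resampled implicitly, and `NA` cells
are excluded from every statistic.

# Wind-farm valuation

Per cell, the candidate farm is valued as

$$\mathrm{NPV} = -\,\mathrm{capex} + \sum_{t=1}^{T} (R_t - C_t)(1+i)^{-t},$$

with constant annual flows. Defaults: 80 turbines × 5 MW (400 MW), lifetime
$T = 20$ yr, discount rate $i = 5\%$/yr, $2M installation per turbine
(applied equally everywhere — depth-dependent foundation costs are
deliberately not modelled), and annual operations and maintenance at 3.5% of
capital expenditure.

**Capex timing.** The sum above runs over $t = 1..T$ and installation is
listed separately from recurring costs, so by default capex is incurred
undiscounted at $t = 0$ and $C_t$ covers O&M only. The alternative
convention (capex discounted one period) is available via
`npv(..., capex_timing = "year1")`; the two differ per cell by exactly the
one-period discount on that cell's capex,
$\mathrm{capex} \cdot i/(1+i)$.

**Wind resource.** Each cell carries Weibull parameters $(k, \lambda)$ for
surface wind speed, either supplied directly or fit from samples.
`fit_weibull()` is maximum likelihood (with a method-of-moments fallback
that solves the coefficient-of-variation identity); both are deterministic
given the data. Hub-height extrapolation multiplies $\lambda$ by
$(z_{hub}/z_{ref})^{\alpha}$ with shear exponent $\alpha = 1/7$ by default
— the neutral-stability open-water convention; the exponent is configurable
because site-specific shear can differ materially.

**Power curve.** Zero below cut-in (3 m s⁻¹) and at/above cut-out
(30 m s⁻¹), rated (5 MW) from rated speed (12.5 m s⁻¹) to cut-out, and
$P(v) = P_r\,(v^x - v_{ci}^x)/(v_r^x - v_{ci}^x)$ in between. The exponent
$x$ defaults to 3 (cubic, the physical scaling of kinetic energy flux) and
is configurable. Expected power
$\int_0^{v_{co}} P(v)\, f(v)\, dv$ is evaluated *exactly* through
regularised incomplete-gamma partial moments of the Weibull distribution
(`stats::pgamma`), which makes the per-cell valuation vectorisable; the
test suite checks this evaluation against independent `integrate()`
quadrature (to 1e-8) and a seeded 10⁶-draw Monte-Carlo simulation (to
0.5%).

**Transmission.** $\mathrm{TransCost} = \beta_0\,MW + \beta_1\,\mathrm{TotCable}$,
where TotCable is distance-to-shore plus a 4 km shore-to-grid run, with AC
coefficients below 60 km of total cable and DC at or beyond. Two choices
deserve note: (i) the 60 km switch is compared against *TotCable*, not raw
distance to shore — the cable, not the shoreline range, is what is
physically AC or DC; (ii) the coefficient pairs and the electricity price
are not physical constants and are required configuration. The shipped
defaults (AC 0.81 $M/MW, 1.36 $M/km; DC 1.09 $M/MW, 0.89 $M/km; 0.2 $/kWh;
10 $M per turbine; 5% availability loss) follow the offshore-wind valuation
documentation lineage this model reimplements and should be revisited for
any real procurement context.

# Cumulative seabird sensitivity

Species-level vulnerability separates a *collision* channel,
$a\,(m + t + n)/3$ — flight altitude $a$ gates the whole term because a
bird that never flies at rotor height cannot collide — and a *displacement*
channel, $(d \cdot h \cdot c)/10$; overall sensitivity is the worse of the
two. The bundled table carries the final ranked integer values (1–5) for 21
Atlantic species; the trait formulas are exported and tested for use with
full trait tables.

The cumulative surface is, per cell,
$$\frac{1}{B}\sum_{b=1}^{B} \log(\mathrm{density}_b + 1)\times \mathrm{value}_b .$$

Choices here:

* **Log base** is natural (configurable). The transform tames the heavy
  right tail of seabird density surfaces; the +1 offset keeps empty cells at
  exactly zero.
* **Weights** are the ranked integer values 1–5, not the raw channel
  scores; the raw-score path exists for trait-table inputs but the ranked
  values are the default because that is what the bundled table provides.
* **Partial nodata**: by default $B$ counts the species with data in each
  cell (mean over available species); a strict mode propagates nodata
  instead. The available-species mean avoids discarding a cell because one
  minor layer is clipped, at the cost of comparing cells averaged over
  different species sets — the strict mode exists precisely for when that
  cost is unacceptable.

Species matching between a density catalog and the sensitivity table is
case-insensitive and prefers scientific names; unmatched species are
reported with a reason, never silently dropped. On the bundled 27-species
catalog this yields 21 matched and 6 dropped.

# Monthly cetacean sensitivity

No OWED-specific sensitivity index exists for most cetaceans, so
conservation status stands in for sensitivity: NatureServe ranks map to a
1–100 score (G1 = 100, G2 = 75, G3 = 51, G4 = 26, G5 = 1). Two-rank codes
(G3G4 etc.) take the floor of the midpoint of their flanking anchors — a
rule inferred because it reproduces all four bundled intermediate values
(87, 63, 38, 13) exactly; supplying a full lookup table overrides it. Guild
scores are arithmetic means of member scores, and a guild modelled as one
density surface is algebraically identical to a pseudo-species carrying
that mean (asserted in the tests).

The aggregate monthly surface z-scores each species' densities, weights by
its score $c_s$, averages across species, and min–max rescales to [0, 1]:

* **Scope of the z-score and of the rescale** is the species' *full
  spatiotemporal stack* (all valid cells × 12 months), not month-by-month.
  The per-site monthly profile is only meaningful if January and July are
  on the same scale; per-month standardisation would erase exactly the
  seasonal signal the timing recommendation needs. This is the single most
  consequential interpretation choice in the module and is therefore a
  function default rather than a hard-coded behaviour.
* **Standard deviation** is the population form (divide by $N$),
  configurable; at grid-scale $N$ the difference from the sample form is
  negligible but the choice is pinned for reproducibility.
* **Zero-variance species** cannot be z-scored; they contribute 0 to the
  species sum (with a warning) and still count in $S$, so adding an
  uninformative species dilutes rather than distorts.
* **Low-density mask**: cells whose all-species, all-months total sits
  strictly below the 1st percentile of cell totals are masked. Ties at the
  threshold are *kept*, so a uniform region can never mask itself; on a
  surface with a genuinely sparse tail the rule removes the intended ~1%.

`best_month()` is the argmin of the 12-month profile, ties broken to the
earliest month and flagged — a tie means the data do not distinguish
months and the flag should prompt a human look.

# The tradeoff simulation

Cells with negative NPV are excluded as unviable; over the remaining cells
both axes are min–max rescaled to [0, 1]. Because of this normalisation all
utilities are *relative to the study area*: enlarging or shrinking the
extent changes every value, which is why the extent is part of the run
configuration and recorded in the run log.

The utility $u = a\,W - (1-a)\,B$ is simulated over the default grid
$a = 0, 0.1, \dots, 1$ (11 values spanning "conservation only" to "profit
only") and averaged. For this symmetric grid the average collapses to
$\bar u = (W - B)/2$ exactly — the simulation machinery exists for
asymmetric stakeholder-elicited grids, and the closed form doubles as a
1e-15 oracle in the tests.

Concern classes follow the 20%/60% quantile convention of seabird
vulnerability mapping: quantiles are empirical (type-7 linear
interpolation) and threshold ties go to the higher-concern class — the
inclusive reading of "top 60%", conservative for conservation. Quadrants on
the tradeoff plane: "avoid" is the bottom 20% of profitability *or* the top
20% of sensitivity; "preferred" excludes the 60% least profitable and the
60% most sensitive; boundaries are inclusive toward caution.

**Selected sites and quadrants can disagree.** Because
$\bar u = (W-B)/2$, a cell with *both* axes low (a windless cell with no
birds) or one axis extreme (the windiest cell despite high sensitivity) can
carry top-20% utility while sitting in the avoid quadrant of one axis. No
universal "sites are never in the avoid quadrant" property exists when the
axes are spatially correlated, as they are on a coast where wind and birds
both increase northward. What does hold, and what the tests assert, is
directional enrichment — selected sites average lower sensitivity and
higher profitability than the study area — plus exact recovery on the
planted-optimum scenario, whose constructed region dominates both axes and
is always classified preferred.

Site extraction takes the top-20% utility cells, labels 8-connected regions
(diagonal contact connects, matching contour-like hotspots), and takes each
region's peak cell; plateau ties break to the northernmost then westernmost
cell and are flagged. Ranks are dense ranks of the site's utility among
*all* valid cells, so rank 62 means 61 distinct utility values beat the
site somewhere in the study area — the same convention as ranking selected
sites against the full surface in published tradeoff tables.

# The synthetic generator

The generator emulates the structural features the pipeline must handle,
with fixed defaults chosen once as field-plausible:

* 60 × 40 grid of 10 km cells, land along the western column;
* Weibull $k = 2$ everywhere, $\lambda$ rising from 6 m s⁻¹ at the
  south-west coast by 0.005 m s⁻¹ per km offshore and 0.002 per km
  northward (≈ 6–9.3 m s⁻¹ at 10 m reference height), plus 0.1 m s⁻¹
  Gaussian noise;
* six seabird species with log-normal densities (sdlog 0.5) around
  north-high exponential gradients, weighted 5, 5, 4, 3, 2, 1;
* four cetacean analysis units: one migratory G1 species whose anisotropic
  Gaussian concentration (along-coast sd 150 km, cross-shore sd 120 km,
  centred 100 km offshore) follows a piecewise-linear coastal path —
  south end in January, passing mid-coast in March, far north in July,
  mid-coast again in November — over a small resident floor with 10%
  log-normal noise; and three residents (G4, G3, G5) whose fields are
  constant across months. Monthly variation in the aggregate is therefore
  driven by the migrant, and a mid-coast cell shows the two-peaked
  (March/November) profile with a mid-summer trough.

The generator's ground truth comes from its own geometry, not from the
pipeline: the trough month at a latitude is the month whose plume centre
lies farthest from it. The known-optimum variant raises one offshore
region's $\lambda$ to 15% above the background maximum and multiplies its
bird densities by 0.01, so the region dominates both tradeoff axes by
construction and the true utility argmax lies inside it.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: spatial autocorrelation structure beyond
smooth gradients, inter-species density correlation, survey-effort
artefacts, coastline geometry more complex than a straight edge, and any
statistical realism for particular species. The end-to-end tests show the
machinery recovers a planted signal; they say nothing about the ecological
fidelity of any input surface.

# Numerical choices and degenerate inputs

* Quantiles: `stats::quantile` type 7 throughout; classification ties go to
  higher concern.
* Distances: planar Euclidean between cell centres in projected km — the
  analysis grid is equal-area and study-scale, so geodesic corrections are
  noise; target cells are 0 by construction.
* Raster I/O: ESRI ASCII grids written at full double precision
  (`%.17g`), so finite values round-trip bit-compatibly; the projection
  descriptor and geographic anchor travel in a `.prj` sidecar.
* Degenerate inputs fail loudly: constant wind samples (zero variance),
  all-negative NPV ("no viable sites"), empty target masks, non-finite
  monthly profiles, unknown NatureServe codes.
* Constant aggregate stacks cannot be rescaled and error; constant
  per-species stacks warn and contribute zero.

# Problem sizes

The shipped tests run small grids (5×5 to 20×15) for unit oracles, a
48 × 16 scenario for pipeline properties, and the full 60 × 40 scenario for
20 end-to-end replicates of planted-optimum recovery; the Monte-Carlo wind
oracle uses 10⁶ draws and the Weibull-recovery check 5 × 10⁴ samples. The
entire suite completes in well under a minute on one core; these sizes were
chosen as the smallest at which every property is sharply testable.

# Known limitations

* Wake and array losses, depth-dependent foundation costs, market price
  curves and lease pricing are out of scope of the valuation.
* Cetacean sensitivity is conservation status, not a dose–response model of
  acoustic impact; the best-month recommendation minimises the aggregate
  score, not a per-species take estimate, and should never be read as
  clearing a month of endangered-species presence.
* Inputs must be pre-aligned to one grid; there is no reprojection.
* The relative normalisation means utilities are not comparable across
  study areas.
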