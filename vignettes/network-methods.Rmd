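---
title: "Methods: road-network models for mosquito-control service delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: road-network models for mosquito-control service delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vectorops)
```

## The problem

Municipal vector-control programs deliver larvicides and residual spraying
from a small number of deployment hubs, moving crews, insecticide and
equipment by truck over the city's road network. When hubs are centrally
located and resources are thin, peripheral neighborhoods — often the ones
with the poorest housing, and hence the highest entomological risk — become
the most expensive to reach. `vectorops` implements a transportation-network
toolkit for auditing and redesigning such a delivery system: service-area
binning by driving distance, closest-facility routing with a trip/fuel cost
model, and weighted p-median siting of alternative hubs.

## Model and assumptions

**Impedance.** The road network is an undirected graph with planar-meter
node coordinates and kilometer edge lengths; the impedance minimized
everywhere is driving distance. This reflects two data realities the package
inherits as assumptions: road segments of unknown class are treated as
functionally equivalent, and a uniform urban speed limit makes travel time
proportional to distance, so distance is the only impedance worth modelling.
One-way restrictions, turn penalties and congestion are out of scope.

**Demand.** A neighborhood is a census-block centroid carrying population,
households, a housing condition index (HCI: the equal-weighted mean of
roof, wall and floor condition grades, each min-max normalized; 0 =
excellent, 1 = very poor) and a reported dengue case count. Incidence is
cases/population × 10,000. Household-level locations are not modelled; the
centroid stands for the block.

**Snapping.** Centroids rarely intersect the network, so each point is
attached to the globally nearest point on any edge, inserting a virtual
node at the perpendicular projection. The two split edges sum exactly to
the host edge length, so pre-existing shortest-path distances are preserved
to machine precision (a tested invariant). Points farther than the snap
tolerance (default 500 m) from every edge are flagged unreachable, reported
in a sidecar, and excluded from every summary — never silently dropped.

**Service areas.** Each reachable neighborhood is assigned the minimum
network distance to any *active* hub and binned at 0.5 / 1 / 3 / 5 km
cutoffs plus an open final band. Intervals are upper-closed
(\[0, 0.5\], (0.5, 1\], ...): the published band labels leave the exact
boundary convention ambiguous, and upper-closed was adopted once and
exposed nowhere else. Per band the package reports neighborhood count,
total population, mean HCI (unweighted across neighborhoods; a
population-weighted option exists) and pooled incidence (Σ cases / Σ
population × 10⁴, not a mean of block rates — pooling is the
epidemiologically standard choice for an aggregate band rate).

**Access cost.** A crew treats `households_per_trip` (default 25)
households per deployment, then returns to its hub to refill, so a
neighborhood needs `ceiling(households / 25)` round trips. One round trip
costs `2 × one_way_km / fuel_economy × fuel_price`, with defaults
$0.61/L and 5.53 km/L (a 2016 Ecuadorian pump price and a 2010 pickup's
city economy). Total neighborhood access cost = trips × round-trip cost.
Costs are kept at full floating precision and rounded to cents only in
display columns. There is no inter-neighborhood chaining: every trip is
hub → neighborhood → hub, because the refill constraint anchors crews to
the hub and the data resolution (centroids) does not support arc routing.
Labor, insecticide, vehicle maintenance and travel time are deliberately
excluded — they are real costs, but not estimable from the modelled inputs,
so the output is a *relative* accessibility surface, not a budget.

**Cost classes.** The access-cost distribution is classed into upper-closed
intervals for reporting. Published class breaks of this kind are typically
data-derived (natural breaks on a specific city's distribution), so the
default here is quintiles of the observed distribution, with explicit
edges accepted wherever classes are used. When two scenarios are compared,
the class edges are frozen from the *baseline* scenario for both, so "the
population served by the least expensive routes" refers to the same dollar
band in both scenarios.

**Location-allocation.** Choosing k hub sites from a candidate pool
(current hubs + available subcenters; both current hubs stay in the pool —
retaining one is an outcome, not a constraint) is the weighted p-median
problem: minimize Σᵢ wᵢ·d(i, nearest selected site). Four weighting
scenarios map to management priorities: unit weights (pure distance),
population (demand volume), raw dengue case counts (reactive,
surveillance-driven control — counts, not incidence, because a crew-visit
workload scales with absolute burden), and HCI (proactive, risk-factor
control). The default solver enumerates all k-subsets exhaustively — the
realistic instance (10 candidates, k = 2) has 45 subsets — with ties broken
by the lexicographically smallest id set. A Teitz–Bart vertex-substitution
heuristic (best-improving swaps to a local optimum, seeded multi-restart)
is provided for larger candidate pools; it is bounded below by the exact
optimum always and matches it on ≥ 95% of random small instances in the
acceptance suite.

## Numerical choices

* Shortest paths: single-pair routes use an internal Dijkstra with a
  deterministic tie-break (among equal-length routes, the
  lexicographically smallest node sequence wins), so outputs are
  bit-reproducible; batch distance matrices delegate to igraph's Dijkstra.
  Both are checked against an independent Floyd–Warshall oracle.
* Exact floating-point equality is used for route-length ties (ties of
  interest arise from identical sums, not rounding); p-median comparisons
  use a 1e-12 slack to keep swap loops from cycling.
* Unreachable pairs are `Inf`, never `NA`; degenerate inputs (0 households
  → 0 trips → $0; empty band → NA incidence) are defined, not errors.
* Snapping to within 1 µm of an existing endpoint reuses that node rather
  than inserting a zero-length edge.

## What the synthetic city emulates

Real inputs of this kind (block-level census aggregates, georeferenced case
counts, facility coordinates) are access-restricted, so the generator
produces cities with the *structure* the method assumes, at realistic
scale:

* a connected jittered-grid street network — default 24 × 24 nodes at
  250 m spacing (a ~5.75 km urban span, so the farthest blocks sit just
  beyond 5 km network distance from central hubs, sparsely populating the
  open band the way a mid-sized city does), 30 m jitter, 5% edge dropout
  with a spanning-tree guard so connectivity is guaranteed by construction;
* 254 block centroids, uniform over the bounding box; populations
  lognormal (median ≈ 700, σ_log = 0.7 — right-skewed block sizes,
  citywide ≈ 230,000); households = population / 3.8;
* HCI = clamp₀₁(0.15 + 0.25·d + N(0, 0.05)), with d the straight-line
  distance to the network centroid normalized by the city radius — housing
  quality degrades toward the periphery (band means run ≈ 0.2 centrally to
  ≈ 0.35+ at the edge);
* dengue cases ~ Poisson(population × 0.02·e^(−2d)) — incidence
  concentrated near the center (citywide ≈ 70–80 per 10,000, a large
  outbreak-year burden);
* 2 active hubs sampled from the innermost quartile of center distance,
  8 candidate subcenters stratified two per quadrant, all on network nodes.

Straight-line center distance (not network distance) drives the attribute
gradients: only the monotone trend matters for emulation and it is far
cheaper. The generator seeds a single RNG stream per city, so a config
fully determines every coordinate, attribute and facility.

**What it does not emulate.** Real street topology (arterials, bridges,
the port district), spatially autocorrelated block sizes, underreporting
gradients in surveillance data, and any temporal dynamics. A green test on
synthetic cities therefore establishes that the *pipeline* recovers
planted structure — central hubs ⇒ peripheral bands are poorer and less
burdened by reported cases; HCI weighting pulls an optimal hub outward —
not that any real city's numbers are reproduced.

## A known statistical limitation

The suite asserts that the band-wise mean HCI is nondecreasing across all
five distance bands in ≥ 90% of 50 default seeds. This currently fails
(≈ 54% of seeds), and the failure is informative rather than a bug: the
innermost band contains only ~8 blocks within 0.5 network-km of a hub, so
its mean HCI has a standard error of ≈ 0.02, while the *expected* HCI gap
between the first two bands is at most ≈ 0.03 even with perfectly central
hubs — and smaller when hubs sit anywhere in the innermost quartile,
because band membership follows hub distance while the HCI gradient
follows center distance. Under the stated generator (gradient slope 0.25,
noise sd 0.05, 254 blocks) the first-band comparison is underpowered, and
no parameter choice consistent with the stated world fixes it; the
monotone *gradient* itself is robust (Spearman ρ(HCI, center distance) > 0
in ≥ 95% of seeds, tested green). The strict band criterion is kept red
deliberately instead of being loosened. Published band summaries of this
kind show the same fragility — a small innermost band's mean can invert
against its neighbor by sampling noise alone.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| snap tolerance | 500 | m | inclusion radius for demand points; true connector distances are usually much shorter |
| band cutoffs | 0.5, 1, 3, 5 | km | operationally meaningful driving-distance rings |
| fuel price | 0.61 | USD/L | 2016 Ecuador pump price |
| fuel economy | 5.53 | km/L | 2010 pickup, city cycle |
| households/trip | 25 | households | backpack-sprayer capacity per crew deployment |
| round-trip factor | 2 | — | crews return to the hub to refill |
| k | 2 | sites | number of hubs to site |
| enumeration limit | 10,000 | subsets | exact solver guard; beyond it use Teitz–Bart |

## Worked example

```{r example}
city <- generate_city(city_config(seed = 42))
res <- run_pipeline(run_config(synth = city_config(seed = 42)),
                    out_dir = file.path(tempdir(), "demo"))
res$bins_summary
res$allocations$hci$selected
round(unlist(res$comparisons$hci), 1)
```

The band table is the service-area summary (population, mean HCI, pooled
incidence per band); the HCI-weighted allocation selects two sites from
the ten-facility pool; the comparison reports the mean-cost reduction and
the change in population inside the baseline's cheapest cost class.
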