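---
title: "Modeling structural wildlife connectivity with corridornet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling structural wildlife connectivity with corridornet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corridornet)
```

## The problem

Protected-area networks only function if animals can move between
reserves. Direct evidence of movement (GPS collars, ground surveys) is
expensive and slow, so a cheap first pass is to assess *structural*
connectivity: is there a swath of natural land cover joining each pair of
reserves, or has anthropogenic conversion (cropland, settlement) cut it?
`corridornet` implements that assessment as a pipeline over a single
input: a binary raster in which each ~1 km cell is natural (0) or
converted (1). The output is a classified corridor network — which
linkages are open, which are severed, which low-protection reserves act
as stepping-stones, and which reserves are isolated.

Structural connectivity is a statement about land cover, not about
animals. The package's validation stage ties the land-cover model to
reported wildlife movement, but a corridor called "open" here is a
candidate for movement, not evidence of it.

## Cost surfaces

Each cell gets a traversal cost. Natural cells cost 1. Converted cells
cost `base_cost` ∈ {10, 100, 1000}; the three values span uncertainty
about how strongly converted land resists large-mammal movement
(an order of magnitude per step). A focal mean over a k × k window
(k ∈ {3, 5, 7, 9}) optionally spreads conversion's influence into
neighboring natural cells, spanning uncertainty about the *spatial scale*
of impact. The factorial {3 base costs} × {unsmoothed + 4 neighborhoods}
yields 15 surfaces; slicing corridors at 4 widths (below) yields the
60-model candidate set.

Numerical choices:

* At grid edges the focal mean divides by the number of in-bounds cells,
  so an all-natural grid stays exactly 1 and an all-converted grid stays
  exactly `base_cost` everywhere. This matches the behavior of the
  desktop-GIS focal-statistics tools the method is modeled on and keeps
  every surface within [1, `base_cost`].
* Large water bodies are **barriers**, not resistances: masked cells
  become non-traversable (`NA`) and take precedence over any conversion
  cost. Barrier cells are excluded from focal windows entirely rather
  than entered as 1 or `base_cost`, so no artificial cost leaks across
  shorelines. The order — smooth, then mask — is an interpretive choice;
  the alternative (mask before smoothing) differs only in cells whose
  window touches water, and the slicing stage is insensitive to it in
  the landscapes simulated here.
* Near-future conversion is projected with a 3 × 3 focal maximum: every
  natural cell adjacent (8-neighborhood) to a converted cell is
  reclassified converted — the precautionary assumption that land nearest
  the agricultural frontier converts first.

## Cost-weighted distance and corridors

Movement is modeled on the 8-connected grid graph. The link between
adjacent cells *i*, *j* costs ((v~i~ + v~j~)/2) · d~ij~ with d~ij~ the
cell size for rook moves and √2 times it for diagonals, so accumulated
distances are in *weighted km*: a route entirely through natural land
accumulates its geometric length, and crossing costly cells multiplies
length by cost. `cost_distance()` computes the multi-source Dijkstra
field from a rasterized reserve polygon (cells whose centers fall
inside); `corridor_raster()` adds the fields from the two reserves and
subtracts the least-cost-path cost, so each cell holds the extra weighted
km incurred by routing through it, with 0 exactly on optimal routes.

A diagonal move may not pass between two barrier cells that touch only
at the corner; without this rule, zero-width water gaps would leak
paths. Predecessor backtracking yields the single-cell least-cost path;
its geometric length is the LCP distance, and the reserve-to-reserve
Euclidean distance is measured polygon edge to polygon edge (not
centroid to centroid), consistent with how the severance exception below
uses it.

Corridor *width* is a percentile slice: the lowest `width_percent`
(5/10/15/20) of finite corridor cells, by cell count, with ties at the
cutoff included (so a constant corridor keeps everything and the LCP is
always inside every slice). Reading "lowest x% of cost cells" as a
cell-count quantile is one of two defensible interpretations; the other —
keep cells whose detour is within x% of the path cost — is available as
`slice_corridor(..., method = "cwd_cutoff")`. The cell-count quantile is
the default because it guarantees non-empty, nested slices regardless of
the cost scale.

## Validation and model selection

Validation locations are labeled points: `movement` where local reports
confirm wildlife crossing, `none` where reports deny it, each with a 5 km
buffer (the typical spacing of the interviewed villages the design
emulates). A model captures a location if any sliced corridor cell center
lies within the buffer radius — a circle–point test rather than a
polygon intersection; at 5 km radii over 1 km cells the difference is
sub-cell. The resulting 2 × 2 confusion matrix gives Cohen's kappa; the
model footprint is the union of sliced cells across all scored pairs.

`select_best_model()` implements highest-kappa-then-parsimony: among
models with kappa within `kappa_tolerance` (default 0.05) of the
maximum, take the fewest-cell model. The tolerance default admits a
trade of ~0.03 kappa for a one-third footprint reduction, the kind of
trade this rule exists to make; it is exposed as a configuration knob.
Remaining ties break deterministically (higher kappa, smaller
neighborhood, lower base cost, smaller width) so reruns are reproducible.

## Open/severed classification

The threshold is *derived, not assumed*: a reference corridor known from
ground data to be severed provides its cost-weighted distance (CWD) and
Euclidean distance (EuD) as the rule. A corridor is

1. **open** if CWD < the reference CWD (strictly — the reference itself
   classifies severed);
2. otherwise **open** if EuD > the reference EuD *and* it does not cross
   converted land — the long-distance exception, which prevents
   corridors from being called severed on account of length alone;
3. otherwise **severed**.

"Crosses converted land" is judged on the single-cell least-cost path by
default; judging it on the full sliced swath is available via
`crossing = "corridor"`. The LCP reading is the default because the
exception asks whether the *best* route is clean, and a wide swath almost
always clips some converted cell. Corridors whose swath threads a third
protected area are dropped (their connectivity is already represented
through that reserve). Two advisory flags never change status: crossing
projected future conversion (open-but-threatened) and crossing a natural
barrier (slope > 10° by Horn's method on the working grid, or permanent
wetland) — barrier permeability is species-specific, so these are
reported, not enforced. Note the 10° threshold is scale-dependent: slopes
computed on a 1 km grid are gentler than on the 30 m grids where such
thresholds originate, so on synthetic terrain the flag is exercised with
planted ridges of known gradient.

## The network

National parks, nature reserves and game reserves ("high protection")
that share a border with positive length (corner contact excluded — a
point is not a traversable border) merge transitively into complexes.
Nodes are complexes plus standalone lower-protection reserves; edges are
the retained classified corridors (dropped ones excluded, at most one
edge per node pair). A node with no open and no contiguous edge is
isolated. A lower-protection reserve is a *stepping-stone* when open
corridors connect it — as an endpoint or by transiting its polygon — to
at least two distinct high-protection nodes; only the open subgraph
counts, since a severed link confers no function. Endpoint and transit
roles both qualify and are distinguished in the output.

## The synthetic landscape generator

No public land-conversion raster or interview dataset accompanies the
method, so the generator builds study regions with known ground truth:

* Background conversion grows as rook random-walk blobs from random
  seeds until a target fraction of background cells is converted —
  spatially autocorrelated patches like an agricultural frontier, not
  salt-and-pepper noise. The default fraction (0.15) represents a
  heterogeneous frontier region: substantial conversion pressure while
  mostly natural.
* Reserves are rectangles, forced natural. Planted corridors are carved
  natural *after* the background; planted blockage bands are laid
  *after* the corridors, so ground truth holds whatever the random
  background did.
* In the demonstration landscape (`demo_landscape_spec()`), three
  reserve pairs with geometrically identical 59 km gaps sit in
  compartments separated by full-height water channels. Carved corridors
  are 11 cells wide — wider than the largest focal neighborhood — so
  corridor interiors cost exactly 1 on every surface, and the planted
  conversion alone fixes the CWD ordering open < reference (1-cell band)
  < blocked (3-cell band) on all 15 surfaces. The water compartments let
  each blockage truly sever its pair (no detour around the band) without
  touching the other compartments, and keep corridor slices from
  wandering into third reserves.
* Positive validation points are midpoints of village pairs straddling
  the open corridor (village spacing 5 km, matching the buffer radius);
  negative points are rejected until they lie ≥ 2 × buffer radius from
  every planted corridor and a buffer-plus-margin clear of the direct
  inter-reserve gap regions. The labels are therefore noise-free by
  construction.

What passing tests on these landscapes show — and what they do not:
recovery of planted structure demonstrates the machinery (distance
fields, slicing, kappa scoring, threshold classification) is correct,
under conditions where the truth is unambiguous. Real interview data are
noisy, villages are not uniformly spaced, real conversion is not
blob-random, and real reserves are not rectangles; kappa values near 1
on synthetic data say nothing about the kappa attainable in the field.

## Problem sizes and costs

The test suite works at the scale the design needs, not larger: oracle
equivalence uses 100 random 15 × 15 surfaces against a plain edge-list
Dijkstra (tolerance 1e-9 per cell), 100 random 20 × 20 grids against a
double-loop focal mean (1e-12), and 1000 random confusion matrices
against the kappa formula (1e-12). Parameter recovery runs the full
pipeline on twenty 200 × 200 landscapes (seeds 1–20), requiring the
planted open/blocked statuses back in at least 19 and a selected-model
kappa ≥ 0.8. A single 200 × 200 pipeline run (15 surfaces × 3 pairs)
takes a few seconds; the distance kernel is compiled (Rcpp), everything
else is vectorized R.

## Known limitations

* Costs are isotropic and species-agnostic; no directional or
  species-specific permeability.
* Circuit-theory current maps are out of scope by design; the method is
  least-cost throughout.
* Grids are treated as planar with constant square cells; geographic
  (degree) grids should be projected upstream.
* The generator plants rectangular reserves and straight corridors;
  irregular geometries exercise the geometry helpers through the
  GeoJSON interface but not the generator.
* One corridor per reserve pair per analysis; braided multi-route
  corridors appear only through corridor widths.
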