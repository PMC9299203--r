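---
title: "Methods: range-and-regulation Red List assessment for insular habitat specialists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: range-and-regulation Red List assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventrisk)
```

## The assessment model

`ventrisk` assesses extinction risk for species whose entire biology is
tied to tiny, widely separated habitat patches — deep-sea hydrothermal
vent fields being the motivating case: individual fields are smaller than
0.1 km², a species rarely occupies more than ten of them, and the single
overriding threat (seabed mining) destroys all local habitat wherever it
happens. Population sizes and trends are unknown, so the assessment rests
on two pillars only:

* the **geometry of the range** — how many sites, how tightly clustered,
  how much area; and
* the **regulatory regime** governing each part of that range — because
  for a threat that is an industrial licensing decision, regulation *is*
  the threat model.

The pipeline is deterministic: the same records and regime table always
produce the same category, and every intermediate (locations, metrics,
threat flags, per-criterion tiers) is exposed for audit.

### Locations

An IUCN location is the area over which one threatening event can rapidly
affect all individuals. Mining plus its sediment plume motivates a
geodesic separation threshold, `threshold_km` (default **80 km**): sites
within one management area whose chain of pairwise gaps stays below the
threshold form one location.

Two readings of "within 80 km of each other" are defensible: pairwise
completeness (every pair below the threshold) or single-linkage
connectivity (chains allowed). `cluster_locations()` implements
**single-linkage**, the precautionary reading — fewer, larger locations,
consistent with a disturbance propagating along a ridge segment. A
distance *exactly* equal to the threshold separates (the threshold is a
minimum separation; membership requires strictly less). The threshold is
a tunable because plume spread depends on sediment, depth and currents;
no region-specific defaults are shipped.

Ties in presentation are broken deterministically: locations are ordered
by their lexicographically smallest member `site_id` and numbered
`L01, L02, …` in that order.

### Area of occupancy

AOO uses the standard 2 × 2 km grid (`cell_km = 2`): each occupied cell
contributes 4 km², multiple sites in one cell count once. The standard
fixes the cell size but not the grid origin, so anchoring is a design
choice; `compute_aoo()` projects sites into a local equirectangular plane
(standard parallel at the coordinate centroid, longitudes re-centred by
circular mean) and anchors the grid with a **cell centre at the projection
origin**. Centre-anchoring matters: with a cell *corner* at the centroid,
any two close sites symmetric about their own midpoint would straddle an
edge and a 0.5-km pair would count 8 km² instead of 4 — the opposite of
the same-cell rule. At vent-range scales the equirectangular plane
distorts distances by far less than a cell width, which is all the
snapping step needs.

### Extent of occurrence

EOO is the minimum convex polygon over the sites, computed in a Lambert
azimuthal equal-area projection about the site centroid (area on this
plane equals spherical area, so the hull's shoelace area is exact up to
the sphere model itself). Longitudes are re-centred before projection, so
ranges spanning the antimeridian — common in the southwestern Pacific —
do not wrap. Degenerate hulls (one site, two sites, collinear sites) have
zero area; following standard guidance, **EOO is floored at the AOO**,
which also keeps single-field species assessable (EOO = AOO = 4 km²
rather than 0). An externally published EOO can be injected via the
`eoo_km2` argument of `assess_species()` — used when an assessment's
printed value should take precedence over approximate fixture
coordinates — and is floored the same way.

All distances are haversine on a sphere of radius **6371.0088 km** (IUGG
mean). Ellipsoidal corrections are below 0.6%, which is noise against an
80-km threshold chosen to one significant figure.

### From regulation to threat

Each management area carries one regime token, in increasing severity:
`PROTECTED_EFFECTIVE` < `UNPROTECTED_NO_LICENSE` < `EXPLORATION_LICENSE`
< `ACTIVE_MINING`. The mapping to IUCN concepts is:

| flag | rule |
|---|---|
| continuing decline (b(iii)) | any location licensed or mined — exploration contracts permit test extraction, so decline is already projected |
| plausible future threat | any location not effectively protected |
| all range destroyed | active commercial mining at *every* location |

"Effective" protection requires regulation that specifically prevents
seabed mining (an enacted moratorium, a treaty, an MPA with a mining
ban). A *proposed* moratorium or a generic MPA does not qualify and must
be encoded as `UNPROTECTED_NO_LICENSE` — the package deliberately gives
proposals no weight, since a published assessment can only be revisited
once protection is real (and then only after the five-year rule).

### Criteria and category

For each tier (CR, EN, VU), B1 fires iff EOO is below the tier bound
**and** the location count satisfies condition (a) **and** continuing
decline supplies condition (b(iii)); B2 is the same with AOO. Extreme
fluctuations (c) are unavailable for vent fauna, so a listing always
needs both a and b. The bounds (EOO 100/5 000/20 000 km², AOO
10/500/2 000 km², locations 1/5/10, D2: AOO < 20 km² or ≤ 5 locations)
are the v3.1 standard constants, held in `threshold_table()` as
configuration.

D2 fires at VU iff the range is very restricted, a plausible threat
exists, and the **worst-case category** — the category under the
hypothetical "every location licensed" scenario, `worst_case_category()` —
is CR. This operationalises "a plausible threat that could rapidly lead
to CR or EX" without a population model.

`assign_category()` takes the highest fired tier. With no tier fired the
package applies one rule: **LC iff no plausible threat anywhere, NT
otherwise**. This single rule reproduces all three published NT contexts
(mixed protected/licensed ranges; unprotected ranges whose worst case is
EN; unprotected species with more locations than any tier bound), so the
package adopts it rather than enumerating sub-cases.

One override sits above the criteria: active commercial mining across the
entire known range forces **CR (possibly extinct)** regardless of fired
tiers, since destruction of all habitat likely extirpates an endemic
before any reassessment. For species with few locations this coincides
with a CR under criterion B and the criteria string is reported as usual;
for a hypothetical widely distributed species (> 10 locations, all being
mined) no range criterion can fire and the assessment carries the
override rationale with an empty criteria string — the one sanctioned
departure from "threatened implies a non-empty criteria string".

### Scenarios and the location-threat matrix

`apply_scenario()` re-runs the engine under regime overrides and reports
the transition. Downlistings are flagged as deferred under the five-year
rule; the flag is metadata — the engine never suppresses the computed
category, because assessment dates are the assessor's business, not the
algorithm's.

`build_matrix()` tabulates category against location-count band (1, 2–5,
6–10, > 10; representatives 1, 3, 8, 12 — interior points of the tier
bounds) and regime row. Every cell is produced by running the full engine
on a canonical synthetic species (single-field locations strung along a
meridian at 1.25 × the threshold, so EOO/AOO stay far below the tier
bounds, as vent geometry dictates); the matrix is a *view* of the engine,
never an independent lookup table. The MIXED row licenses half the
locations (rounded up) and protects the rest. Cells corroborated by
published assessments are tagged `text-confirmed`, the remainder
`engine-derived`. For monotonicity checks the MIXED row is ordered
between `PROTECTED_EFFECTIVE` and `EXPLORATION_LICENSE`: it contains
licensed locations and hence a continuing decline, so it is strictly more
severe than an unlicensed-but-unprotected range in decline terms even
though part of its range is protected.

## The synthetic generator

`generate_synthetic_ridge()` emulates the along-ridge geometry of vent
systems: clusters of fields with jittered spacing (default mean 20 km)
separated by long gaps (default 200 km), management-area boundaries cut
at fractional positions along the ridge, regimes cycled over the areas.
Because placement is constructive — intra-cluster gaps validated below
the location threshold, inter-cluster gaps above it — the generator
returns the true location partition, making it an exact oracle for the
clustering step. The spec of a run (`synthetic_ridge_spec()`) requires an
explicit seed; there is no hidden global state.

What it does *not* emulate: bathymetry, larval-dispersal connectivity,
off-axis vent fields, detection failure (real surveys miss sites), or
taxonomic uncertainty. Passing tests on synthetic ridges therefore
demonstrate the geometry-to-category machinery, not robustness to survey
incompleteness — though the published worked examples suggest the
framework is insensitive to added localities precisely because regulation
dominates the outcome.

## Fixtures and validation choices

The four curated fixtures (two protected East Scotia Ridge fields; the
single licensed Longqi field; four southwestern Pacific fields across
three EEZs; three Manus Basin fields forming one location) use
approximate published vent-field positions — the source assessments print
categories, AOO and in one case EOO, but no coordinate tables. Tests
therefore assert categories, location counts and AOO (which depend only
on coarse geometry), and carry the one published EOO (171.23 km²) as an
input rather than recomputing it from approximate coordinates.

Test problem sizes, chosen to exercise the combinatorics while keeping
the default suite fast: 1 000 random instances of up to 50 sites for the
clustering-equals-transitive-closure property; 30 random hulls of up to
50 sites against an independent geodesic polygon-area routine (agreement
within 0.1%); the exhaustive category grid over 12 location counts × 5
regime patterns × EOO/AOO values straddling every tier bound, checked
against an independently coded flat decision table.

## Known limitations

* Sites are points; polygon footprints, license-polygon overlay and any
  spatial reasoning below the management-area level are out of scope —
  regimes are declared per management area, matching assessment practice.
* Criteria A, C, D1 and E are deliberately unimplemented; the framework
  is exactly as applicable as range-plus-regulation data are.
* The regime model is a present-tense snapshot: no temporal histories, no
  probabilistic weighting of regulatory futures.
* The 80-km threshold is a precautionary constant, not a plume model;
  adjust `threshold_km` per region as evidence accumulates.
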