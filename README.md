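# ventrisk

Rapid, reproducible IUCN Red List extinction-risk assessment for species
endemic to small, insular habitat patches — built around deep-sea
hydrothermal vent fields threatened by seabed mining.

## The problem

Vent-endemic species are textbook "data poor": there are no population
estimates, no temporal trends, and no basis for quantitative extinction
modelling, which rules out IUCN criteria A, C, D1 and E. What *is* known is
where a species occurs and how each part of the seabed is regulated. That
is enough for the two remaining criteria:

* **Criterion B** (geographic range): a threatened tier requires a small
  extent of occurrence, EOO (B1), or area of occupancy, AOO (B2), *plus*
  two of three subconditions — here, few locations (a) and a continuing
  decline in habitat extent/quality (b(iii)); extreme fluctuations (c) are
  not relevant for sessile vent fauna.
* **Criterion D2** (very restricted): VU when AOO < 20 km² or ≤ 5
  locations *and* a plausible future threat could rapidly drive the
  species to CR or extinction.

`ventrisk` operationalises this for assessors:

1. **Locations.** An IUCN *location* is an area over which one threatening
   event (a mining operation plus its sediment plume) can rapidly affect
   all individuals. Occurrence sites are clustered single-linkage within a
   management area using a geodesic threshold (default 80 km, haversine on
   a sphere of radius 6371.0088 km).
2. **Range metrics.** AOO on the standard 2 × 2 km grid (one 4 km² cell
   per occupied cell, deterministic centroid-centred anchoring); EOO as
   the minimum convex polygon in a Lambert azimuthal equal-area plane
   about the site centroid, floored at the AOO.
3. **Threat.** Each management area carries one of four regulatory
   regimes — `PROTECTED_EFFECTIVE`, `UNPROTECTED_NO_LICENSE`,
   `EXPLORATION_LICENSE`, `ACTIVE_MINING`. Exploration or active mining
   anywhere in the range implies a projected continuing decline; anything
   short of effective protection implies a plausible future threat.
4. **Category.** Criteria B1, B2 and D2 are evaluated against the v3.1
   tier bounds (EOO 100/5 000/20 000 km²; AOO 10/500/2 000 km²; locations
   1/5/10) and the highest fired tier wins; with no tier fired, a fully
   protected range is LC and anything else NT. Commercial mining across
   the entire range forces CR (possibly extinct).

A scenario engine re-assesses species under regulatory change (flagging
downlistings for the five-year rule), and a location-threat matrix
summarises the whole decision surface. A synthetic ridge-system generator
produces occurrence data with a constructively known location partition
for validation.

## Worked example

A mussel known from three vent fields in the Manus Basin, all within 80 km
of each other inside one licensed exclusive economic zone, with a
published EOO of 171.23 km²:

```r
library(ventrisk)
fx <- case_study_fixtures()$b_manusensis
assess_species(fx$fields, fx$regimes, eoo_km2 = 171.23)
#> Bathymodiolus manusensis: EN B1ab(iii)+2ab(iii)
#> Range metrics: 3 field(s), 1 location(s), AOO 12 km^2, EOO 171.23 km^2
#> Threat: decline=TRUE, plausible=TRUE, 1 threatened / 0 protected location(s)
#>  - B1 met at EN: a: n_locations=1; b(iii): projected decline in extent/quality of habitat
#>  - B2 met at EN: a: n_locations=1; b(iii): projected decline in extent/quality of habitat
```

The three fields collapse into a single location and occupy three grid
cells (AOO = 12 km²). Because EOO (171.23) and AOO (12) exceed the CR
bounds of 100 and 10 km², the species is endangered rather than
critically endangered — the canonical "EN rather than CR" outcome for a
multi-field single location.

The full decision surface:

```r
build_matrix()
#> Location-threat matrix (category by band x regime):
#>   ACTIVE_MINING            CR*   CR*   CR*   CR*
#>   EXPLORATION_LICENSE      CR    EN    VU    NT
#>   UNPROTECTED_NO_LICENSE   VU    NT    NT    NT
#>   MIXED                    CR    EN    VU    NT
#>   PROTECTED_EFFECTIVE      LC    LC    LC    LC
#>   bands: 1, 2-5, 6-10, >10  (* possibly extinct)
```

## Command line

```sh
inst/scripts/ventrisk fixtures --out fix
inst/scripts/ventrisk assess --occurrences fix/occurrences.csv \
    --regimes fix/regimes.csv --out out
inst/scripts/ventrisk matrix --out out
inst/scripts/ventrisk scenario --occurrences fix/occurrences.csv \
    --regimes fix/regimes.csv --scenario fix/scenario_d_subfusca.json --out out
inst/scripts/ventrisk simulate --n-fields 18 --n-clusters 3 --seed 7 --out sim
```

`assess` writes one JSON assessment (plus a plain-text rationale block)
per species and a summary table of categories and criteria; `--threshold-km`
and `--cell-km` override the geographic defaults.

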