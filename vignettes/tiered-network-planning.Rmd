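---
title: "Planning a tiered national CD4 testing network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning a tiered national CD4 testing network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiernet)
```

## The planning problem

A national HIV programme needs CD4 counts for every patient entering or
monitored on antiretroviral therapy. Testing is cheapest in large
centralized laboratories, but samples from remote clinics then travel
hundreds of kilometres, and turnaround times (TAT) blow past the 24–48 hour
window in which treatment algorithms expect a result. Point-of-care (POC)
devices solve the distance problem at several times the per-test cost.

`tiernet` implements the planning calculus behind an integrated tiered
service delivery model that balances these forces with six service tiers,
classified purely by daily test volume:

| Tier | Role | Daily volume | Instrument capacity/day | USD/test |
|------|------|--------------|-------------------------|----------|
| T1 | on-site POC at a remote ART clinic | ≤ 10 | 10 | 32.32 |
| T2 | POC-hub consolidating ~8–10 clinics within 10–20 km | ≤ 40 | 30 | 15.88 |
| T3 | community laboratory | ≤ 150 | 150 | 7.42 |
| T4 | district laboratory | ≤ 300 | 384 | 6.24 |
| T5 | metro/centralized laboratory | > 300 | 768 | 5.37 |
| T6 | national reference/coordination (no testing cost) | — | 1536 | — |

All of these numbers live in a single `tier_schedule()` object; every one is
overridable from a YAML/JSON config, and the defaults are the published
reference values above. Volume breaks are normalized to inclusive upper
bounds — the source descriptions mix strict and non-strict inequalities, and
a single consistent rule (`T1 = (0,10], T2 = (10,40], …`) keeps
classification a well-defined step function. Clinic counts per tier are
deliberately an *annotation*, not a constraint: the published clinic-load
descriptions for tier 3 are mutually inconsistent (≤40 vs 11–50 vs "up to
100"), so volume alone decides the tier and `clinic_count_consistent` merely
flags unusual combinations, with the tabulated 11–50 range as the default.

## The pipeline

`itsdm(facilities, labs)` chains the five analysis stages; each is also a
standalone exported function.

**Coverage.** Each facility is assigned to its nearest testing laboratory
(`assign_nearest()`), and a facility is *covered* when that laboratory is
within the service-precinct radius (default 100 km). The source analysis
drew "Euclidian" 100 km radii on a projected map; at 100–400 km scales the
defensible reading is geodesic distance, so the default metric is haversine
on the IUGG mean-radius sphere (6371.0088 km), with an equirectangular
planar option (`metric = "planar"`) for comparison with planar buffers. Ties
are broken by smallest laboratory id so the assignment is reproducible.
Coverage is reported both facility-weighted (the published "~10% of clinics
uncovered" is this flavour) and volume-weighted, because the two diverge
exactly where planning decisions are hardest — remote districts have many
low-volume clinics.

**Tiering.** Assigned annual volumes are converted to daily demand at 260
working days/year (5-day weeks; configurable, since primary-care clinics
often operate 4-day weeks) and classified. `capacity_check()` compares
installed instrument capacity to demand — positive margins are expected and
deliberate (growth and disaster-recovery redundancy); negative margins are
flagged. `build_support_graph()` links every T1/T2 site to its nearest T3+
laboratory, the "parent" responsible for quality control, training and
maintenance; `superlab_candidates()` finds connected clusters of T4/T5
laboratories within one radius of each other whose combined demand exceeds
600/day — candidates for consolidation into a single super-laboratory.

**Placement.** The published siting of new tiers was manual map inspection.
`propose_sites()` formalizes it as greedy maximal covering: candidates are
existing general-pathology laboratories (cheap hosts for T2/T3 services)
plus the uncovered facilities themselves (T1). Each step picks the candidate
covering the most still-uncovered facilities (ties: larger covered volume,
then smaller id), with its tier set by `classify_tier()` on the volume it
would absorb; a candidate whose absorbed volume is hub-scale (≤ T2) only
consolidates clinics within the 20 km hub radius. Greedy was chosen over
exact set cover or p-median deliberately: it is transparent, deterministic
and auditable, mirrors the manual process it replaces, and its (ln n + 1)
approximation guarantee is verified in the test suite against exhaustive
optima on small instances. `min_gain = 2` by default, so a single isolated
clinic becomes on-site T1 rather than a dedicated hub — exactly the T1 role.
Note one interface subtlety: under `min_gain = 2` a candidate that would
mop up a single remaining facility is never opened; cover-equivalence
comparisons therefore run with `min_gain = 1`.

**Costing.** The expansion arithmetic is exact. Volumes are apportioned by
largest remainder (`allocate_volumes()`), so per-tier integers always sum to
the national total; money is handled in integer cents, so totals are exact
and order-independent, and rounding happens only in printed reports. Two
scenarios are built in: `scenario_full_itsdm()` costs each tier's allocation
at its own rate; `scenario_widespread_poc()` is the counterfactual in which
the whole 15% extension volume is tested at the T1 POC rate. With the
default schedule (3.9 M tests, shares 2/3/10/15/70%):

```{r cost}
full <- scenario_full_itsdm()
poc <- scenario_widespread_poc()
full$total_usd
poc$total_usd
compare_scenarios(poc, full)
```

The saving decomposes algebraically as
$V_{T2}(c_1 - c_2) + V_{T3}(c_1 - c_3)$ — only the volumes diverted from POC
pricing into tiers 2 and 3 matter — and the test suite asserts this identity
exactly. One source inconsistency is handled explicitly: the published ZAR
saving (R125,009,280) does not equal the published USD saving times the
published R11/USD rate (R127,979,280). The package always reports the
computed product; the ">R125 million" headline bound still holds.

**TAT.** `summarize_tat()` bands districts by the fraction of samples whose
laboratory TAT (registration to authorization) beats a threshold (default
48 h, 24 h strict mode). The published legend's band edges have small gaps
(34–35%, 80–86%); they are normalized to contiguous edges [35, 85, 95] so
every fraction maps to exactly one band.

## The synthetic network generator

Real facility GPS registries and warehouse TAT extracts are confidential,
so the generator builds networks with the same statistical anatomy, and the
geographic results in this package are *emulation*, not reproduction.
Defaults (all in `network_config()`):

* 52 districts on a jittered grid over a South-Africa-sized extent
  (lat −34.8…−22.1, lon 16.5…32.9), grouped into 9 provinces by proximity;
  ~15% of districts metropolitan.
* 4,756 facilities, allocated to districts with metro weight 6 and
  log-normal district-size heterogeneity (sdlog 0.7) — facility counts track
  population density, so remote districts are sparse. Within a district,
  facilities mix a tight town cluster (sd 0.06°) with rural scatter
  (sd 0.2 of a grid cell ≈ 40 km).
* Category mix 19% mobile / 4% satellite / 65% PHC / 1% CDC / 5% CHC /
  5% district hospital / 1% regional hospital.
* Volumes: log-normal draws (sdlog 1.5) times category multipliers
  (hospitals ≫ mobile clinics, tuned so primary-care-type facilities send
  roughly two thirds of national volume) times a metro boost, apportioned by
  largest remainder to **exactly** 3,900,000 tests/year. The resulting tail
  spans <5 to >17,000 tests/year.
* 65 CD4 laboratories: the 14 lowest-volume non-metro districts get none
  (cross-border referral), every other district gets one, and the remaining
  labs follow volume. 195 general-pathology-only laboratories (260 labs in
  total) cover all districts and act as placement candidates.

The rural scatter and district-size dispersion were calibrated once, by a
seed sweep, so that ~10% of facilities fall outside 100 km precincts
(9.6–12.6% across seeds here) — the published coverage gap — and then
frozen. What the generator does *not* emulate: real road networks and
drive times, population rasters, HIV prevalence surfaces, or the actual
shape of South African districts. Consequently passing tests demonstrate
the correctness and stability of the *methods* on paper-like inputs, not
agreement with the real network: the published counts of proposed sites
(22/22/21 new T1/T2/T3) and the 15% decentralized volume share depend on
real geography and are not targets. On synthetic defaults the decentralized
tiers absorb ~4–8% of national volume, because synthetic uncovered
facilities are predominantly low-volume rural clinics.

### Turnaround model

No transport-time model was published, so the TAT simulator is this
package's own construction, calibrated only to the qualitative remote
district contrast (pre-analytic median >15 h at ~400 km referral falling
below 5 h with a local laboratory, overall laboratory TAT <18 h).
Pre-analytic time is `base + distance/speed + U(0, batching interval)` with
defaults 0.5 h, 30 km/h effective courier speed, 5 h batching. Laboratory
time is a log-normal processing draw (median 6 h, sdlog 1.0) plus two
structural delays: samples arriving after the 16:00 receiving cutoff wait
for the 08:00 opening — the mechanism by which distance degrades
*laboratory* TAT, keeping the district banding responsive to geography
without conflating legs — and demand above capacity adds a proportional
overload penalty.

```{r tat}
net <- generate_network(network_config(seed = 1))
fit <- itsdm(net$facilities, net$labs)
fit
```

## Numerical choices and degenerate inputs

* Money: integer cents throughout; unit costs are stored as exact cent
  integers (`round(usd * 100)`).
* Apportionment ties (equal fractional remainders) go to the earlier tier;
  assignment and parent ties (within 1e-9 km) to the smaller id.
* Zero-demand laboratories classify as T1 with a warning rather than
  erroring — registries legitimately contain newly opened sites.
* Missing `annual_volume` becomes 0 with a warning (conservative for
  capacity planning); malformed coordinates, duplicate ids and unknown
  categories are hard errors with row numbers.
* Empty uncovered sets produce an empty plan, not an error.

## Known limitations

Assignment is nearest-distance only — capacity is reported, never enforced
as a constraint, mirroring the source analysis. There is no
budget-constrained or multi-analyte placement, no drive-time isochrones,
and no ingredient-level costing (capital, staffing, maintenance): the cost
model is exactly the per-test schedule, which is what the published
scenario comparison uses. Problem sizes in the examples and tests (full
4,756-facility networks, small oracle instances up to 50 facilities) run in
seconds on a single CPU.
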