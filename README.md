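# tiernet

Planning toolkit for **tiered national diagnostic testing networks**, built
around CD4 laboratory services for large HIV treatment programmes.

National programmes face a structural trade-off: centralized laboratories
test cheapest per sample, but remote clinics then wait days for results;
point-of-care (POC) devices return results locally at several times the
cost. `tiernet` implements the planning calculus of an integrated tiered
service delivery model that resolves this with six service tiers — on-site
POC (T1), POC-hubs (T2), community (T3), district (T4) and metro (T5)
laboratories plus a coordinating reference tier (T6) — classified purely by
daily test volume, with per-test costs falling steeply from USD 32.32 (T1)
to USD 5.37 (T5).

For a facility registry and a laboratory registry it computes:

* **service precincts & coverage** — great-circle (haversine,
  6371.0088 km sphere) nearest-laboratory assignment, covered/uncovered
  status against a 100 km precinct radius, per-district distances,
  over-serviced laboratory pairs;
* **tier classification** — daily demand against the volume breaks
  (10/40/150/300 samples/day, inclusive upper bounds), instrument capacity
  margins, the hierarchical parent-support graph (every T1/T2 site linked
  to its nearest T3+ laboratory), and super-laboratory consolidation
  candidates (>600 combined samples/day within one radius);
* **site placement** — new decentralized T1/T2/T3 sites proposed by
  deterministic greedy maximal covering over general-pathology host
  laboratories, verified against exhaustive optimal covers in the tests;
* **scenario costing** — exact integer-cent arithmetic: largest-remainder
  volume apportionment, per-tier costs, and the comparison of a full tiered
  expansion against the widespread-POC counterfactual (the whole extension
  volume at T1 pricing);
* **turnaround times** — a seeded per-sample TAT simulator (courier +
  batching + laboratory processing with a same-day cutoff) and district
  banding by the fraction of results within 24/48 h.

A seeded synthetic network generator (`generate_network()`) emulates a
country-scale system — 52 districts, 9 provinces, 4,756 facilities with the
published category mix, heavy-tailed volumes summing to exactly 3.9 M
tests/year, 65 CD4 laboratories with 14 laboratory-free districts — so the
whole pipeline is testable without confidential registry data.

## Worked example

```r
library(tiernet)

net <- generate_network(network_config(seed = 1))
fit <- itsdm(net$facilities, net$labs)
fit
#> Tiered service delivery plan
#>   4756 facilities, 65 testing laboratories, 3,900,000 tests/yr
#>   coverage at 100 km: 90.2% of facilities (95.8% of volume)
#>   proposed new sites: 6 hubs/labs + 364 on-site POC
#>   expansion saving (tiered vs widespread POC): $11,634,480 (R127,979,280)
```

About 10% of facilities sit outside every 100 km service precinct; the plan
opens community laboratories/hubs where they pay and leaves isolated
clinics on on-site POC. The cost lines are the national scenario model:

```r
full <- scenario_full_itsdm()     # each tier at its own rate
poc  <- scenario_widespread_poc() # whole extension volume at POC pricing
full$total_usd
#> [1] 25583220
poc$total_usd
#> [1] 37217700
compare_scenarios(poc, full)
#> widespread_poc vs full_itsdm: saving $11,634,480 (R127,979,280)
```

Reading: extending coverage with tiers 2–3 instead of blanket POC testing
costs $25.58 M rather than $37.22 M per year — an $11.63 M (>R125 M)
saving, driven by the unit-cost gap between POC ($32.32) and community
laboratories ($7.42, i.e. 23% of the POC rate, though 38% above the metro
rate of $5.37).

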