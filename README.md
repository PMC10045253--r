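# storknet

Spatial movement networks and valued ERGMs from white stork GPS tracking.

White storks (*Ciconia ciconia*) forage at landfills and then visit
wetlands, rice fields and farmland, physically connecting habitats — and
whatever travels in their guts travels with them. `storknet` turns
high-frequency GPS telemetry of such movements into a spatially explicit
network analysis, for movement ecologists studying habitat connectivity and
biovectoring:

* **trackio** — read Movebank-dialect fix tables, compute per-step
  kinematics (great-circle distance, time difference, speed), apply a
  five-stage quality cascade (winter residency box, September–March season,
  \>4-minute sampling interval, 100 km/h speed ceiling, ≥1000 fixes per
  bird-year) and split records into bird-years.
* **sites** — build network nodes from land-cover polygons: a 14-class
  Corine reclassification, shoreline buffering of wetlands, 10-km
  single-linkage merging of same-habitat polygons, fix-to-node assignment
  and a median bird-year occupancy cutoff.
* **flights** — segment trajectories into *direct flights*: maximal runs of
  fixes at ≥10 km/h bounded by stationary fixes (<10 km/h) in two different
  nodes, with no step longer than an hour; pool them into a weighted
  directed edge list.
* **netmetrics** — in/out strength, betweenness over shortest paths costed
  by centroid distance in metres, and undirected habitat-by-habitat flight
  totals.
* **mapeq** — spatial modules by minimising the two-level map equation
  (deterministic greedy optimiser, seeded restarts).
* **vergm** — valued exponential random graph models with a Poisson
  reference, `P(y) ∝ [Π 1/y_ij!] exp(θᵀg(y))`, with statistics `sum`,
  `nodeofactor`/`nodeifactor` (habitat sources/sinks), `edgecov` (distance
  in km) and `mutuality` (negative absolute difference `−Σ|y_ij − y_ji|`).
  Because every statistic is dyad-pair decomposable, the likelihood
  factorizes over dyads and `storknet` fits by **exact** maximum likelihood
  (truncated dyad partition sums in C++, exact Fisher information, Newton)
  and simulates exactly — no MCMC on either side.
* **synthdata** — seeded generators for habitat landscapes, ground-truthed
  commuting trajectories (5-minute cadence, 10 m GPS noise, transmission
  gaps) and ERGM-distributed networks, so the whole pipeline is testable
  offline.

## Worked example

Simulate a small landscape and two birds for one non-breeding season, run
the pipeline, and model the resulting counts:

```r
library(storknet)

land   <- gen_landscape(landscape_spec(
            n_sites = c("Landfills" = 2, "Marshes" = 2, "Rice fields" = 1),
            seed = 3))
tracks <- gen_tracks(land, movement_spec(n_birds = 2, seed = 11,
                                         gap_per_day = 0))
fixes  <- filter_cascade(tracks$fixes,
                         filter_config(min_fixes_per_birdyear = 100))
fixes  <- split_bird_years(fixes)
nodes  <- merge_nearby(land, site_config(shoreline_buffer_m = 0))
fixes  <- assign_fixes(fixes, nodes)
flights <- extract_direct_flights(fixes)
net    <- build_network(flights_to_edgelist(flights),
                        node_occupancy(fixes, nodes))
net
#> <spatial_network> 5 nodes, 20 valued links, total weight 2014

aggregate_by_habitat(net)
#> # A tibble: 5 × 3
#>   habitat_a habitat_b   weight
#>   <chr>     <chr>        <int>
#> 1 Landfills Marshes       1097
#> 2 Marshes   Marshes        573
#> 3 Marshes   Rice fields    143
#> 4 Landfills Rice fields    131
#> 5 Landfills Landfills       70
```

2014 of the birds' flights connect the five sites; landfill–marsh is the
strongest habitat link, as expected under the generator's landfill-weighted
site choice. Fitting the valued ERGM:

```r
mod <- ergm_model(c("sum", "nodeofactor:Landfills",
                    "edgecov:distance_km", "mutuality"),
                  net$nodes$habitat,
                  covariates = list(distance_km = net$distance_m / 1000))
fit_mle(net, mod)
#> Valued ERGM (Poisson reference), exact dyad-factorized MLE
#> log-likelihood: -104.93466  (converged)
#>
#>  Term                  Estimate SE   z value p value
#>  sum                    7.08    0.06  123.60 < 0.001 ***
#>  nodeofactor:Landfills  1.95    0.11  17.60  < 0.001 ***
#>  edgecov:distance_km   -0.05    0.00 -37.51  < 0.001 ***
#>  mutuality              0.99    0.08  13.12  < 0.001 ***
```

The landfill out-factor of 1.95 means flights *from* landfills are
`exp(1.95) ≈ 7.1` times more frequent than from a default node, all else
equal; each kilometre of distance multiplies expected counts by
`exp(-0.05)`, and the positive mutuality coefficient says reciprocal link
values are strongly favoured. `coefficient_multiplier()` prints these
interpretations directly.

A command-line wrapper over the same functions lives at
`inst/scripts/storknet`:

```sh
storknet full-pipeline --config pipeline.cfg --seed 4 --out-dir out/
```

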