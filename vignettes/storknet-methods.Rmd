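---
title: "From GPS fixes to habitat networks: the storknet methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GPS fixes to habitat networks: the storknet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(storknet)
```

## The problem

White storks (*Ciconia ciconia*) forage opportunistically at landfills and
then visit wetlands and farmland, carrying whatever their guts carry —
plastics, antibiotic-resistant bacteria, seeds. Quantifying which habitat
patches their non-stop flights connect turns a conservation question into a
network question: sites become nodes, direct flights become weighted directed
links, and the topology can be summarised (centrality, modules, habitat-level
totals) and modelled (which habitats act as sources and sinks of flights,
once distance and reciprocity are controlled for).

`storknet` implements that pipeline end to end for Movebank-dialect GPS
telemetry, together with a synthetic landscape/trajectory/network generator
so that every stage can be validated against known ground truth without any
data download.

## Filtering telemetry into bird-years

The quality cascade runs five stages, in a fixed order:

1. **Winter residency.** A bird is retained if the median of its
   December–February positions falls inside the winter box (latitude
   30.0–42.5°N, longitude 10.0°W–3.5°E). The median-position test is this
   package's operationalisation: it is insensitive to brief excursions and
   needs no home-range machinery. Birds with no December–February fixes are
   dropped — they did not winter in the box.
2. **Season.** Only September–March fixes are kept. A *bird-year* is one
   individual's fixes within one such season; January–March fixes belong to
   the season started the previous calendar year ("3029-2017" runs from
   September 2017 to March 2018).
3. **Sampling interval.** A greedy forward scan keeps a fix only if it is
   more than 4 minutes after the last kept fix, standardising multi-rate
   tags to a common cadence. Fixes arriving after 61 minutes or more are
   *kept but flagged* as segment starts: deleting them would discard all
   data after every transmission gap, whereas flagging lets the flight
   extractor refuse to bridge the gap (the one-hour rule below). This is the
   one place where the cascade's verbal description admits two readings; the
   retain-and-flag reading preserves the data while enforcing the same
   gap semantics downstream.
4. **Speed.** Trajectory speed is the great-circle distance over the time
   difference of consecutive fixes, attributed to the later fix (the
   "incoming" convention, which the flight segmentation relies on). A
   forward relinking sweep drops any fix whose speed from the last *kept*
   fix exceeds 100 km/h. The sweep removes a displaced spike without
   sacrificing its innocent successor — deleting all fast fixes at once
   would take both, since the successor's incoming step is fast too — and a
   single pass is already a fixed point (a second pass is run as a guard).
5. **Volume.** Bird-years with fewer than 1000 fixes are dropped as likely
   tag failures or early mortality.

Kinematics are recomputed after stages 3 and 4. Great-circle distances use
the haversine formula with mean Earth radius 6371.0088 km throughout.
Timestamps are treated as UTC with no timezone arithmetic.

## Sites, nodes and occupancy

Habitat polygons carry one of 14 classes (three urban, three agricultural,
five artificial-wetland, three natural-wetland), obtained from Corine Land
Cover codes via a fixed reclassification; ambiguous codes (422 salines vs
fish aquaculture; 512 lakes vs dams vs irrigation ponds) default to the
first label unless an explicit override is supplied, and code 131 (mineral
extraction) is treated as landfills, which are routinely misclassified that
way.

Wetland polygons are buffered outward along the shoreline (default 200 m —
a package default, configurable; shorelines are favoured stork habitat).
Buffering is a Minkowski sum with a disk computed in a local Lambert
azimuthal equal-area projection; corner arcs are discretised with 16
segments, exact for convex rings and slightly under-buffering at reflex
corners. Same-habitat polygons whose boundaries come within 10 km are merged
into one node by single-linkage clustering; boundary distance is
approximated by sampling each perimeter at most every 100 m. Node ids are
assigned deterministically by centroid latitude then longitude, and
centroids are area-weighted, computed in the local equal-area projection.

A bird-year *uses* a node if at least one of its fixes falls inside it
(point-in-polygon on WGS84 coordinates; boundary points count as inside;
overlaps after buffering resolve to the smallest node id). The occupancy
cutoff is the median bird-year count over candidate nodes at or below
latitude 38°N — the core wintering area — applied network-wide; for an even
number of candidates the *lower* middle value is taken (the conservative
choice, retaining more nodes). An explicit override reproduces a known
cutoff such as six bird-years.

## Direct flights and the spatial network

A fix is *stationary* when its incoming speed is below 10 km/h, *flying* at
or above it (the threshold itself counts as flying; the first fix of a
segment has no incoming speed and counts as stationary). A maximal run of
flying fixes bounded by two stationary fixes becomes a **direct flight**
when the bounding fixes lie in two different nodes, every step inside the
bounded run — including the two bounding steps — is at most 60 minutes, and
no transmission-gap boundary interrupts the run. Node crossings at flying
speed do not split a flight: a stork passing over a site without stopping
does not create a link to it. Pooling flights over all bird-years yields the
directed edge list, weighted by flight counts.

Network metrics follow the standard weighted-digraph definitions: in/out
strength are column/row sums of the weight matrix, and betweenness counts
minimum-cost paths with edge cost equal to the great-circle distance between
node centroids in metres — flight counts deliberately do not modulate the
cost, and the scores are left unnormalized. Habitat-level networks sum
flights over unordered habitat pairs; same-habitat totals are reported as
self-links, and grand totals are available both with and without them.

## Map-equation modules

Spatial modules minimise the two-level map equation
\(L(\mathsf{M}) = q H(Q) + \sum_m p_m H(P_m)\):
the expected per-step description length of a random walk under a two-level
code, where \(q\) is the total module-exit flow and each module's codebook
covers its nodes' visit rates plus its exit rate. Visit rates come from
power iteration of the weighted walk with uniform teleportation
\(\tau = 0.15\) (dangling nodes teleport uniformly; convergence at an L1
change below \(10^{-12}\)); exit flows include the teleportation flow
leaving each module. Optimisation is greedy agglomeration — seeded
single-node moves to neighbouring modules until no move reduces the
codelength, followed by greedy merges of connected modules, restarted from
10 seeded shuffles — rather than simulated random walks: the objective is
identical, the optimiser deterministic given a seed. On instances small
enough to enumerate every partition the greedy search attains the exhaustive
minimum (this is tested), but like all map-equation optimisers it carries no
global guarantee, and module counts on real data are optimiser-dependent.

## The valued ERGM

Flight counts are modelled by an exponential random graph model with a
Poisson reference measure:

\[
P(y) \;=\; \Big[\prod_{i \ne j} \tfrac{1}{y_{ij}!}\Big]
           \exp\big(\theta^\top g(y)\big) \,/\, Z(\theta),
\]

with statistics: the **sum** of all counts (the intercept), **nodeofactor**
(counts leaving nodes of one habitat — landfills as the source of interest),
**nodeifactor** (counts entering nodes of one habitat — the wetland sinks),
an **edge covariate** (the centroid distance matrix, in kilometres, so a
coefficient is per km), and **mutuality** as the negative absolute
difference \(-\sum_{i<j} |y_{ij} - y_{ji}|\), which rewards reciprocal link
values. Coefficients act log-linearly: \(\exp(\theta)\) multiplies the
expected count per unit of the statistic.

Every one of these statistics depends on a dyad only through
\((y_{ij}, y_{ji}, |y_{ij}-y_{ji}|)\), so the likelihood factorizes over
unordered dyads. `storknet` exploits this for **exact** inference instead of
MCMC maximum likelihood: each dyad's partition function

\[
Z_{ij} = \sum_{a,b \ge 0}
  \frac{\exp(a\,\eta_{ij} + b\,\eta_{ji} - \theta_m |a-b|)}{a!\,b!}
\]

is evaluated by truncated summation in log space (C++ kernel), with caps of
at least \(\max(30,\ \lambda + 10\sqrt{\lambda} + 10)\) where
\(\lambda = e^{\eta + |\theta_m|}\), a boundary-mass check guaranteeing a
relative tail below \(10^{-10}\), and doubling on failure. First and second
moments of \((a, b, |a-b|)\) accumulate in the same pass, giving the exact
gradient and the exact Fisher information (each statistic is dyad-linear, so
per-dyad covariances map through a constant \(p \times 3\) matrix). The MLE
is found by Newton iterations with step halving — the log-likelihood is
concave, so five to ten iterations from \(\theta = 0\) suffice — and
standard errors are the inverse Fisher information's diagonal, with
two-sided normal p values and no multiple-testing correction. Simulation is
exact too: per-dyad inverse-CDF draws from the same truncated pmf, which is
what makes the parameter-recovery experiments clean (no sampler error on
either side).

Limitations are the flip side of the factorization: statistics that couple
more than one dyad (triangles, stars on values) are out of scope and
rejected explicitly, as are non-Poisson references.

## The synthetic generator

The generator is deliberately minimal — a two-state commuting model, not a
behavioural simulation — because its purpose is to exercise every filter and
the segmentation automaton under known ground truth:

* **Landscape**: non-overlapping 24-gon sites (radius 300–800 m) placed by
  rejection sampling in a bounding box in the core wintering latitudes;
  default separation at least 12 km so each site becomes its own node under
  the 10-km merge.
* **Movement**: birds alternate dwells (log-normal, median 3 h, SD 0.6 on
  the log scale, clamped at 15 min so consecutive transits are always
  separated by a stationary fix — without the clamp two back-to-back trips
  could merge into one apparent flight and ground-truth equality could not
  hold even noiselessly) and straight transits at a constant speed drawn
  uniformly from 25–60 km/h, destination chosen with probability
  proportional to habitat preference (landfills weighted 3:1 by default)
  times \(e^{-d/20\text{km}}\). Fixes arrive every 5 minutes with ±30 s
  jitter, Gaussian position noise (σ = 10 m, the tags' average accuracy),
  and an optional transmission-gap process (probability 0.05 per day of a
  2–24 h outage).
* **Ground truth**: every transit is logged (origin, destination, times) and
  aggregated into a trip-count matrix.

At σ = 10 m and a 5-minute cadence, dwell-phase displacements are of order
2σ, implying apparent speeds far below 1 km/h — two orders of magnitude
under the 10 km/h flight threshold — so noise cannot masquerade as flight.
What the generator does **not** emulate: soaring circling (intermediate
speeds), diel rhythm, altitude, position-error outliers beyond Gaussian
noise, or migratory corridor structure. Passing the recovery tests therefore
shows the pipeline is correct under its stated definitions, not that those
definitions are robust to every pathology of real telemetry.

The ERGM generator materialises a habitat inventory and uniform 2–200 km
symmetric distances, then draws counts exactly. Two regional presets mirror
the study system: a 34-site southern-Spain configuration (5 landfills, 3 of
each of the eight wetland classes, 5 terrestrial default sites) and a
31-site northern-Morocco configuration without fish aquaculture, irrigation
ponds, dams or salines, which are absent from that region's network.

## Numerical choices, in one place

* Haversine with R = 6371.0088 km; distances to the betweenness module in
  metres, to the ERGM in kilometres (both fixed conventions).
* Sampling-interval thinning keeps fixes strictly more than 4 minutes after
  the last kept fix; 60-minute gaps are admissible inside a flight, 61
  minutes and above open a new segment.
* Stationary is strictly below 10 km/h; exactly 10 km/h is flying.
* Lower-median convention for even occupancy counts; threshold computed on
  the ≤ 38°N subset, applied network-wide.
* Map equation: τ = 0.15, L1 tolerance 1e-12, 10 restarts, improvement
  threshold 1e-12 bits; ties in node ordering broken by seeded shuffle.
* ERGM: truncation tolerance 1e-10, all sums in log space, Newton with up
  to 30 step-halvings, gradient stopping rule scaled by |log-likelihood|.
* Equal-cost shortest paths are compared by the graph library's exact
  arithmetic; test fixtures construct exact ties by equatorial symmetry.

## Validation scale

The test suite validates against brute-force oracles at small sizes
(exhaustive path enumeration up to 8 nodes, all 4140 partitions of 8 nodes,
double-loop statistics at 5 nodes, double-sum partition functions to cap
200) and runs the parameter-recovery experiment at the regional scale it
targets (20 replicates of 34- and 31-node networks, a few minutes on one
CPU). The trajectory ground-truth checks use 2 birds over one season on a
5-site landscape (~120k fixes), which already exercises every cascade stage
and the segmentation automaton; the generator scales linearly if larger
scenarios are wanted.
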