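---
title: "Species-flow networks: model, estimation and design choices"
author: "sfhon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-flow networks: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfhon)
```

# The problem

Commercial ships move aquatic organisms between ports through two vectors:
**ballast water** (organisms pumped aboard with stabilizing water and
discharged elsewhere) and **biofouling** (organisms attached to the hull).
Given port-call records, ship metadata, port environments and a marine
biogeography, the package estimates the probability that nonindigenous
species (NIS) spread between every ordered pair of ports, and asks how that
risk propagates along *multi-leg* ship itineraries: a ship that loads ballast
in port C and discharges some of it in A and the rest in E creates an
indirect C-to-E pathway that a first-order (pair-by-pair) network misses.

Three network models are implemented and compared:

* **SF-FON** — first-order network; edges are the aggregated pairwise risks.
* **SF-HON** — higher-order network; nodes are ports *conditioned on recent
  visiting history* (for example `p2|p0,p1`), created only where the data show
  a statistically significant, recurrent dependency.
* **All-Paths** — a baseline that connects every ordered pair of visits along
  each full trajectory, with no significance filtering.

# The voyage-level risk model

The spread risk between ports $i$ and $j$ is a product of three independent
probabilities:

$$P(\text{spread})_{ij} = P(\text{nonindigenous})_{ij}\times
  P(\text{establish})_{ij}\times P(\text{intro})_{ij}.$$

**Nonindigenous indicator.** Ports in the same or neighbouring marine
ecoregions share native species pools, so the indicator is 0 there and 1
otherwise. The ecoregion neighbour graph is an input (`read_ecoregions()`).

**Establishment.** A Gaussian in the environmental differences,
$\alpha\,e^{-\frac12[(\Delta T/\delta_T)^2+(\Delta S/\delta_S)^2]}$ with
$\alpha = 1.5\times10^{-4}$, $\delta_T = 2\,^\circ$C, $\delta_S = 10$ ppt.
$\alpha$ caps every spread probability: pair risks are small numbers, and all
comparative statements in the package are about their *relative* structure.

**Introduction, biofouling.** Per voyage:
$A^{(t)}\,(\beta_1 d^3 - \beta_2 d^2 + \beta_3 d)\,e^{-\gamma v}$, where $d$
is the stay (days) at the source port, $v$ the voyage velocity (km/day,
great-circle distance over duration), $A^{(t)}$ the share of the ship's type
operating without an antifouling system (Container 0.19, Auto 0.20, Tanker
0.30, Passenger 0.31, Bulk 0.42, General 0.53, all other types 0.60), and the
cubic's coefficients depend on the *source port's* climate zone — tropical
within 35 degrees of the equator (boundary inclusive), temperate poleward.
The accumulation cubic is a fit on a proportion scale and exceeds 1 for very
long stays (tropical $d \gtrsim 430$ days), so it is clamped into $[0,1]$;
`clamp_accumulation = FALSE` exposes the raw fit for diagnostics. The decay
constant $\gamma = 0.008$ per (km/day) is used exactly as published even
though it implies very low survival at typical commercial speeds; override
`gamma` if your velocities are in other units.

**Introduction, ballast.** Per voyage:
$\rho\,(1-e^{-\lambda D})\,e^{-\mu\,\Delta t}$ with discharge volume $D$
(observed if available, otherwise a per-type coefficient times gross weight
tonnage), transit time $\Delta t$ (days), mortality $\mu = 0.02$/day and
uptake $\lambda = 3.22\times10^{-6}$ per m$^3$. $\rho$ is a
ballast-water-management factor kept exactly as the model defines it
(multiplying risk; default 1 = no management modelled). The per-type discharge
coefficients are **synthetic defaults** — plausible orders of magnitude, not
survey estimates — and should be replaced via the config for real analyses.

**Aggregation.** All voyage probabilities for one ordered pair combine as a
union of independent Bernoulli events, $1-\prod_v(1-p^{(v)})$, computed in
log space (`log1p`/`expm1`) so that thousands of tiny terms lose no
precision.

Defaults for every constant live in `default_params()`; a YAML/JSON config
(`read_params()`/`write_params()`) overrides any subset.

## Kinematics and trajectory conventions

Dates are ISO 8601; durations are fractional days with a configurable floor
(default 0.5 day) so same-day voyages have finite velocity. Distances are
haversine on a 6371 km sphere. A ship's stay at the source port is the gap
between its previous arrival there and the sail date; the first record of a
ship (or a gap in coverage) uses a configurable default (7 days). Self-loop
voyages are excluded from risk and trajectories. Trajectories are split into
maximal *continuous* segments whenever a ship's next source differs from its
previous destination: this keeps reconstruction lossless (the consecutive
visit pairs of all segments are exactly the non-self-loop voyages), which a
single per-ship sequence cannot guarantee on gappy data.

# Higher-order rule extraction

A *rule* is a context (the ship's recent ports, oldest to current) plus a
next port, carrying the spread probability of the context-plus-next path
under the edge-risk union
$P_S = 1-\prod_{(i,j)\in S}(1-p_{ij})$ — for the worked example, a rule
$P(\{p_0,p_1,p_2\to p_3\}) = 0.5$ becomes the edge
$p_2|p_0,p_1 \to p_3$ with weight 0.5.

**Which contexts deserve extra history?** The path-risk union is monotone:
prepending a port can only raise $P_S$, typically by an $O(1)$ relative
amount whenever the prepended edge carries any risk. A rule that extends
whenever the path risk rises "significantly" therefore extends essentially
*every* frequent context, regardless of whether ship behaviour actually
depends on the longer history; memoryless traffic would sprout thousands of
spurious higher-order nodes. What distinguishes a genuine dependency is that
the *next-port distribution* changes when the history is extended. The
default criterion is accordingly a likelihood-ratio (G) test of the extended
context's empirical next-port distribution against its parent context's
distribution, with the extension accepted at `alpha = 0.001`, and a
higher-order rule emitted for a next port only when that port's own share
also shifts (1-df G test at the same level). Extension also requires
`min_support` (default 5) traversals and respects `max_order` (default 5).

The `alpha` default comes from a pre-registered power calculation at the
scales the package targets (tens of ports, $10^4$–$10^5$ voyages): under
memoryless traffic with pair supports around 25, the context G statistic is
roughly $\chi^2$ with (ports − 1) degrees of freedom, so `alpha = 0.001`
admits on the order of one spurious context per few hundred tested, and the
additional per-next test removes most of those; a planted dependency with
boost 0.9 and support $\gtrsim 20$ yields G statistics several times the
critical value. Alternative criteria are available: `"kld"` (the
divergence-vs-$k/\log_2(1+N)$ rule of the original higher-order-network
framework) and `"relative"`/`"absolute"` path-risk change with a threshold,
which implement the monotone criterion literally for comparison.

**Wiring.** Each rule's context becomes a node `current|older,...`; the edge
target is the highest-order existing node for the next port whose context is
a suffix of the extended history, falling back to the first-order node, so
walks remain history-consistent. Rules with zero path risk are kept
structurally but their zero-weight edges are excluded from risk outputs.
Because several nodes can map to one physical port, `collapse_to_ports()`
combines parallel edges per ordered port pair (default: Bernoulli union) and
gives each port an in-risk; `port_in_risk()` zero-fills ports the network
never reaches so that models are compared over a common region set.

**Baselines.** `build_fon()` wires the pairwise risks directly.
`build_all_paths()` adds one Bernoulli term per ordered index pair along
every trajectory (optionally span-bounded; default unbounded), so its weight
for any pair always dominates the first-order weight — the mechanism behind
its systematic over-prediction.

# Network statistics

`graph_stats()` reports node/edge counts, average degree $|E|/|V|$, the
directed clustering coefficient (neighbourhood = union of in- and
out-neighbours; numerator counts directed edges; nodes with fewer than two
neighbours score 0), density in two conventions — `as_printed`
($2|E|/|V|^2$, the published formula) and `directed_standard`
($|E|/(|V|(|V|-1))$) — betweenness on edge lengths $1/w$ (inverted transfer
probabilities; $-\log w$ available), normalized by $(n-1)(n-2)/2$ with
endpoints excluded, the centralization $2\sum_i(C'_{max}-C'_i)/(n-1)$ exactly
in the published form, and weak/strong component counts. Note the published
density convention halves the usual directed denominator, and the published
network tables cannot be reconciled with either convention exactly; both are
therefore exposed rather than silently corrected. Realm-level flow matrices
average collapsed pair risks over ordered cross-realm port pairs (absent
pairs as 0, self-pairs excluded) and min-max normalize; a constant matrix is
degenerate and reported as zeros with a flag.

# Flow clustering

Communities of quick-and-easy species flow are found by minimizing the
two-level map equation. Visit rates come from power iteration of the
out-weight-normalized walk with teleportation 0.15 (tolerance $10^{-12}$,
at most $10^4$ iterations; dangling nodes redistribute uniformly);
teleportation is used only to make the stationary distribution well defined
and is not counted as inter-module flow. The optimizer is a seeded greedy
scheme — local moves over adjacent modules followed by module aggregation,
repeated to a fixed point, best of `n_restarts = 10` — which is exact enough
at package scale (hundreds of nodes) and bit-reproducible for a given seed.
Because higher-order nodes of one port can land in different modules, ports
acquire multi-cluster membership; `membership_report()` quantifies the share
of multi-cluster ports and the port coverage of the largest clusters.

# Evaluation against introduction records

Region-level observed risk is the min-max-normalized count of first NIS
introductions per region. Model risk per region is the *mean* of the per-port
in-risks over the region's ports (summation saturates regions at 1 and the
median collapses them toward 0), min-max scaled per model. Fit is mean
squared error over regions; models are compared by a paired two-tailed
t-test on per-region squared errors (zero-variance differences are flagged,
with p reported as 1 when the differences vanish), and a direction report
gives the share of regions over- versus under-estimated (ties count as
neither). Scaling is per model; a shared scaling across models is available
via `rescale_predictions = FALSE` after scaling externally.

# The synthetic world

Every statistical claim in the test suite runs on synthetic data from
`synth_config()`/`gen_scenario()`: ports on a latitude grid in contiguous
ecoregion bands nested in realms (temperature decreasing with absolute
latitude, salinity uniform in a configurable range), a typed fleet with
lognormal tonnage, trajectories from a first-order base chain with optional
per-port attractiveness weights and transition biases, *planted* higher-order
dependencies (when a ship's recent ports match a planted context, the next
port is the planted target with the boost probability), and introduction
counts generated from the true region risk (scale 1000, truncated Gaussian
noise). The generator's truth (`true_port_risk()`) mirrors the collapsed
higher-order semantics: first-order pair risks for all traversed pairs,
unioned with the path risk of each realized planted dependency at its target
port — computed from generator-side knowledge, never from an estimator.

`hub_scenario_config()` freezes the reference world used by the end-to-end
tests: 40 ports, 5 ecoregion bands, 2 realms, 8 regions, 120 ships, 12000
voyages, four planted second-order rules. Its three deliberate features
emulate the regimes in which the three models genuinely differ:

* **Heavy-tailed attractiveness** (busy hub region, quiet equatorial-belt
  ports). With uniform traffic, the All-Paths baseline concentrates indirect
  mass on exactly the ports that already dominate the truth, and after
  min-max scaling it *under*-predicts; with a quiet belt shared by both
  profiles, the scaled comparison is anchored consistently and the baseline's
  indiscriminate indirect mass shows up as over-prediction, as it does on
  real records.
* **Long (100-call) itineraries** at moderate volume, so All-Paths pair
  unions sit in the concave, partially saturating regime rather than all at
  ~1 (where min-max scaling would only amplify numerical noise).
* **Planted rules on mirror-latitude pairs** across non-neighbouring
  ecoregions, so the planted pathways carry real establishment risk and the
  first-order model's omission of them is visible at region level; pair
  supports at this volume stay above `min_support`, so the higher-order
  network's first-order layer is not truncated relative to SF-FON.

What passing these tests shows — and what it does not. The suite
demonstrates internal correctness (oracle equivalence of every statistic,
exact recovery of planted dependencies, false-discovery control on
memoryless traffic) and that the qualitative model ordering
$\mathrm{MSE}_{\text{SF-HON}} < \mathrm{MSE}_{\text{SF-FON}}$ with
over-predicting All-Paths emerges under realistic traffic structure. It does
not validate the biological parameter values, which are taken as published,
nor does the generator reproduce real-world port-call statistics
(seasonality, liner schedules, trade imbalances); conclusions about real
shipping data require the real records.

# Numerical and degenerate-input conventions

* Probability unions and path risks accumulate in log space; results are in
  $[0,1]$ by construction, and negative zeros are normalized away.
* Duration floor 0.5 day; zero-weight edges are excluded from shortest-path
  traversal (infinite length) and from risk outputs.
* Min-max scaling of a constant vector returns zeros with a `degenerate`
  flag; realm matrices and Pearson correlations report their degenerate
  cases explicitly rather than returning `NaN`.
* Unknown ship types fall back to the `other` antifouling value (0.60) with a
  message; unknown ecoregions are an error, not a silent zero.
* `extract_rules` is deterministic given its inputs; `infomap_cluster` and
  the generator are deterministic given their seeds, and neither disturbs the
  caller's RNG state.

# Known limitations

* Voyage-route environmental exposure is not modelled (risk uses endpoint
  environments only), and partial ballast discharge along multi-leg routes is
  not observed — both inherited from the model's data situation.
* The built-in map-equation optimizer is two-level and exact-search greedy;
  very large networks would need an external Infomap backend behind the same
  interface.
* Betweenness is exact (no sampling); intended for desk-scale networks.
* The discharge-coefficient defaults are synthetic placeholders (see above).

# A complete run

```{r pipeline, eval = TRUE}
cfg <- hub_scenario_config(seed = 1)
sc <- gen_scenario(cfg)
truth <- true_port_risk(sc, vector = "ballast")
obs <- gen_introductions(region_risk(truth$port_risk, sc$ports),
                         noise_sd = 0, seed = 1)

rules <- extract_rules(sc$trajectories, truth$edge_risk)
table(rules$order)

hon <- wire_hon(rules)
fon <- build_fon(truth$pair_risks)
ap  <- build_all_paths(sc$trajectories, truth$edge_risk)

evals <- lapply(list(`SF-HON` = hon, `SF-FON` = fon, `All-Paths` = ap),
                function(g) evaluate_predictions(
                  region_risk(port_in_risk(g, sc$ports), sc$ports),
                  obs, "model"))
sapply(evals, function(e) c(mse = e$mse,
                            mean_error = mean(e$per_region$error)))
```
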