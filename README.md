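# sfhon — species-flow higher-order networks for ship-borne invasion risk

Commercial shipping is the main vector moving aquatic nonindigenous species
(NIS) between ports, through ballast water and hull biofouling. `sfhon`
estimates the NIS spread probability for every ordered pair of ports from
port-call records, ship metadata, port environments and a marine
biogeography, and models how that risk propagates along multi-leg ship
itineraries. It is aimed at invasion ecologists and biosecurity analysts who
want to rank ports, regions and shipping pathways by relative introduction
risk.

## The model

Per ordered port pair, the spread risk is a product of three probabilities:

    P(spread)_ij = P(nonindigenous)_ij x P(establish)_ij x P(intro)_ij

* `P(nonindigenous)` is 0 for ports in the same or neighbouring marine
  ecoregions, else 1.
* `P(establish) = alpha * exp(-1/2 [ (dT/delta_T)^2 + (dS/delta_S)^2 ])` —
  a Gaussian in the temperature and salinity differences
  (`alpha = 1.5e-4`, `delta_T = 2` degC, `delta_S = 10` ppt).
* `P(intro)` aggregates per-voyage introduction probabilities as a Bernoulli
  union `1 - prod(1 - p_v)`. Biofouling voyages use
  `A_type * (b1 d^3 - b2 d^2 + b3 d) * exp(-gamma v)` (antifouling share by
  ship type, climate-zone-specific accumulation over the source-port stay
  `d`, survival decaying in voyage velocity `v`); ballast voyages use
  `rho * (1 - exp(-lambda D)) * exp(-mu dt)` (discharge volume `D`, transit
  time `dt`, `mu = 0.02`/day, `lambda = 3.22e-6`/m^3).

Three networks are built from these risks and the ship trajectories:

* **SF-FON** — the first-order network (edges = pairwise risks);
* **SF-HON** — the higher-order network: where a statistically significant,
  recurrent dependency on visiting history exists, conditioned nodes such as
  `p2|p0,p1` are created, and a rule `P({p0,p1,p2 -> p3}) = 0.5` becomes the
  edge `p2|p0,p1 -> p3` with weight 0.5 (path risk
  `P_S = 1 - prod (1 - p_ij)` over the path's edges);
* **All-Paths** — a baseline connecting every ordered pair of visits along
  each full trajectory, with no significance filtering.

The package also computes directed network statistics (clustering
coefficient, density, betweenness/centralization, components), realm-level
flow matrices, map-equation flow clustering with multi-cluster port
membership, and region-level validation against NIS first-introduction
counts (min-max scaling, MSE, paired t-tests, over/under-prediction shares).
A seeded synthetic-data generator with planted higher-order dependencies
makes the whole pipeline testable without any external data.

## Worked example

A synthetic hub-and-spoke world with four planted second-order dependencies
(`?hub_scenario_config` for the design):

```r
library(sfhon)
cfg <- hub_scenario_config(seed = 1)
sc  <- gen_scenario(cfg)                      # ports, fleet, 12000 voyages
truth <- true_port_risk(sc, vector = "ballast")

rules <- extract_rules(sc$trajectories, truth$edge_risk)
table(rules$order)
#>   1   2
#> 848   4
rules[rules$order >= 2, ]
#>  context next_port order support  probability
#>  P36|P15       P26     2      77 7.085181e-05
#>  P37|P14       P27     2      78 4.998601e-05
#>  P38|P13       P28     2      63 6.601147e-05
#>  P39|P12       P29     2      75 5.121781e-05
```

All four planted dependencies are recovered — context oldest to current, so
the first rule reads "ships that visited hub port P36 and then P15 carry a
7.1e-5 spread probability on to P26" — and no spurious higher-order rules
appear. Wiring and evaluation against noiseless introduction counts generated
from the true risk:

```r
hon <- wire_hon(rules)
fon <- build_fon(truth$pair_risks)
ap  <- build_all_paths(sc$trajectories, truth$edge_risk)
obs <- gen_introductions(region_risk(truth$port_risk, sc$ports),
                         noise_sd = 0, seed = 1)
evals <- lapply(list(`SF-HON` = hon, `SF-FON` = fon, `All-Paths` = ap),
                function(g) evaluate_predictions(
                  region_risk(port_in_risk(g, sc$ports), sc$ports), obs, "m"))
round(sapply(evals, function(e)
  c(mse = e$mse, mean_error = mean(e$per_region$error))), 5)
#>             SF-HON  SF-FON All-Paths
#> mse          2e-05 0.03380   0.11563
#> mean_error  -2e-03 0.12252   0.24724
```

The higher-order model tracks the truth (MSE 2e-5), the first-order model
misses the planted indirect pathways (MSE 0.034), and the unfiltered
All-Paths baseline both fits worst (MSE 0.116) and over-predicts on average
(mean signed error +0.247). Network statistics and flow clustering:

```r
graph_stats(fon)
#> <sf_graph_stats>
#>   nodes 40, edges 595, avg degree 14.88
#>   avg clustering coefficient 0.1435, density 0.7438 (as printed), 0.3814 (directed)
#>   avg betweenness 0.1386, centralization 0.9863
#>   components: 1 weak, 1 strong
infomap_cluster(hon, seed = 1)
#> <sf_partition> 35 nodes in 4 clusters; map equation 4.28753 bits
```

## Command line

A thin dispatcher over the same functions ships at
`system.file("cli", "sfhon", package = "sfhon")`, with subcommands `synth`,
`voyage-risk`, `pair-risk`, `build-fon`, `build-allpaths`, `build-hon`,
`stats`, `cluster`, `evaluate` and `compare`, reading the neutral CSV schemas
documented in `?read_ports`, `?read_voyages`, `?read_ships`,
`?read_ecoregions` and `?read_introductions`.

## Documentation

The methods vignette (`vignettes/species-flow-networks.Rmd`) describes the
risk model and its assumptions, the rule-extraction statistics, the clustering
objective, the evaluation protocol, the synthetic-world design, numerical
conventions and known limitations.
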