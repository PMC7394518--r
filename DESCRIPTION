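Package: sfhon
Title: Species-Flow Higher-Order Networks for Ship-Borne Invasion Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the spread risk of nonindigenous aquatic species
    through a shipping network via ballast water and biofouling. Combines
    per-voyage introduction probabilities (environmental similarity,
    biofouling accumulation and en-route survival, ballast discharge and
    mortality) into pairwise port risks, extracts significant higher-order
    dependencies from ship trajectories to build a species-flow higher-order
    network (SF-HON) alongside first-order and all-paths baselines, computes
    directed network statistics, performs map-equation flow clustering, and
    evaluates region-level predictions against introduction records. Includes
    a seeded synthetic-data generator with planted higher-order dependencies
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
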