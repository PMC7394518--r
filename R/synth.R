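#' Configuration for the synthetic world generator
#'
#' Describes a synthetic shipping world: ports embedded in contiguous
#' ecoregions nested in realms with an environmental gradient, a typed fleet,
#' first-order base traffic with optional transition biases, planted
#' higher-order dependencies, and the observation-noise level for introduction
#' counts. A single seed fixes all randomness.
#'
#' @param n_ports,n_ecoregions,n_realms,n_regions counts; must nest
#'   (`n_ports >= n_ecoregions >= n_realms >= 1`; `n_regions` groups ports for
#'   evaluation).
#' @param n_ships,n_voyages fleet size and total number of voyages (split
#'   evenly across ships).
#' @param planted_rules list of planted higher-order dependencies, each a list
#'   `list(context = c(...), next_port = "...", boost = 0.9)`: whenever a
#'   ship's most recent ports match `context` exactly, its next port is
#'   `next_port` with probability `boost` (otherwise the base chain applies).
#' @param chain_bias `NULL` or data.frame `from,to,prob`: first-order
#'   transition biases layered over the base chain (the remaining probability
#'   mass follows the attractiveness weights over the other ports).
#' @param attractiveness `NULL` (uniform) or a positive weight per port:
#'   the base chain sends a ship from any port to port `j` with probability
#'   proportional to `attractiveness[j]`, emulating the heavy-tailed port-call
#'   volumes of real traffic (busy hubs, quiet minor ports).
#' @param temperature_range,salinity_range environmental ranges: temperature
#'   (degC) decreases linearly with absolute latitude across its range;
#'   salinity (ppt) is drawn uniformly within its range.
#' @param speed_kmday nominal ship speed used to set voyage durations.
#' @param stay_meanlog,stay_sdlog lognormal parameters of port-stay days.
#' @param noise_sd observation noise (sd, on the normalized risk scale) for
#'   introduction counts.
#' @param seed integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_ports = 25, n_ecoregions = 5, n_realms = 2,
                         n_regions = 5, n_ships = 30, n_voyages = 12000,
                         planted_rules = list(), chain_bias = NULL,
                         attractiveness = NULL,
                         temperature_range = c(2, 29),
                         salinity_range = c(20, 36),
                         speed_kmday = 400, stay_meanlog = log(3),
                         stay_sdlog = 0.5, noise_sd = 0, seed = 1L) {
  stopifnot(n_ports >= n_ecoregions, n_ecoregions >= n_realms, n_realms >= 1,
            n_regions >= 1, n_ships >= 1, n_voyages >= 1,
            speed_kmday > 0, noise_sd >= 0)
  for (pr in planted_rules) {
    stopifnot(is.list(pr), length(pr$context) >= 1L,
              is.character(pr$context), length(pr$next_port) == 1L,
              pr$boost > 0, pr$boost <= 1)
    if (pr$next_port == pr$context[length(pr$context)])
      stop("planted next_port must differ from the current (last context) port")
  }
  if (!is.null(attractiveness)) {
    stopifnot(length(attractiveness) == n_ports, all(attractiveness > 0))
  }
  if (!is.null(chain_bias)) {
    stopifnot(all(c("from", "to", "prob") %in% names(chain_bias)),
              all(chain_bias$prob > 0))
    tot <- tapply(chain_bias$prob, chain_bias$from, sum)
    if (any(tot >= 1)) stop("chain_bias rows for one source port must sum to < 1")
  }
  structure(list(n_ports = n_ports, n_ecoregions = n_ecoregions,
                 n_realms = n_realms, n_regions = n_regions,
                 n_ships = n_ships, n_voyages = n_voyages,
                 planted_rules = planted_rules, chain_bias = chain_bias,
                 attractiveness = attractiveness,
                 temperature_range = temperature_range,
                 salinity_range = salinity_range,
                 speed_kmday = speed_kmday, stay_meanlog = stay_meanlog,
                 stay_sdlog = stay_sdlog, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

port_name <- function(i) sprintf("P%02d", i)

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate synthetic ports and their ecoregion graph
#'
#' Ports are placed on a latitude/longitude grid spanning both hemispheres;
#' ecoregions are contiguous blocks of ports, nested inside contiguous realms,
#' with chain adjacency (ecoregion `i` neighbours `i + 1`). Temperature
#' decreases linearly with absolute latitude across `temperature_range`;
#' salinity is uniform within `salinity_range`. Regions (the evaluation
#' grouping) are contiguous blocks of ports.
#'
#' @param config a `synth_config`.
#' @return list with `ports` (a port table) and `eco` (`sf_ecoregions`).
#' @export
gen_ports <- function(config) {
  with_seed(config$seed, {
    n <- config$n_ports
    i <- seq_len(n)
    lat <- seq(-55, 55, length.out = n) + stats::rnorm(n, 0, 1)
    lat <- pmax(pmin(lat, 89), -89)
    lon <- ((i * 360 / min(n, 36)) %% 360) - 180 + stats::rnorm(n, 0, 2)
    lon <- pmax(pmin(lon, 180), -180)
    tr <- config$temperature_range
    temperature <- tr[2] - (tr[2] - tr[1]) * abs(lat) / 90 + stats::rnorm(n, 0, 0.5)
    salinity <- stats::runif(n, config$salinity_range[1], config$salinity_range[2])
    block <- function(m) ceiling(i * m / n)  # contiguous blocks of ports
    ecoregion <- block(config$n_ecoregions)
    realm_of_eco <- ceiling(seq_len(config$n_ecoregions) * config$n_realms /
                              config$n_ecoregions)
    ports <- data.frame(
      port_id = port_name(i), name = paste("Port", i),
      latitude = lat, longitude = lon,
      temperature = temperature, salinity = salinity,
      ecoregion_id = paste0("E", ecoregion),
      realm_id = paste0("RL", realm_of_eco[ecoregion]),
      region_id = paste0("R", block(config$n_regions)),
      stringsAsFactors = FALSE
    )
    ne <- config$n_ecoregions
    pairs <- if (ne > 1L) cbind(paste0("E", 1:(ne - 1)), paste0("E", 2:ne))
             else matrix(character(), ncol = 2)
    list(ports = ports, eco = ecoregion_graph(pairs, ports = ports))
  })
}

#' Generate a synthetic fleet
#'
#' Ship types drawn from a fixed mix of the published categories; gross weight
#' tonnage lognormal with a type-dependent scale (bulk/auto/tanker carriers
#' larger than container/general ships).
#'
#' @param config a `synth_config`.
#' @return a ship table (`ship_id`, `ship_type`, `gwt`).
#' @export
gen_fleet <- function(config) {
  with_seed(config$seed + 1L, {
    types <- c("Container", "Bulk", "General", "Auto", "Tanker", "Chemical",
               "Passenger", "Gas", "Ref-Cargo", "Fishing", "Research", "Yacht",
               "Other")
    mix <- c(0.28, 0.23, 0.20, 0.06, 0.10, 0.06, 0.015, 0.025, 0.02,
             0.002, 0.001, 0.001, 0.006)
    ty <- sample(types, config$n_ships, replace = TRUE, prob = mix)
    scale <- c(Container = 9.2, Bulk = 10.3, General = 8.8, Auto = 10.0,
               Tanker = 10.2, Chemical = 9.4, Passenger = 10.0, Gas = 9.8,
               `Ref-Cargo` = 9.0, Fishing = 7.0, Research = 7.5, Yacht = 6.0,
               Other = 8.0)
    gwt <- round(stats::rlnorm(config$n_ships, meanlog = scale[ty], sdlog = 0.4))
    data.frame(ship_id = sprintf("S%03d", seq_len(config$n_ships)),
               ship_type = ty, gwt = pmax(gwt, 100), stringsAsFactors = FALSE)
  })
}

#' Generate voyages from a base chain with planted higher-order dependencies
#'
#' Each ship performs a history-aware random walk over the ports: when its
#' most recent visited ports match a planted context exactly (longest match
#' first), the next port is the planted target with the rule's boost
#' probability; otherwise the next port is drawn from the first-order base
#' chain (uniform over the other ports, modulated by `chain_bias`). Sail and
#' arrival dates follow from lognormal port stays and distance over the
#' nominal speed. The empirical conditional next-port frequencies converge to
#' the configured ones as the walk grows.
#'
#' @param config a `synth_config`.
#' @param ports port table from [gen_ports()].
#' @param fleet ship table from [gen_fleet()].
#' @return a voyage table (continuous per ship: each voyage starts where the
#'   previous one arrived).
#' @export
gen_trajectories <- function(config, ports, fleet) {
  n <- nrow(ports)
  ids <- ports$port_id
  # base transition rows: attractiveness-weighted (uniform when NULL) over
  # the other ports, overridden by chain_bias rows
  att <- if (is.null(config$attractiveness)) rep(1, n) else as.numeric(config$attractiveness)
  base <- matrix(rep(att, each = n), n, n, dimnames = list(ids, ids))
  diag(base) <- 0
  base <- base / rowSums(base)
  if (!is.null(config$chain_bias)) {
    cb <- config$chain_bias
    for (r in seq_len(nrow(cb))) {
      from <- cb$from[r]; to <- cb$to[r]
      stopifnot(from %in% ids, to %in% ids)
    }
    for (from in unique(cb$from)) {
      rows <- cb[cb$from == from, ]
      rest <- setdiff(ids, c(from, rows$to))
      w <- att[match(rest, ids)]
      base[from, ] <- 0
      base[from, rows$to] <- rows$prob
      base[from, rest] <- (1 - sum(rows$prob)) * w / sum(w)
    }
  }
  plants <- config$planted_rules
  plant_env <- new.env(parent = emptyenv(), hash = TRUE)
  orders <- integer(0)
  for (pr in plants) {
    key <- paste(c(pr$context), collapse = "\t")
    assign(key, pr, envir = plant_env)
    orders <- c(orders, length(pr$context))
  }
  orders <- sort(unique(orders), decreasing = TRUE)

  steps <- ceiling(config$n_voyages / config$n_ships)
  with_seed(config$seed + 2L, {
    out <- vector("list", config$n_ships)
    for (s in seq_len(config$n_ships)) {
      walk <- character(steps + 1L)
      walk[1L] <- sample(ids, 1L)
      for (t in seq_len(steps)) {
        nxt <- NA_character_
        for (k in orders) {
          if (t < k) next
          key <- paste(walk[(t - k + 1L):t], collapse = "\t")
          pr <- plant_env[[key]]
          if (!is.null(pr) && stats::runif(1L) < pr$boost &&
              pr$next_port != walk[t]) {
            nxt <- pr$next_port
            break
          }
        }
        if (is.na(nxt)) nxt <- sample(ids, 1L, prob = base[walk[t], ])
        walk[t + 1L] <- nxt
      }
      out[[s]] <- walk
    }
    # kinematics and dates, vectorized per ship
    parts <- vector("list", config$n_ships)
    pidx <- stats::setNames(seq_len(n), ids)
    for (s in seq_len(config$n_ships)) {
      w <- out[[s]]
      m <- length(w) - 1L
      i <- pidx[w[-length(w)]]; j <- pidx[w[-1L]]
      dist <- haversine_km(ports$latitude[i], ports$longitude[i],
                           ports$latitude[j], ports$longitude[j])
      dur <- pmax(1, round(dist / config$speed_kmday))
      stay <- pmax(1, round(stats::rlnorm(m, config$stay_meanlog, config$stay_sdlog)))
      sail <- numeric(m); arrive <- numeric(m)
      tnow <- 0
      for (v in seq_len(m)) {
        tnow <- tnow + stay[v]
        sail[v] <- tnow
        tnow <- tnow + dur[v]
        arrive[v] <- tnow
      }
      start <- as.Date("2012-05-01")
      parts[[s]] <- data.frame(
        ship_id = fleet$ship_id[s], source = w[-length(w)], dest = w[-1L],
        sail_date = start + sail, arrival_date = start + arrive,
        discharge = NA_real_, stringsAsFactors = FALSE)
    }
    v <- do.call(rbind, parts)
    v <- v[seq_len(min(nrow(v), config$n_voyages)), , drop = FALSE]
    rownames(v) <- NULL
    v
  })
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper: ports + ecoregions, fleet, voyages, trajectories.
#'
#' @param config a `synth_config`.
#' @return list with `config`, `ports`, `eco`, `ships`, `voyages`,
#'   `trajectories`.
#' @export
gen_scenario <- function(config) {
  pw <- gen_ports(config)
  fleet <- gen_fleet(config)
  voyages <- gen_trajectories(config, pw$ports, fleet)
  list(config = config, ports = pw$ports, eco = pw$eco, ships = fleet,
       voyages = voyages, trajectories = build_trajectories(voyages))
}

#' True per-port risk of a synthetic scenario
#'
#' The generating process's own risk: for each port, the probabilistic union
#' of (a) the first-order pairwise spread risks of all incoming traversed
#' pairs and (b) for each planted dependency realized in the data, the spread
#' probability of its context-plus-next path, credited to the planted target
#' port. This mirrors the collapsed higher-order network semantics, computed
#' from generator-side knowledge of the planted rules rather than from any
#' estimator.
#'
#' @param scenario output of [gen_scenario()].
#' @param vector `"ballast"` or `"biofouling"`.
#' @param params an `sfhon_params`.
#' @return list with `port_risk` (named vector), `pair_risks` (the first-order
#'   pair table), `edge_risk` (named lookup).
#' @export
true_port_risk <- function(scenario, vector = "ballast",
                           params = default_params()) {
  vr <- voyage_risks(scenario$voyages, scenario$ships, scenario$ports,
                     vector, params)
  pr <- pair_risks(vr, scenario$ports, scenario$eco, params)
  risks <- edge_risks(pr)
  port_in <- collapse_to_ports(build_fon(pr))$port_in
  seqs <- as_port_sequences(scenario$trajectories)
  for (rule in scenario$config$planted_rules) {
    path <- c(rule$context, rule$next_port)
    k <- length(path)
    realized <- any(vapply(seqs, function(s) {
      m <- length(s)
      if (m < k) return(FALSE)
      any(vapply(seq_len(m - k + 1L),
                 function(a) all(s[a:(a + k - 1L)] == path), logical(1L)))
    }, logical(1L)))
    if (!realized) next
    p <- path_risk(path, risks)
    j <- rule$next_port
    port_in[j] <- 1 - (1 - port_in[j]) * (1 - p)
  }
  list(port_risk = port_in, pair_risks = pr, edge_risk = risks)
}

#' Generate region-level introduction counts from true risk
#'
#' Counts proportional to the min-max-normalized true region risk (scale
#' 1000), plus Gaussian observation noise of sd `noise_sd` on the normalized
#' scale, truncated at zero and rounded. With `noise_sd = 0` the counts are
#' rank-identical to the risks. The generating transform is recorded in the
#' `transform` attribute.
#'
#' @param true_region_risk named numeric vector (region -> risk).
#' @param noise_sd observation noise sd on the normalized scale.
#' @param seed integer seed.
#' @return introductions data.frame (`region_id`, `n_first_introductions`,
#'   `normalized`).
#' @export
gen_introductions <- function(true_region_risk, noise_sd = 0, seed = 1L) {
  with_seed(as.integer(seed) + 3L, {
    scaled <- minmax_scale(true_region_risk)
    noisy <- as.numeric(scaled) + stats::rnorm(length(scaled), 0, noise_sd)
    counts <- pmax(0, round(1000 * noisy))
    out <- data.frame(region_id = names(true_region_risk),
                      n_first_introductions = counts,
                      stringsAsFactors = FALSE)
    out$normalized <- minmax_scale(out$n_first_introductions)
    attr(out, "transform") <- sprintf(
      "round(max(0, 1000 * (minmax(risk) + N(0, %g))))", noise_sd)
    out
  })
}

#' Reference hub-and-spoke scenario configuration
#'
#' The package's canonical synthetic world for end-to-end demonstrations and
#' tests: 40 ports in 5 latitudinal ecoregion bands (2 realms, 8 evaluation
#' regions), heavy-tailed port attractiveness (a busy hub region, quiet
#' equatorial-belt ports), 12000 voyages by 120 ships, and four planted
#' second-order dependencies. Each planted rule routes ships that visited a
#' hub port and then the mirror-latitude port of its target on to that target
#' (mirror latitudes give high environmental establishment between
#' non-neighbouring ecoregions, so the planted pathways carry real risk).
#'
#' The design emulates three features of real shipping data that drive the
#' qualitative behaviour of the three network models: hub-and-spoke traffic
#' with heavy-tailed port-call volumes, recurrent multi-leg service patterns
#' (the planted dependencies), and right-skewed region-level introduction
#' counts. See the methods vignette for the full rationale.
#'
#' @param seed integer seed.
#' @param noise_sd observation noise, see [synth_config()].
#' @return a `synth_config`.
#' @export
hub_scenario_config <- function(seed = 1L, noise_sd = 0) {
  synth_config(
    n_ports = 40, n_ecoregions = 5, n_realms = 2, n_regions = 8,
    n_ships = 120, n_voyages = 12000,
    planted_rules = list(
      list(context = c("P36", "P15"), next_port = "P26", boost = 0.9),
      list(context = c("P37", "P14"), next_port = "P27", boost = 0.9),
      list(context = c("P38", "P13"), next_port = "P28", boost = 0.9),
      list(context = c("P39", "P12"), next_port = "P29", boost = 0.9)),
    chain_bias = data.frame(from = c("P36", "P37", "P38", "P39"),
                            to = c("P15", "P14", "P13", "P12"), prob = 0.12),
    attractiveness = c(rep(1, 15), rep(0.05, 10), rep(1, 10), rep(2, 5)),
    noise_sd = noise_sd, seed = seed)
}
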