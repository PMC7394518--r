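#' Probability that a transferred species is nonindigenous
#'
#' Ports in the same or neighbouring ecoregions are assumed to share native
#' species pools, so the probability that one introduces a nonindigenous
#' species to the other is 0; for all other port pairs it is 1. The relation is
#' symmetric.
#'
#' @param port_i,port_j single rows of a port table (or lists with an
#'   `ecoregion_id` field). Vectorized over equal-length inputs.
#' @param eco an `sf_ecoregions` object.
#' @return 0 or 1 (numeric vector).
#' @export
prob_nonindigenous <- function(port_i, port_j, eco) {
  a <- as.character(port_i$ecoregion_id)
  b <- as.character(port_j$ecoregion_id)
  unknown <- unique(c(a[!(a %in% eco$ecoregions)], b[!(b %in% eco$ecoregions)]))
  if (length(unknown)) stop("unknown ecoregion id: ", paste(unknown, collapse = ", "))
  eco_nonindigenous(a, b, eco)
}

# vectorized core on ecoregion ids (no validity check)
eco_nonindigenous <- function(a, b, eco) {
  related <- a == b | paste(a, b, sep = "\t") %in% eco$neighbor_key
  as.numeric(!related)
}

#' Establishment probability from environmental similarity
#'
#' Gaussian in the temperature and salinity differences of the two ports:
#' `alpha * exp(-0.5 * ((dT/delta_T)^2 + (dS/delta_S)^2))`. Symmetric, maximal
#' (`alpha`) for identical environments, and monotonically vanishing as the
#' environments diverge.
#'
#' @param port_i,port_j port rows (need `temperature`, `salinity`); vectorized.
#' @param params an `sfhon_params` object.
#' @return establishment probability in `(0, alpha]`.
#' @examples
#' p <- data.frame(temperature = 20, salinity = 30)
#' prob_establish(p, p)  # = alpha = 0.00015
#' @export
prob_establish <- function(port_i, port_j, params = default_params()) {
  dT <- port_i$temperature - port_j$temperature
  dS <- port_i$salinity - port_j$salinity
  if (anyNA(dT) || anyNA(dS))
    stop("both ports need temperature and salinity for establishment")
  params$alpha * exp(-0.5 * ((dT / params$delta_T)^2 + (dS / params$delta_S)^2))
}

#' Biofouling accumulation during a port stay
#'
#' Proportion of maximum species richness accumulated on the hull after `stay`
#' days in port, modelled as a climate-zone-specific cubic
#' `b1*d^3 - b2*d^2 + b3*d` with no constant term. The raw cubic exceeds 1 for
#' very long stays (tropical stays beyond roughly 430 days), so the value is
#' clamped into `[0, 1]` by default (`params$clamp_accumulation = FALSE`
#' disables the clamp for diagnostics).
#'
#' @param stay days at the source port (`>= 0`); vectorized.
#' @param zone `"tropical"` or `"temperate"` (recycled).
#' @param params an `sfhon_params` object.
#' @return accumulation proportion.
#' @export
biofouling_accumulation <- function(stay, zone, params = default_params()) {
  if (any(stay < 0)) stop("stay must be non-negative")
  zone <- match.arg(zone, c("tropical", "temperate"), several.ok = TRUE)
  b <- rbind(tropical = params$beta_tropical, temperate = params$beta_temperate)
  bz <- b[zone, , drop = FALSE]
  if (nrow(bz) == 1L && length(stay) > 1L)
    bz <- bz[rep(1L, length(stay)), , drop = FALSE]
  raw <- bz[, 1] * stay^3 - bz[, 2] * stay^2 + bz[, 3] * stay
  if (isTRUE(params$clamp_accumulation)) raw <- pmin(pmax(raw, 0), 1)
  unname(raw)
}

#' Biofouling survival over a voyage
#'
#' Exponential decay in the average voyage velocity: `exp(-gamma * v)`, with
#' `v` in km/day.
#'
#' @param velocity km/day (`>= 0`); vectorized.
#' @param params an `sfhon_params` object.
#' @return survival probability in `(0, 1]`.
#' @export
biofouling_survival <- function(velocity, params = default_params()) {
  if (any(velocity < 0)) stop("velocity must be non-negative")
  exp(-params$gamma * velocity)
}

#' Per-voyage biofouling introduction probability
#'
#' Product of the ship type's antifouling proportion (share of that type
#' without an operational antifouling system), the accumulation during the
#' source-port stay, and survival over the voyage. Ship types outside the
#' published categories fall back to the `"other"` antifouling value (0.60).
#'
#' @param stay days at the source port.
#' @param velocity voyage velocity, km/day.
#' @param ship_type raw ship type string(s).
#' @param zone climate zone of the source port.
#' @param params an `sfhon_params` object.
#' @return probability in `[0, 1]`.
#' @export
biofouling_voyage_prob <- function(stay, velocity, ship_type, zone,
                                   params = default_params()) {
  af <- unname(params$antifouling[resolve_ship_type(ship_type, params, "antifouling")])
  af * biofouling_accumulation(stay, zone, params) *
    biofouling_survival(velocity, params)
}

#' Ballast discharge volume
#'
#' Observed discharge volume wins when present; otherwise the volume is
#' estimated as the ship type's discharge coefficient times gross weight
#' tonnage.
#'
#' @param ship_type,gwt ship type string(s) and gross weight tonnage (> 0).
#' @param observed observed discharge volume (m^3) or `NA`.
#' @param params an `sfhon_params` object.
#' @return discharge volume (m^3).
#' @export
ballast_discharge <- function(ship_type, gwt, observed = NA_real_,
                              params = default_params()) {
  if (any(!is.na(gwt) & gwt <= 0)) stop("gwt must be > 0")
  cat_ <- resolve_ship_type(ship_type, params, "discharge_coeff")
  co <- params$discharge_coeff[cat_]
  if (anyNA(co)) stop("missing discharge coefficient for type(s): ",
                      paste(unique(ship_type[is.na(co)]), collapse = ", "))
  est <- unname(co) * gwt
  ifelse(is.na(observed), est, observed)
}

#' Per-voyage ballast introduction probability
#'
#' `rho * (1 - exp(-lambda * D)) * exp(-mu * dt)`: the probability that a
#' discharge of volume `D` (m^3) after `dt` days in transit introduces a
#' species, with daily in-tank mortality `mu` and introduction potential per
#' volume `lambda`. `rho` is the route's ballast-water-management efficacy
#' factor exactly as the model prints it (see [default_params()] for the
#' caveat on its semantics); the default 1 corresponds to no management.
#'
#' @param discharge volume discharged at destination (m^3, `>= 0`).
#' @param duration voyage duration in days (`>= 0`).
#' @param rho efficacy factor in `[0, 1]`.
#' @param params an `sfhon_params` object.
#' @return probability in `[0, 1]`.
#' @export
ballast_voyage_prob <- function(discharge, duration, rho = NULL,
                                params = default_params()) {
  if (is.null(rho)) rho <- params$rho_default
  stopifnot(all(discharge >= 0), all(duration >= 0),
            all(rho >= 0 & rho <= 1))
  rho * (1 - exp(-params$lambda * discharge)) * exp(-params$mu * duration)
}

#' Union of independent per-voyage probabilities
#'
#' Aggregates the voyage-level introduction probabilities of all voyages
#' between one ordered port pair: `1 - prod(1 - p)`. Computed in log space
#' (`log1p`) for numerical stability; order-independent and at least as large
#' as any single term. The empty union is 0.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @return a single probability.
#' @examples
#' prob_union(c(0.5, 0.5))  # 0.75
#' @export
prob_union <- function(p) {
  if (!length(p)) return(0)
  stopifnot(all(p >= 0 & p <= 1))
  if (any(p == 1)) return(1)
  -expm1(sum(log1p(-p))) + 0  # + 0 normalizes negative zero
}

#' Voyage-level NIS introduction probabilities
#'
#' Computes the per-voyage introduction probability for one vector
#' (`"ballast"` or `"biofouling"`) for every non-self-loop voyage. Kinematics
#' and source stays are derived if absent. Biofouling uses the climate zone of
#' the source port; ballast uses estimated (or observed) discharge and the
#' voyage duration. An optional `rho` column in the voyage table overrides the
#' ballast-management default per voyage.
#'
#' @param voyages voyage table.
#' @param ships ship table.
#' @param ports port table.
#' @param vector `"ballast"` or `"biofouling"`.
#' @param params an `sfhon_params` object.
#' @param duration_floor,default_stay see [derive_kinematics()] and
#'   [annotate_stays()].
#' @return the voyage table (self-loops dropped) with `ship_type`, `gwt`,
#'   `zone`, and the per-voyage probability `prob`.
#' @export
voyage_risks <- function(voyages, ships, ports,
                         vector = c("ballast", "biofouling"),
                         params = default_params(),
                         duration_floor = 0.5, default_stay = 7) {
  vector <- match.arg(vector)
  if (!all(c("distance", "duration", "velocity") %in% names(voyages)))
    voyages <- derive_kinematics(voyages, ports, duration_floor)
  if (!"source_stay" %in% names(voyages))
    voyages <- annotate_stays(voyages, default_stay)
  v <- voyages[voyages$source != voyages$dest, , drop = FALSE]
  si <- match(v$ship_id, ships$ship_id)
  if (anyNA(si)) stop("voyage references a ship absent from the ship table")
  v$ship_type <- ships$ship_type[si]
  v$gwt <- ships$gwt[si]
  pi_ <- match(v$source, ports$port_id)
  v$zone <- if (nrow(v)) climate_zone(ports$latitude[pi_]) else character()
  if (vector == "biofouling") {
    cat_ <- resolve_ship_type(v$ship_type, params, "antifouling")
    fell_back <- unique(v$ship_type[cat_ == "other" & tolower(v$ship_type) != "other"])
    if (length(fell_back))
      message("ship type(s) mapped to 'other' antifouling (0.60): ",
              paste(fell_back, collapse = ", "))
    v$prob <- biofouling_voyage_prob(v$source_stay, v$velocity, v$ship_type,
                                     v$zone, params)
  } else {
    D <- ballast_discharge(v$ship_type, v$gwt, v$discharge, params)
    rho <- if ("rho" %in% names(v)) v$rho else NULL
    v$prob <- ballast_voyage_prob(D, v$duration, rho, params)
  }
  attr(v, "vector") <- vector
  rownames(v) <- NULL
  v
}

#' Pairwise NIS spread risk
#'
#' Aggregates voyage-level probabilities into a per-ordered-port-pair table:
#' `p_intro` is the union over all voyages from `source` to `dest`,
#' `p_nonindigenous` the 0/1 ecoregion indicator, `p_establish` the
#' environmental-similarity Gaussian, and
#' `p_spread = p_nonindigenous * p_establish * p_intro` is the spread risk
#' used as the network edge weight.
#'
#' @param vrisks output of [voyage_risks()] (or a voyage table, in which case
#'   `ships`, `vector`, `params` are used to compute it).
#' @param ports port table.
#' @param eco `sf_ecoregions` object.
#' @param params an `sfhon_params` object.
#' @param ships ship table, only needed when `vrisks` lacks a `prob` column.
#' @param vector introduction vector, only needed with raw voyages.
#' @return data.frame sorted by `(source, dest)` with columns `source`,
#'   `dest`, `vector`, `p_nonindigenous`, `p_establish`, `p_intro`,
#'   `p_spread`, `n_voyages`.
#' @export
pair_risks <- function(vrisks, ports, eco, params = default_params(),
                       ships = NULL, vector = NULL) {
  if (!"prob" %in% names(vrisks)) {
    if (is.null(ships) || is.null(vector))
      stop("provide voyage_risks() output, or ships= and vector= to compute it")
    vrisks <- voyage_risks(vrisks, ships, ports, vector, params)
  }
  vec <- attr(vrisks, "vector") %||% vector %||% NA_character_
  if (nrow(vrisks) == 0L) {
    return(data.frame(source = character(), dest = character(),
                      vector = character(), p_nonindigenous = numeric(),
                      p_establish = numeric(), p_intro = numeric(),
                      p_spread = numeric(), n_voyages = integer()))
  }
  dt <- data.table::as.data.table(vrisks[, c("source", "dest", "prob")])
  agg <- dt[, list(
    p_intro = -expm1(sum(log1p(-prob))) + 0,
    n_voyages = .N
  ), by = c("source", "dest")]
  agg <- as.data.frame(agg)
  i <- match(agg$source, ports$port_id)
  j <- match(agg$dest, ports$port_id)
  agg$p_nonindigenous <- prob_nonindigenous(ports[i, ], ports[j, ], eco)
  agg$p_establish <- prob_establish(ports[i, ], ports[j, ], params)
  agg$p_spread <- agg$p_nonindigenous * agg$p_establish * agg$p_intro
  agg$vector <- vec
  agg <- agg[order(agg$source, agg$dest),
             c("source", "dest", "vector", "p_nonindigenous", "p_establish",
               "p_intro", "p_spread", "n_voyages")]
  rownames(agg) <- NULL
  agg
}

#' Edge-risk lookup from a pair-risk table
#'
#' Turns a pair-risk table (or any data.frame with `source`, `dest` and a
#' weight column) into the named numeric vector used by [path_risk()],
#' [extract_rules()] and [build_all_paths()]. By default the full spread risk
#' `p_spread` is used as the per-edge risk entering path unions; set
#' `column = "p_intro"` to use the traffic-only introduction probability.
#'
#' @param pair_risks data.frame with `source` and `dest` columns.
#' @param column name of the weight column (default `"p_spread"`).
#' @return named numeric vector keyed by `source -> dest`.
#' @export
edge_risks <- function(pair_risks, column = "p_spread") {
  if (!column %in% names(pair_risks)) stop("no column '", column, "' in pair risks")
  stats::setNames(pair_risks[[column]],
                  edge_key(pair_risks$source, pair_risks$dest))
}

edge_key <- function(source, dest) paste(source, dest, sep = " -> ")

# risk of a single directed edge under a lookup; missing edges risk 0
edge_risk_of <- function(risks, source, dest) {
  if (!length(risks)) return(rep(0, length(source)))
  r <- unname(risks[edge_key(source, dest)])
  r[is.na(r)] <- 0
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
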