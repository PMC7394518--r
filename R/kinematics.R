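#' Climate zone of a latitude
#'
#' Tropical/subtropical is defined as the band within 35 degrees of the
#' equator (boundary inclusive); everything poleward is temperate. The zone of
#' the *source* port selects the biofouling accumulation curve, since hull
#' communities accumulate during the stay at the source.
#'
#' @param latitude numeric vector of latitudes in degrees.
#' @return character vector, `"tropical"` or `"temperate"`.
#' @examples
#' climate_zone(c(0, 35, -50))
#' @export
climate_zone <- function(latitude) {
  stopifnot(all(is.finite(latitude)), all(abs(latitude) <= 90))
  ifelse(abs(latitude) <= 35, "tropical", "temperate")
}

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorized).
#' @return distance in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Derive voyage kinematics
#'
#' Completes a voyage table with great-circle `distance` (km), `duration`
#' (fractional days, floored at `duration_floor` so same-day voyages never
#' yield an infinite velocity) and `velocity = distance / duration` (km/day).
#' Self-loop voyages (source equals destination) get distance 0 and are
#' flagged in the logical column `self_loop`; they are excluded from risk
#' computations and trajectories downstream.
#'
#' @param voyages voyage table from [read_voyages()].
#' @param ports port table from [read_ports()] carrying the coordinates.
#' @param duration_floor minimum duration in days (default 0.5).
#' @return the voyage table with `distance`, `duration`, `velocity`,
#'   `self_loop` columns added.
#' @export
derive_kinematics <- function(voyages, ports, duration_floor = 0.5) {
  stopifnot(duration_floor > 0)
  i <- match(voyages$source, ports$port_id)
  j <- match(voyages$dest, ports$port_id)
  if (anyNA(i) || anyNA(j)) stop("voyage references a port absent from the port table")
  n <- nrow(voyages)
  voyages$distance <- if (n) haversine_km(ports$latitude[i], ports$longitude[i],
                                          ports$latitude[j], ports$longitude[j]) else numeric()
  raw <- as.numeric(voyages$arrival_date - voyages$sail_date)
  voyages$duration <- pmax(raw, duration_floor)
  voyages$velocity <- voyages$distance / voyages$duration
  voyages$self_loop <- voyages$source == voyages$dest
  voyages
}

#' Source-port stay durations
#'
#' For each departure, the stay at the source port is the gap between the
#' ship's previous arrival there and the sail date. When the previous record's
#' destination does not match the current source (a gap in coverage), or the
#' voyage is the ship's first record, the configurable `default_stay` is used.
#'
#' @param voyages voyage table (any order; sorted per ship by sail date
#'   internally).
#' @param default_stay stay in days assumed for cold starts (default 7).
#' @return the voyage table, sorted by `(ship_id, sail_date)`, with a
#'   `source_stay` column (days, `>= 0`).
#' @export
annotate_stays <- function(voyages, default_stay = 7) {
  stopifnot(default_stay >= 0)
  o <- order(voyages$ship_id, voyages$sail_date, voyages$arrival_date)
  v <- voyages[o, , drop = FALSE]
  n <- nrow(v)
  stay <- rep(default_stay, n)
  if (n > 1L) {
    same_ship <- v$ship_id[-1L] == v$ship_id[-n]
    continuous <- same_ship & (v$source[-1L] == v$dest[-n])
    gap <- as.numeric(v$sail_date[-1L] - v$arrival_date[-n])
    idx <- which(continuous & gap >= 0)
    stay[idx + 1L] <- gap[idx]
  }
  v$source_stay <- stay
  rownames(v) <- NULL
  v
}

#' Assemble ship trajectories
#'
#' Lists the sequence of ports visited by each ship, ordered by sail date.
#' Immediate repeats (self-loop voyages) are removed. A ship's record is split
#' into maximal continuous segments wherever the previous destination differs
#' from the next source, so that concatenating consecutive visit pairs of all
#' trajectories recovers exactly the set of non-self-loop voyages.
#'
#' @param voyages voyage table.
#' @return an object of class `sf_trajectories`: a list of character vectors
#'   of port ids, one per continuous segment, named by ship id (ships with
#'   several segments repeat their name).
#' @examples
#' v <- data.frame(ship_id = "s1", source = c("C", "A"), dest = c("A", "E"),
#'                 sail_date = as.Date(c("2012-05-01", "2012-05-10")),
#'                 arrival_date = as.Date(c("2012-05-05", "2012-05-15")))
#' build_trajectories(v)
#' @export
build_trajectories <- function(voyages) {
  if (nrow(voyages) == 0L) return(structure(list(), class = "sf_trajectories"))
  o <- order(voyages$ship_id, voyages$sail_date, voyages$arrival_date)
  v <- voyages[o, , drop = FALSE]
  n <- nrow(v)
  if (n > 1L) {
    same_ship <- v$ship_id[-1L] == v$ship_id[-n]
    overlap <- same_ship & (v$sail_date[-1L] < v$arrival_date[-n])
    if (any(overlap))
      warning(sum(overlap), " overlapping voyage(s); order kept by sail date")
  }
  v <- v[v$source != v$dest, , drop = FALSE]  # self-loop removal
  n <- nrow(v)
  if (n == 0L) return(structure(list(), class = "sf_trajectories"))
  new_seg <- c(TRUE, v$ship_id[-1L] != v$ship_id[-n] | v$source[-1L] != v$dest[-n])
  seg <- cumsum(new_seg)
  out <- lapply(split(seq_len(n), seg), function(idx) {
    c(v$source[idx[1L]], v$dest[idx])
  })
  names(out) <- vapply(split(v$ship_id, seg), `[`, character(1L), 1L)
  structure(out, class = "sf_trajectories")
}

#' @export
print.sf_trajectories <- function(x, ...) {
  len <- lengths(x)
  cat(sprintf("<sf_trajectories> %d trajectory segment(s) from %d ship(s); %s port visits\n",
              length(x), length(unique(names(x))), format(sum(len))))
  invisible(x)
}

# coerce trajectories / list of character vectors to plain port sequences
as_port_sequences <- function(trajectories) {
  if (inherits(trajectories, "sf_trajectories")) return(unclass(trajectories))
  if (is.character(trajectories)) return(list(trajectories))
  stopifnot(is.list(trajectories), all(vapply(trajectories, is.character, logical(1L))))
  trajectories
}
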