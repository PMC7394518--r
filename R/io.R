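#' Read a port table
#'
#' Expects a CSV with header
#' `port_id,name,lat,lon,temperature_c,salinity_ppt,ecoregion_id,realm_id,region_id`.
#' Ports lacking temperature or salinity cannot enter any risk computation and
#' are dropped (the number dropped is recorded in the `n_dropped` attribute and
#' reported via a message).
#'
#' @param path CSV file path.
#' @return a `data.frame` with columns `port_id`, `name`, `latitude`,
#'   `longitude`, `temperature`, `salinity`, `ecoregion_id`, `realm_id`,
#'   `region_id`, keyed by unique `port_id`; attribute `n_dropped` counts rows
#'   removed for missing environment.
#' @export
read_ports <- function(path) {
  req <- c("port_id", "name", "lat", "lon", "temperature_c", "salinity_ppt",
           "ecoregion_id", "realm_id", "region_id")
  x <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("ports file missing column(s): ", paste(miss, collapse = ", "))
  dup <- unique(x$port_id[duplicated(x$port_id)])
  if (length(dup)) stop("duplicate port_id: ", paste(dup, collapse = ", "))
  num <- function(col) suppressWarnings(as.numeric(x[[col]]))
  lat <- num("lat"); lon <- num("lon")
  bad <- which((is.na(lat) & nzchar(x$lat)) | (is.na(lon) & nzchar(x$lon)))
  if (length(bad)) stop("unparseable latitude/longitude at row(s): ",
                        paste(bad, collapse = ", "))
  out <- data.frame(
    port_id = x$port_id, name = x$name,
    latitude = lat, longitude = lon,
    temperature = num("temperature_c"), salinity = num("salinity_ppt"),
    ecoregion_id = x$ecoregion_id, realm_id = x$realm_id,
    region_id = x$region_id, stringsAsFactors = FALSE
  )
  validate_ports(out)
  keep <- !is.na(out$temperature) & !is.na(out$salinity)
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " port(s) dropped for missing temperature/salinity")
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

validate_ports <- function(p) {
  stopifnot(
    all(is.na(p$latitude) | (p$latitude >= -90 & p$latitude <= 90)),
    all(is.na(p$longitude) | (p$longitude >= -180 & p$longitude <= 180)),
    all(is.na(p$salinity) | p$salinity >= 0),
    all(nzchar(p$ecoregion_id)), all(nzchar(p$realm_id))
  )
  if (any(grepl("[|,]", p$port_id)))
    stop("port_id must not contain '|' or ',' (reserved by node labels)")
  invisible(p)
}

#' @rdname read_ports
#' @param ports a port table as returned by `read_ports`.
#' @export
write_ports <- function(ports, path) {
  out <- data.frame(
    port_id = ports$port_id, name = ports$name,
    lat = ports$latitude, lon = ports$longitude,
    temperature_c = ports$temperature, salinity_ppt = ports$salinity,
    ecoregion_id = ports$ecoregion_id, realm_id = ports$realm_id,
    region_id = ports$region_id
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a ship metadata table
#'
#' CSV schema `ship_id,ship_type,gwt`. Gross weight tonnage must be positive.
#'
#' @param path CSV file path.
#' @return data.frame with `ship_id`, `ship_type`, `gwt`.
#' @export
read_ships <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("ship_id", "ship_type", "gwt")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("ships file missing column(s): ", paste(miss, collapse = ", "))
  x$ship_id <- as.character(x$ship_id)
  dup <- unique(x$ship_id[duplicated(x$ship_id)])
  if (length(dup)) stop("duplicate ship_id: ", paste(dup, collapse = ", "))
  x$gwt <- as.numeric(x$gwt)
  if (any(is.na(x$gwt) | x$gwt <= 0)) stop("gwt must be > 0 for every ship")
  x[c("ship_id", "ship_type", "gwt")]
}

#' Read a voyage table
#'
#' CSV schema `ship_id,source_port,dest_port,sail_date,arrival_date[,discharge_m3]`,
#' dates in ISO 8601 (`YYYY-MM-DD`). Voyages referencing unknown ports or ships
#' are dropped and counted (attribute `n_dropped`); rows whose arrival precedes
#' their sail date are rejected with a warning (attribute `n_rejected`).
#'
#' @param path CSV file path.
#' @param ports port table from [read_ports()]; used to drop voyages touching
#'   unknown (or environment-less) ports. `NULL` skips the check.
#' @param ships ship table from [read_ships()]; `NULL` skips the check.
#' @return data.frame with `ship_id`, `source`, `dest`, `sail_date`,
#'   `arrival_date` (`Date`), `discharge` (m^3 or `NA`). Kinematics
#'   (distance/duration/velocity) are added later by [derive_kinematics()].
#' @export
read_voyages <- function(path, ports = NULL, ships = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(x) == 0L) {
    out <- data.frame(ship_id = character(), source = character(),
                      dest = character(), sail_date = as.Date(character()),
                      arrival_date = as.Date(character()), discharge = numeric())
    attr(out, "n_dropped") <- 0L; attr(out, "n_rejected") <- 0L
    return(out)
  }
  req <- c("ship_id", "source_port", "dest_port", "sail_date", "arrival_date")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("voyages file missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    ship_id = as.character(x$ship_id),
    source = as.character(x$source_port),
    dest = as.character(x$dest_port),
    sail_date = as.Date(x$sail_date),
    arrival_date = as.Date(x$arrival_date),
    discharge = if ("discharge_m3" %in% names(x)) as.numeric(x$discharge_m3) else NA_real_,
    stringsAsFactors = FALSE
  )
  n_dropped <- 0L
  if (!is.null(ports)) {
    ok <- out$source %in% ports$port_id & out$dest %in% ports$port_id
    n_dropped <- n_dropped + sum(!ok)
    out <- out[ok, , drop = FALSE]
  }
  if (!is.null(ships)) {
    ok <- out$ship_id %in% ships$ship_id
    n_dropped <- n_dropped + sum(!ok)
    out <- out[ok, , drop = FALSE]
  }
  bad <- out$arrival_date < out$sail_date
  n_rejected <- sum(bad)
  if (n_rejected) {
    warning(n_rejected, " voyage(s) rejected: arrival before sail date")
    out <- out[!bad, , drop = FALSE]
  }
  if (n_dropped) message(n_dropped, " voyage(s) dropped for unknown port/ship")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_rejected") <- n_rejected
  out
}

#' @rdname read_voyages
#' @param voyages a voyage table.
#' @export
write_voyages <- function(voyages, path) {
  out <- data.frame(
    ship_id = voyages$ship_id, source_port = voyages$source,
    dest_port = voyages$dest,
    sail_date = format(voyages$sail_date, "%Y-%m-%d"),
    arrival_date = format(voyages$arrival_date, "%Y-%m-%d"),
    discharge_m3 = voyages$discharge
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an ecoregion neighbourhood graph
#'
#' CSV schema `ecoregion_a,ecoregion_b`, one undirected neighbour pair per
#' row. Two ports introduce nonindigenous species to each other only when
#' their ecoregions are neither identical nor neighbours.
#'
#' @param path CSV file path.
#' @param ports optional port table; if given, every port ecoregion must
#'   appear in the graph's ecoregion set (ids seen in the pair file or in the
#'   port table itself).
#' @return an object of class `sf_ecoregions`: list with `ecoregions`
#'   (character) and `neighbors` (2-column character matrix, symmetric
#'   closure applied).
#' @export
read_ecoregions <- function(path, ports = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("ecoregion_a", "ecoregion_b")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("ecoregion file missing column(s): ", paste(miss, collapse = ", "))
  ecoregion_graph(pairs = cbind(as.character(x$ecoregion_a), as.character(x$ecoregion_b)),
                  ports = ports)
}

#' @rdname read_ecoregions
#' @param pairs 2-column matrix/data.frame of unordered neighbour id pairs.
#' @export
ecoregion_graph <- function(pairs, ports = NULL) {
  pairs <- as.matrix(pairs)
  if (length(pairs)) {
    storage.mode(pairs) <- "character"
  } else {
    pairs <- matrix(character(), ncol = 2L)
  }
  eco <- unique(c(pairs[, 1], pairs[, 2], if (!is.null(ports)) ports$ecoregion_id))
  structure(list(ecoregions = eco, neighbor_key = unique(c(
    paste(pairs[, 1], pairs[, 2], sep = "\t"),
    paste(pairs[, 2], pairs[, 1], sep = "\t")
  ))), class = "sf_ecoregions")
}

#' @export
print.sf_ecoregions <- function(x, ...) {
  cat(sprintf("<sf_ecoregions> %d ecoregions, %d undirected neighbour pairs\n",
              length(x$ecoregions), length(x$neighbor_key) / 2L))
  invisible(x)
}

#' Read region-level NIS first-introduction counts
#'
#' CSV schema `region_id,n_first_introductions`. The normalized column (counts
#' min-max scaled into `[0, 1]`) is added on read.
#'
#' @param path CSV file path.
#' @return data.frame with `region_id`, `n_first_introductions`, `normalized`.
#' @export
read_introductions <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("region_id", "n_first_introductions")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("introductions file missing column(s): ", paste(miss, collapse = ", "))
  x$region_id <- as.character(x$region_id)
  x$n_first_introductions <- as.numeric(x$n_first_introductions)
  if (any(is.na(x$n_first_introductions) | x$n_first_introductions < 0))
    stop("introduction counts must be non-negative numbers")
  x$normalized <- minmax_scale(x$n_first_introductions)
  x[c("region_id", "n_first_introductions", "normalized")]
}
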