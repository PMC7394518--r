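#' Risk-model parameters
#'
#' Bundles every fitted constant of the voyage-level risk model: the
#' establishment Gaussian (`alpha`, `delta_T`, `delta_S`), the biofouling
#' accumulation cubics (`beta_tropical`, `beta_temperate`) and survival decay
#' (`gamma`), the per-ship-type antifouling proportions, the ballast mortality
#' and uptake constants (`mu`, `lambda`), the ballast-management efficacy
#' default (`rho_default`) and the per-ship-type discharge coefficients.
#'
#' Defaults reproduce the published constants: `alpha = 0.00015`,
#' `delta_T = 2` degC, `delta_S = 10` ppt, `gamma = 0.008` per (km/day),
#' tropical cubic coefficients `(1.29e-7, 8.316e-5, 0.0149)`, temperate
#' `(1.4e-9, 1.6566e-5, 5.193e-3)`, `mu = 0.02` per day,
#' `lambda = 3.22e-6` per m^3, antifouling proportions Container 0.19,
#' Auto 0.20, Tanker 0.30, Passenger 0.31, Bulk 0.42, General 0.53 and all
#' other types 0.60, and `rho_default = 1` (no ballast-water management
#' modelled).
#'
#' The discharge coefficients (m^3 discharged per GWT tonne) are not published
#' alongside the model; the shipped defaults are synthetic order-of-magnitude
#' values per ship type and should be replaced with survey-derived figures for
#' real analyses.
#'
#' Note on `rho`: as written, the voyage ballast probability is multiplied by
#' `rho`, labelled the efficacy of ballast-water management. A management
#' efficacy that scales risk up rather than down is counterintuitive; it is
#' implemented exactly as the model prints it, and `rho_default = 1` (no
#' management) makes the factor inert by default.
#'
#' Note on `gamma`: with voyage velocity in km/day, `gamma = 0.008` gives
#' survival `exp(-0.008 v)`; at typical commercial speeds (~500 km/day) this is
#' ~2%. The constant is used as printed; override via `gamma` if your velocity
#' units differ.
#'
#' @param ... named overrides for any field listed above. Partial overrides of
#'   the `antifouling`, `discharge_coeff` or `type_alias` tables replace only
#'   the named entries.
#' @return an object of class `sfhon_params` (a validated named list).
#' @examples
#' p <- default_params()
#' p$alpha
#' default_params(gamma = 0.0008)$gamma
#' @export
default_params <- function(...) {
  p <- list(
    alpha = 0.00015,
    delta_T = 2,
    delta_S = 10,
    gamma = 0.008,
    beta_tropical = c(1.29e-7, 8.316e-5, 0.0149),
    beta_temperate = c(1.4e-9, 1.6566e-5, 5.193e-3),
    mu = 0.02,
    lambda = 3.22e-6,
    rho_default = 1,
    antifouling = c(
      Container = 0.19, Auto = 0.20, Tanker = 0.30, Passenger = 0.31,
      Bulk = 0.42, General = 0.53, other = 0.60
    ),
    # synthetic defaults, m^3 per GWT tonne (see ?default_params)
    discharge_coeff = c(
      Container = 0.10, Auto = 0.25, Tanker = 0.30, Passenger = 0.10,
      Bulk = 0.33, General = 0.15, Chemical = 0.30, Gas = 0.25,
      `Ref-Cargo` = 0.15, Research = 0.10, Fishing = 0.10, Yacht = 0.10,
      other = 0.15
    ),
    # maps raw ship_type strings (case-folded) onto antifouling categories
    type_alias = c(
      container = "Container", auto = "Auto", tanker = "Tanker",
      `tanker/oil` = "Tanker", oil = "Tanker", passenger = "Passenger",
      bulk = "Bulk", general = "General"
    ),
    clamp_accumulation = TRUE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    for (nm in names(dots)) {
      if (nm %in% c("antifouling", "discharge_coeff", "type_alias") &&
          !is.null(names(dots[[nm]]))) {
        p[[nm]][names(dots[[nm]])] <- dots[[nm]]
      } else {
        p[[nm]] <- dots[[nm]]
      }
    }
  }
  validate_params(p)
  structure(p, class = "sfhon_params")
}

validate_params <- function(p) {
  stopifnot(
    is.numeric(p$alpha), length(p$alpha) == 1L, p$alpha > 0, p$alpha <= 1,
    p$delta_T > 0, p$delta_S > 0, p$gamma > 0, p$mu > 0, p$lambda > 0,
    length(p$beta_tropical) == 3L, length(p$beta_temperate) == 3L,
    p$rho_default >= 0, p$rho_default <= 1,
    all(p$antifouling >= 0 & p$antifouling <= 1),
    "other" %in% names(p$antifouling),
    all(p$discharge_coeff >= 0),
    "other" %in% names(p$discharge_coeff)
  )
  invisible(p)
}

#' @export
print.sfhon_params <- function(x, ...) {
  cat("<sfhon_params>\n")
  cat(sprintf("  establishment: alpha=%g, delta_T=%g degC, delta_S=%g ppt\n",
              x$alpha, x$delta_T, x$delta_S))
  cat(sprintf("  biofouling:    gamma=%g per (km/day); cubic coefficients per climate zone\n",
              x$gamma))
  cat(sprintf("  ballast:       mu=%g per day, lambda=%g per m^3, rho=%g\n",
              x$mu, x$lambda, x$rho_default))
  cat(sprintf("  antifouling:   %s\n",
              paste(names(x$antifouling), x$antifouling, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Read or write a parameter configuration file
#'
#' Parameters are stored as YAML (or JSON, which YAML parses) with the field
#' names of [default_params()]. Fields absent from the file keep their default
#' values, so a config containing only `gamma: 0.0008` is valid.
#'
#' @param path file path.
#' @param params an `sfhon_params` object (for `write_params`).
#' @return `read_params` returns an `sfhon_params` object.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("antifouling", "discharge_coeff", "type_alias")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  for (nm in c("beta_tropical", "beta_temperate")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.numeric(unlist(raw[[nm]]))
  }
  do.call(default_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sfhon_params"))
  out <- unclass(params)
  out$antifouling <- as.list(out$antifouling)
  out$discharge_coeff <- as.list(out$discharge_coeff)
  out$type_alias <- as.list(out$type_alias)
  yaml::write_yaml(out, path)
  invisible(path)
}

# resolve raw ship_type strings to a coefficient-table category; strings are
# case-folded, passed through the alias table, and fall back to "other"
resolve_ship_type <- function(ship_type, params, table = c("antifouling", "discharge_coeff")) {
  table <- match.arg(table)
  known <- names(params[[table]])
  raw <- trimws(as.character(ship_type))
  key <- tolower(raw)
  mapped <- unname(params$type_alias[key])
  # prefer an exact (case-insensitive) match in the table itself
  direct <- known[match(key, tolower(known))]
  out <- ifelse(!is.na(direct), direct, ifelse(!is.na(mapped), mapped, raw))
  ifelse(out %in% known, out, "other")
}
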