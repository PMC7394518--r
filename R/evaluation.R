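#' Region-level risk from per-port risk
#'
#' Arithmetic mean of per-port risk over the ports of each region (aggregating
#' by sum saturates many regions at 1 and the median pushes them to ~0, so the
#' mean is used). Scored ports without a region raise an error; regions without
#' scored ports are omitted with a warning.
#'
#' @param port_risk named numeric vector of per-port risk (e.g.
#'   `collapse_to_ports(hon)$port_in`).
#' @param ports port table with `region_id`.
#' @return named numeric vector region -> mean port risk.
#' @export
region_risk <- function(port_risk, ports) {
  reg <- ports$region_id[match(names(port_risk), ports$port_id)]
  if (anyNA(reg)) stop("scored port(s) missing from the port table: ",
                       paste(names(port_risk)[is.na(reg)], collapse = ", "))
  out <- tapply(port_risk, reg, mean)
  missing_regions <- setdiff(unique(ports$region_id), names(out))
  if (length(missing_regions))
    warning("region(s) with no scored ports omitted: ",
            paste(missing_regions, collapse = ", "))
  stats::setNames(as.numeric(out), names(out))
}

#' Min-max scaling into [0, 1]
#'
#' `(x - min) / (max - min)`. A constant input is degenerate: all values are
#' set to 0 and the result is flagged with attribute `degenerate = TRUE`.
#'
#' @param x numeric vector (length >= 1).
#' @return scaled vector in `[0, 1]` (names kept).
#' @export
minmax_scale <- function(x) {
  stopifnot(length(x) >= 1L, all(is.finite(x)))
  rng <- range(x)
  if (rng[2] > rng[1]) {
    out <- (x - rng[1]) / (rng[2] - rng[1])
    attr(out, "degenerate") <- FALSE
  } else {
    out <- x * 0
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Evaluate model predictions against introduction records
#'
#' Scales the model's per-region risk and the observed normalized
#' introduction counts to `[0, 1]` (min-max, per model) over the shared
#' region set, and reports per-region squared errors and their mean (MSE).
#'
#' @param predicted named numeric vector of per-region model risk (from
#'   [region_risk()]).
#' @param observations introductions table from [read_introductions()] (or any
#'   data.frame with `region_id` and `normalized`).
#' @param model_name label stored in the result.
#' @param rescale_predictions min-max scale the predictions (default `TRUE`);
#'   observations are assumed already normalized.
#' @return object of class `sf_evaluation`: list with `per_region`
#'   (data.frame `region_id`, `predicted_scaled`, `observed`, `error`
#'   (signed, predicted - observed), `squared_error`), `mse`, `n_regions`,
#'   `model_name`.
#' @export
evaluate_predictions <- function(predicted, observations,
                                 model_name = "model",
                                 rescale_predictions = TRUE) {
  obs <- stats::setNames(observations$normalized, observations$region_id)
  common <- intersect(names(predicted), names(obs))
  extra <- c(setdiff(names(predicted), names(obs)),
             setdiff(names(obs), names(predicted)))
  if (!length(common)) stop("no shared regions between predictions and observations")
  if (length(extra))
    warning("region(s) present on one side only, dropped: ",
            paste(unique(extra), collapse = ", "))
  common <- sort(common)
  pred <- predicted[common]
  if (rescale_predictions) pred <- minmax_scale(pred)
  err <- as.numeric(pred) - as.numeric(obs[common])
  per_region <- data.frame(region_id = common,
                           predicted_scaled = as.numeric(pred),
                           observed = as.numeric(obs[common]),
                           error = err, squared_error = err^2,
                           stringsAsFactors = FALSE)
  structure(list(per_region = per_region, mse = mean(err^2),
                 n_regions = length(common), model_name = model_name),
            class = "sf_evaluation")
}

#' @export
print.sf_evaluation <- function(x, ...) {
  cat(sprintf("<sf_evaluation:%s> %d regions, MSE %.6g\n",
              x$model_name, x$n_regions, x$mse))
  invisible(x)
}

#' Paired two-tailed t-test between two models' per-region errors
#'
#' Tests whether the per-region squared errors of two models differ, pairing
#' by region. Degenerate cases are flagged: when every paired difference is
#' zero the p-value is reported as 1; when the differences are constant but
#' non-zero the t statistic is infinite and p is 0.
#'
#' @param eval_a,eval_b `sf_evaluation` objects over the same regions.
#' @return list with `t`, `df`, `p_value`, `mean_diff` (a minus b) and `flag`.
#' @export
compare_models <- function(eval_a, eval_b) {
  a <- stats::setNames(eval_a$per_region$squared_error, eval_a$per_region$region_id)
  b <- stats::setNames(eval_b$per_region$squared_error, eval_b$per_region$region_id)
  if (!setequal(names(a), names(b)))
    stop("region mismatch: ",
         paste(union(setdiff(names(a), names(b)), setdiff(names(b), names(a))),
               collapse = ", "))
  regions <- sort(names(a))
  d <- a[regions] - b[regions]
  n <- length(d)
  if (n < 2L) stop("need at least 2 paired regions")
  s <- stats::sd(d)
  flag <- NULL
  if (s == 0) {
    if (mean(d) == 0) {
      t <- 0; p <- 1
      flag <- "identical error vectors; p reported as 1"
    } else {
      t <- sign(mean(d)) * Inf; p <- 0
      flag <- "constant non-zero differences; zero variance"
    }
  } else {
    t <- mean(d) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(t = unname(t), df = n - 1L, p_value = unname(p),
       mean_diff = unname(mean(d)), flag = flag)
}

#' Over- / under-estimation shares
#'
#' Fraction of regions where the scaled prediction exceeds (over) or falls
#' below (under) the observation; exact ties count as neither, so the shares
#' may sum to less than 1.
#'
#' @param evaluation an `sf_evaluation`.
#' @return list with `over_share`, `under_share`, `n_regions`.
#' @export
direction_report <- function(evaluation) {
  e <- evaluation$per_region$error
  list(over_share = mean(e > 0), under_share = mean(e < 0),
       n_regions = length(e))
}
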