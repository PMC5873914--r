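# Deterministic growth-curve core: logistic leaf growth on a thermal-time
# (degree-day) axis and the function-valued trait (FVT) transforms derived
# from it.

#' Logistic growth-curve parameters
#'
#' Bundle and validate the parameters of a logistic leaf growth curve on a
#' degree-day axis: the intrinsic growth rate `r` (1/DD), the asymptotic
#' leaf size `Lmax` (mm) and the initial size at germination `L0` (mm).
#'
#' @param r Intrinsic growth rate, per degree day. Must be positive.
#' @param Lmax Asymptotic (final) leaf size in mm. Must exceed `L0`.
#' @param L0 Initial leaf size at germination in mm. Must be positive.
#' @param trait_label Optional label for the measurement the parameters
#'   describe (e.g. `"leaf_width"`).
#' @return An object of class `logistic_params` (a named list).
#' @examples
#' p <- logistic_params(r = 0.1, Lmax = 100, L0 = 5)
#' logistic_size(p, 30)
#' @export
logistic_params <- function(r, Lmax, L0, trait_label = NA_character_) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'r' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(Lmax) || length(Lmax) != 1L || !is.finite(Lmax))
    stop("'Lmax' must be a single finite number", call. = FALSE)
  if (!is.numeric(L0) || length(L0) != 1L || !is.finite(L0) || L0 <= 0)
    stop("'L0' must be a single positive finite number", call. = FALSE)
  if (Lmax <= L0)
    stop("'Lmax' must exceed 'L0'", call. = FALSE)
  structure(list(r = r, Lmax = Lmax, L0 = L0, trait_label = trait_label),
            class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("Logistic growth parameters%s\n",
              if (is.na(x$trait_label)) "" else paste0(" (", x$trait_label, ")")))
  cat(sprintf("  r    = %.4g /DD\n  Lmax = %.4g mm\n  L0   = %.4g mm\n",
              x$r, x$Lmax, x$L0))
  invisible(x)
}

as_logistic_params <- function(params) {
  if (inherits(params, "logistic_params")) return(params)
  if (is.list(params) || is.numeric(params)) {
    p <- as.list(params)
    return(logistic_params(p$r, p$Lmax, p$L0,
                           trait_label = if (is.null(p$trait_label))
                             NA_character_ else p$trait_label))
  }
  stop("cannot interpret 'params' as logistic parameters", call. = FALSE)
}

#' Evaluate the logistic growth curve
#'
#' Closed-form solution of the logistic growth equation
#' \deqn{dL/dt = r L (1 - L / L_{max})}
#' with initial condition \eqn{L(0) = L_0}:
#' \deqn{L(t) = L_{max} / (1 + A e^{-r t}), \quad A = (L_{max} - L_0)/L_0.}
#' The curve is strictly increasing in thermal time and bounded in
#' (`L0`, `Lmax`).
#'
#' @param params A [logistic_params()] object (or coercible list).
#' @param t Thermal time in degree days; vector of non-negative values.
#' @return Leaf size in mm, same length as `t`.
#' @export
logistic_size <- function(params, t) {
  params <- as_logistic_params(params)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative", call. = FALSE)
  A <- (params$Lmax - params$L0) / params$L0
  params$Lmax / (1 + A * exp(-params$r * t))
}

# Vectorized evaluation without validation; used in the MCMC inner loop
# where r, Lmax, L0 vary per observation.
logistic_size_vec <- function(r, Lmax, L0, t) {
  Lmax / (1 + ((Lmax - L0) / L0) * exp(-r * t))
}

#' Inflection time of the growth curve
#'
#' Thermal time `iD` at which leaf growth transitions from accelerating to
#' decelerating, i.e. where \eqn{L(t) = L_{max}/2}. For the logistic curve
#' this is \eqn{iD = \log((L_{max}-L_0)/L_0) / r}.
#'
#' If `L0 >= Lmax/2` the inflection precedes the observation window; the
#' function returns 0 with a warning (flagged degenerate case).
#'
#' @inheritParams logistic_size
#' @return Inflection time in degree days.
#' @export
inflection_time <- function(params) {
  params <- as_logistic_params(params)
  if (params$L0 >= params$Lmax / 2) {
    if (params$L0 > params$Lmax / 2)
      warning("L0 >= Lmax/2: inflection precedes germination; returning 0",
              call. = FALSE)
    return(0)
  }
  log((params$Lmax - params$L0) / params$L0) / params$r
}

#' Thermal time to a fraction of final size
#'
#' Closed-form inversion of the logistic curve: the degree-day time at
#' which the leaf reaches `fraction * Lmax`. With `fraction = 0.95` this is
#' the growth-duration trait `d` (germination to 95% of final size).
#'
#' @inheritParams logistic_size
#' @param fraction Target proportion of `Lmax`, strictly between
#'   `L0/Lmax` and 1. Default 0.95.
#' @return Degree days to reach the target fraction.
#' @export
duration_to_fraction <- function(params, fraction = 0.95) {
  params <- as_logistic_params(params)
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction))
    stop("'fraction' must be a single finite number", call. = FALSE)
  if (fraction <= params$L0 / params$Lmax || fraction >= 1)
    stop("'fraction' must lie strictly between L0/Lmax and 1", call. = FALSE)
  A <- (params$Lmax - params$L0) / params$L0
  log(A * fraction / (1 - fraction)) / params$r
}

#' Derived function-valued traits
#'
#' Convenience wrapper returning both derived FVT parameters: the growth
#' duration `d` (time to 95% of `Lmax`) and inflection time `iD`.
#'
#' @inheritParams logistic_size
#' @return Named list with elements `d` and `iD` (degree days).
#' @export
derived_fvt <- function(params) {
  params <- as_logistic_params(params)
  list(d = duration_to_fraction(params, 0.95),
       iD = inflection_time(params))
}

#' Accumulate degree days from daily temperature extremes
#'
#' Thermal time via the simple-average method: each day contributes
#' `max(0, (tmin + tmax)/2 - base)` degree days. The default base
#' temperature is the species-specific 0.96 degrees C.
#'
#' @param tmin,tmax Aligned daily minimum/maximum temperatures (deg C).
#' @param base Base temperature in deg C (default 0.96).
#' @param dates Optional vector of dates aligned with the series.
#' @return A `thermal_time` data.frame with columns `date`, `daily_dd`
#'   and `cumulative_dd`; the base temperature is attached as attribute
#'   `base_temp`.
#' @export
accumulate_degree_days <- function(tmin, tmax, base = 0.96, dates = NULL) {
  if (length(tmin) != length(tmax))
    stop("'tmin' and 'tmax' must have equal length", call. = FALSE)
  if (length(tmin) == 0L)
    stop("empty temperature series", call. = FALSE)
  if (any(!is.finite(tmin)) || any(!is.finite(tmax)))
    stop("temperature series must be finite", call. = FALSE)
  if (is.null(dates)) dates <- seq_along(tmin)
  daily <- pmax(0, (tmin + tmax) / 2 - base)
  out <- data.frame(date = dates, daily_dd = daily,
                    cumulative_dd = cumsum(daily))
  attr(out, "base_temp") <- base
  class(out) <- c("thermal_time", "data.frame")
  out
}

#' Read a daily temperature CSV and accumulate degree days
#'
#' Expects columns `date`, `tmin_c`, `tmax_c`.
#'
#' @param path Path to the CSV file.
#' @inheritParams accumulate_degree_days
#' @return A `thermal_time` data.frame (see [accumulate_degree_days()]).
#' @export
read_thermal_time <- function(path, base = 0.96) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin_c", "tmax_c")
  if (!all(need %in% names(df)))
    stop("temperature CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  accumulate_degree_days(df$tmin_c, df$tmax_c, base = base, dates = df$date)
}

#' Write a thermal-time series to CSV
#'
#' @param x A `thermal_time` data.frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_thermal_time <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
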