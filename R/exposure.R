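#' Extract the series an occupant experiences
#'
#' Maps a per-zone concentration series through a room-occupancy schedule.
#' Intervals spent outdoors contribute the outdoor concentration for
#' outdoor-origin species (CONTA, CONTB) and zero for the indoor stove species.
#'
#' @param series A `concentration_series` from [simulate_day()].
#' @param occupancy Character vector of 144 zone labels (or `"OUTDOORS"`).
#' @param species One of `"NO2_stove"`, `"CONTA"`, `"CONTB"`.
#' @return Numeric vector of 144 exposures, ppbv.
#' @export
person_series <- function(series, occupancy, species = "NO2_stove") {
  stopifnot(inherits(series, "concentration_series"),
            length(occupancy) == N_INTERVALS)
  species <- match.arg(species, dimnames(series)$species)
  zones <- dimnames(series)$zone
  unknown <- setdiff(unique(occupancy), c(zones, OUTDOORS))
  if (length(unknown))
    stop("occupancy references unknown zone(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  outdoor_val <- if (species == "NO2_stove") 0 else attr(series, "conta_outdoor")
  out <- numeric(N_INTERVALS)
  idx <- match(occupancy, zones)
  for (i in seq_len(N_INTERVALS)) {
    out[i] <- if (is.na(idx[i])) outdoor_val else series[idx[i], species, i]
  }
  out
}

#' Chronic (long-term) exposure for one modeled day
#'
#' The arithmetic mean of the 144 10-min exposures — the long-term mean
#' assuming the modeled 24-h day repeats indefinitely.
#'
#' @param x Numeric vector of 144 10-min exposures, ppbv.
#' @return Mean exposure, ppbv.
#' @export
chronic_exposure <- function(x) {
  if (length(x) != N_INTERVALS)
    stop("expected 144 10-min values", call. = FALSE)
  mean(x)
}

#' Acute (maximum hour-averaged) exposure for one modeled day
#'
#' The maximum, over all 139 complete 1-h windows (6 consecutive 10-min
#' intervals) in the day, of the window mean. Windows do not wrap around
#' midnight: the modeled day is a standalone 24-h period.
#'
#' @param x Numeric vector of 144 10-min exposures, ppbv.
#' @return Maximum hour-averaged exposure, ppbv.
#' @export
acute_exposure <- function(x) {
  if (length(x) != N_INTERVALS)
    stop("expected 144 10-min values", call. = FALSE)
  cs <- cumsum(c(0, x))
  max((cs[7:(N_INTERVALS + 1)] - cs[1:(N_INTERVALS - 5)]) / 6)
}

#' Scale tracer infiltration to outdoor-attributable NO2
#'
#' The infiltration tracer is held at 100 ppbv outdoors, so a modeled tracer
#' exposure reads as a percent infiltration; outdoor-attributable NO2 exposure
#' is that percentage applied to the local outdoor NO2 concentration:
#' `OA_NO2 = OA_CONTA * [NO2] / [CONTA]`.
#'
#' @param conta_exposure Modeled tracer exposure, ppbv (in `[0, conta_reference]`).
#' @param outdoor_no2 Local outdoor NO2, ppbv.
#' @param conta_reference Outdoor tracer level, ppbv (100).
#' @return Outdoor-attributable NO2 exposure, ppbv.
#' @export
outdoor_attributable <- function(conta_exposure, outdoor_no2,
                                 conta_reference = 100) {
  if (any(conta_exposure < 0) ||
      any(conta_exposure > conta_reference + 1e-9))
    stop("tracer exposure must lie in [0, ", conta_reference, "] ppbv",
         call. = FALSE)
  conta_exposure * outdoor_no2 / conta_reference
}

#' Weekly expectation of day-level exposures
#'
#' Weights day-level chronic and acute exposures by their weekly prevalence
#' (e.g. no-cook/typical/heavy days at 2/7, 4/7, 1/7) to produce the
#' scenario-level exposure.
#'
#' @param chron_days,acute_days Day-level values, ppbv.
#' @param weights Normalized day weights (e.g. from [weekly_weights()]).
#' @return List with `chron` and `acute`, ppbv.
#' @export
weekly_expectation <- function(chron_days, acute_days, weights) {
  if (length(chron_days) != length(weights) ||
      length(acute_days) != length(weights))
    stop("day values and weights must have equal length", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must be normalized", call. = FALSE)
  list(chron = sum(chron_days * weights),
       acute = sum(acute_days * weights))
}

#' Days per year above an acute threshold
#'
#' Computes the weighted fraction of modeled person-days whose maximum
#' hour-averaged exposure exceeds a threshold, times 365. Because the
#' prevalence assigned to heavy (95th-percentile) stove-use weeks dominates
#' this statistic and is uncertain, the fraction is computed once per
#' heavy-week prevalence (default 10% and a 5% sensitivity value) and reported
#' as a range.
#'
#' @param acute_day Day-level maximum hour-averaged exposures, ppbv.
#' @param weight Day weights (normalized within the input set).
#' @param is_heavy_week Logical: does the day belong to a heavy-use week?
#' @param threshold Acute benchmark, ppbv (default 100: the WHO 200 ug/m3
#'   (~100 ppbv) 1-h guideline and the EPA 100 ppbv standard coincide).
#' @param heavy_week_weights Heavy-week prevalences to evaluate.
#' @return Named numeric vector of days/year, one per heavy-week prevalence.
#' @export
exceedance_days_per_year <- function(acute_day, weight, is_heavy_week,
                                     threshold = 100,
                                     heavy_week_weights = c(0.10, 0.05)) {
  n <- length(acute_day)
  if (!n) stop("no modeled days supplied", call. = FALSE)
  stopifnot(length(weight) == n, length(is_heavy_week) == n, threshold > 0)
  weight <- weight / sum(weight)
  over <- acute_day > threshold
  vapply(heavy_week_weights, function(hw) {
    w <- weight
    wh <- sum(w[is_heavy_week])
    if (wh > 0 && wh < 1) {
      w[is_heavy_week] <- w[is_heavy_week] * hw / wh
      w[!is_heavy_week] <- w[!is_heavy_week] * (1 - hw) / (1 - wh)
    }
    365 * sum(w[over])
  }, 0, USE.NAMES = FALSE) -> days
  names(days) <- paste0("heavy_", format(heavy_week_weights))
  days
}
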