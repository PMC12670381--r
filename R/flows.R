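#' Simulation configuration
#'
#' Environmental drivers and numerical settings for one modeled 24-h day.
#'
#' The airflow driver for leakage paths is
#' `wind_coef * windspeed + stack_coef * sqrt(|dT|) + min_infiltration`,
#' where `dT` is the indoor/outdoor temperature difference. With the defaults
#' (`wind_coef = 0.08` per m/s, `stack_coef = 0.04` per sqrt(K)) the driver
#' equals 1 at the calibration point used when sizing synthetic floorplan
#' leakage (10 m/s wind, 25 K temperature difference), and 0 in still air at
#' equal temperatures, reproducing the 0 to ~6 per hour whole-dwelling
#' air-exchange range the model is anchored to.
#'
#' @param decay_rate First-order indoor NO2 loss rate, per hour (negative;
#'   default -0.86).
#' @param ambient_temperature Outdoor temperature, degrees C.
#' @param indoor_temperature Indoor temperature, degrees C (default 20).
#' @param windspeed Ground windspeed, m/s.
#' @param outdoor_no2 Outdoor NO2, ppbv (used when scaling infiltration).
#' @param conta_outdoor Outdoor concentration of the infiltration tracer, ppbv
#'   (fixed at 100 so indoor tracer reads as percent infiltration).
#' @param internal_timestep Internal step, s; must divide `output_interval`.
#' @param output_interval Output step, s; must be 600 (10 min) so a day has
#'   exactly 144 intervals.
#' @param min_infiltration Driver floor (dimensionless, default 0).
#' @param wind_coef,stack_coef Driver coefficients (see Details).
#' @param forced_air_ach Recirculation rate added between each zone and the
#'   central hub while the forced-air system runs, in zone volumes per hour.
#' @param forced_air_on Is the forced-air system running (heating/cooling
#'   season)? If `NA`, it runs when `ambient_temperature` is outside 15-25 C.
#' @return A `sim_config` object.
#' @export
sim_config <- function(decay_rate = -0.86,
                       ambient_temperature = 20,
                       indoor_temperature = 20,
                       windspeed = 0,
                       outdoor_no2 = 10,
                       conta_outdoor = 100,
                       internal_timestep = 60,
                       output_interval = 600,
                       min_infiltration = 0,
                       wind_coef = 0.08,
                       stack_coef = 0.04,
                       forced_air_ach = 5,
                       forced_air_on = NA) {
  if (decay_rate > 0) stop("decay_rate must be <= 0 (a loss)", call. = FALSE)
  if (86400 %% output_interval != 0 || 86400 / output_interval != N_INTERVALS)
    stop("output_interval must give exactly 144 intervals per day",
         call. = FALSE)
  if (output_interval %% internal_timestep != 0)
    stop("internal_timestep must divide output_interval", call. = FALSE)
  if (windspeed < 0) stop("windspeed must be non-negative", call. = FALSE)
  if (conta_outdoor <= 0) stop("conta_outdoor must be positive", call. = FALSE)
  if (is.na(forced_air_on))
    forced_air_on <- ambient_temperature < 15 || ambient_temperature > 25
  structure(
    list(decay_rate = decay_rate,
         ambient_temperature = ambient_temperature,
         indoor_temperature = indoor_temperature,
         windspeed = windspeed, outdoor_no2 = outdoor_no2,
         conta_outdoor = conta_outdoor,
         internal_timestep = internal_timestep,
         output_interval = output_interval,
         min_infiltration = min_infiltration,
         wind_coef = wind_coef, stack_coef = stack_coef,
         forced_air_ach = forced_air_ach,
         forced_air_on = isTRUE(forced_air_on)),
    class = "sim_config"
  )
}

# wind/stack driver multiplier applied to leakage reference flows
flow_driver <- function(config) {
  dt <- abs(config$ambient_temperature - config$indoor_temperature)
  config$wind_coef * config$windspeed + config$stack_coef * sqrt(dt) +
    config$min_infiltration
}

# zone label used as the forced-air return/supply hub
forced_air_hub <- function(fp) {
  kinds <- zone_kinds(fp)
  ids <- names(kinds)
  if (any(kinds == "hallway")) return(ids[kinds == "hallway"][1L])
  if (any(kinds == "living")) return(ids[kinds == "living"][1L])
  ids[1L]
}

#' Compute the balanced inter-zone airflow matrix
#'
#' Replaces a full pressure-network airflow solution with a parametric
#' wind/stack model. Every path carries equal bi-directional flow, so each
#' zone's air inflow equals its outflow by construction. Leakage path flows
#' scale with the wind/stack driver (see [sim_config()]); open windows add
#' their reference flow while open; interzone openings always carry their
#' reference flow; a running forced-air system adds recirculation between each
#' zone and a central hub.
#'
#' @param fp A [floorplan()].
#' @param config A [sim_config()].
#' @param window_state Either a single logical (all operable windows open or
#'   closed) or a named logical vector per zone.
#' @return A square matrix `Q` (m3/h) over `c(zones, "OUTDOORS")`, where
#'   `Q[a, b]` is the flow from `a` to `b`; symmetric, hence balanced.
#' @export
compute_flows <- function(fp, config, window_state = FALSE) {
  validate_floorplan(fp)
  stopifnot(inherits(config, "sim_config"))
  ids <- zone_ids(fp)
  if (length(window_state) == 1L)
    window_state <- setNames(rep(isTRUE(window_state), length(ids)), ids)
  nodes <- c(ids, OUTDOORS)
  q <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  m <- flow_driver(config)
  for (p in fp$paths) {
    f <- switch(p$kind,
      leakage = p$reference_flow * m,
      interzone_opening = p$reference_flow,
      open_window = {
        z <- if (p$from_zone == OUTDOORS) p$to_zone else p$from_zone
        if (isTRUE(window_state[[z]])) p$reference_flow else 0
      }
    )
    q[p$from_zone, p$to_zone] <- q[p$from_zone, p$to_zone] + f
    q[p$to_zone, p$from_zone] <- q[p$to_zone, p$from_zone] + f
  }
  if (fp$has_forced_air && config$forced_air_on) {
    hub <- forced_air_hub(fp)
    vols <- zone_volumes(fp)
    for (z in setdiff(ids, hub)) {
      f <- config$forced_air_ach * vols[[z]]
      q[z, hub] <- q[z, hub] + f
      q[hub, z] <- q[hub, z] + f
    }
  }
  q
}

#' Whole-dwelling air exchange rate implied by a flow matrix
#'
#' Total outdoor-air inflow divided by total indoor volume, per hour.
#'
#' @param q A flow matrix from [compute_flows()].
#' @param fp The corresponding floorplan.
#' @return Air changes per hour.
#' @export
whole_house_aer <- function(q, fp) {
  ids <- zone_ids(fp)
  sum(q[OUTDOORS, ids]) / sum(zone_volumes(fp))
}
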