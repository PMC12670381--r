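# Deterministic daily schedules on the 144-interval (10-min) grid.
# Interval i covers clock time [(i-1)*10, i*10) minutes after midnight.

interval_at <- function(hour) as.integer(hour * 6) + 1L

# meal start intervals: breakfast 07:00, lunch 12:00, dinner 18:00
MEAL_STARTS <- c(breakfast = 43L, lunch = 73L, dinner = 109L)

#' Cooking emission pattern for one day type
#'
#' Unit-total emission schedules: the returned 144-vector of mg/h rates
#' integrates to exactly 1 mg over the day, so scaling it by a daily emission
#' gives that day's schedule. The `"typical"` pattern cooks 80 min/day
#' (20 breakfast / 20 lunch / 40 dinner); `"heavy"` cooks 160 min/day with
#' doubled episode lengths; `"none"` is all zero.
#'
#' @param pattern `"none"`, `"typical"` or `"heavy"`.
#' @return Numeric vector of 144 emission rates, mg/h, summing to 1 mg/day
#'   (except `"none"`).
#' @export
cooking_pattern <- function(pattern = c("typical", "heavy", "none")) {
  pattern <- match.arg(pattern)
  rate <- numeric(N_INTERVALS)
  if (pattern == "none") return(rate)
  lens <- if (pattern == "typical") c(2L, 2L, 4L) else c(4L, 4L, 8L)
  for (m in seq_along(MEAL_STARTS)) {
    idx <- MEAL_STARTS[m] + seq_len(lens[m]) - 1L
    rate[idx] <- 1
  }
  minutes <- sum(lens) * 10
  rate * 60 / minutes  # total = minutes/60 h * rate = 1 mg
}

#' Intervals during which cooking occurs for a pattern
#'
#' Used as the range-hood-on schedule: hoods, when used, run while cooking.
#'
#' @inheritParams cooking_pattern
#' @return Logical vector of 144.
#' @export
cooking_intervals <- function(pattern = c("typical", "heavy", "none")) {
  cooking_pattern(pattern) > 0
}

#' Window-opening schedule
#'
#' Windows open as a block in the middle of the day: 4-h schedules run
#' 11:00-15:00, 12-h schedules 08:00-20:00.
#'
#' @param open_hours 0, 4 or 12.
#' @return Logical vector of 144 (whole-dwelling open state; open means the
#'   kitchen, bedroom and living-room windows are open together).
#' @export
window_schedule_hours <- function(open_hours) {
  s <- rep(FALSE, N_INTERVALS)
  if (open_hours <= 0) return(s)
  start <- if (open_hours <= 4) interval_at(11) else interval_at(8)
  s[start + seq_len(as.integer(open_hours * 6)) - 1L] <- TRUE
  s
}

#' Build a deterministic room-occupancy schedule
#'
#' A stylized day: bedroom overnight (to 07:00 and after 22:00), living room
#' otherwise, an outdoor block starting at 09:00, and kitchen blocks at meal
#' times (a quarter of the kitchen time at breakfast and lunch, half at
#' dinner). Kitchen time takes precedence over the outdoor block.
#'
#' @param fp A [floorplan()] supplying the zone labels.
#' @param kitchen_min Minutes/day in the kitchen (rounded to 10-min intervals).
#' @param outdoor_min Minutes/day outdoors.
#' @return Character vector of 144 zone labels (or `"OUTDOORS"`).
#' @export
build_occupancy_schedule <- function(fp, kitchen_min = 35, outdoor_min = 120) {
  kinds <- zone_kinds(fp)
  kitchen <- names(kinds)[kinds == "kitchen"][1L]
  bedroom <- if (any(kinds == "bedroom")) names(kinds)[kinds == "bedroom"][1L]
             else kitchen
  living <- if (any(kinds == "living")) names(kinds)[kinds == "living"][1L]
            else bedroom
  occ <- rep(living, N_INTERVALS)
  occ[1:(interval_at(7) - 1L)] <- bedroom
  occ[interval_at(22):N_INTERVALS] <- bedroom
  n_out <- min(as.integer(round(outdoor_min / 10)), interval_at(22) - interval_at(9))
  if (n_out > 0)
    occ[interval_at(9) + seq_len(n_out) - 1L] <- OUTDOORS
  n_kit <- as.integer(round(kitchen_min / 10))
  shares <- c(0.25, 0.25, 0.5)
  lens <- floor(n_kit * shares)
  lens[3] <- n_kit - sum(lens[1:2])
  for (m in seq_along(MEAL_STARTS)) {
    if (lens[m] > 0)
      occ[MEAL_STARTS[m] + seq_len(lens[m]) - 1L] <- kitchen
  }
  occ
}

# population-weighted representative ambient temperature of a band
band_temperature <- function(temp_axis, band) {
  degs <- vapply(temp_axis$levels, `[[`, 0, "deg_c")
  w <- axis_weights(temp_axis)
  sel <- if (band == "cold") degs < 15 else degs >= 15
  if (!any(sel)) stop("no temperature levels in band '", band, "'",
                      call. = FALSE)
  sum(degs[sel] * w[sel]) / sum(w[sel])
}

#' Scenario-level exposures for one floorplan in one temperature band
#'
#' Runs the multizone simulator over the distinct physical configurations
#' (windspeed x window schedule; the representative band temperature) and
#' assembles the 540-scenario exposure table. The stove channel is linear in
#' the emission rate, so each configuration is simulated once per cooking
#' pattern at unit emission and scenario values are obtained by scaling with
#' the stove-use level's daily emission, the day type's multiplier and the
#' hood level's `1 - capture_efficiency`; the tracer channel is independent of
#' the stove and reused across those factors.
#'
#' @param fp A [floorplan()].
#' @param band `"cold"` or `"warm"`.
#' @param axes Scenario axes (default [default_scenario_axes()] for the band).
#' @param day_types Day-type table (default [default_day_types()]).
#' @param decay_rate Indoor NO2 loss rate, per hour.
#' @param conta_outdoor Outdoor tracer level, ppbv.
#' @return A data frame with one row per scenario: axis labels, `weight`,
#'   `chron_stove`, `acute_stove` (ppbv), `chron_conta`, `acute_conta`
#'   (percent infiltration), `band`, `floorplan_id`. A `day_level` attribute
#'   holds the per-day acute values used for exceedance-day statistics.
#' @export
floorplan_scenario_exposures <- function(fp, band = c("cold", "warm"),
                                         axes = default_scenario_axes(band),
                                         day_types = default_day_types(),
                                         decay_rate = -0.86,
                                         conta_outdoor = 100) {
  band <- match.arg(band)
  validate_floorplan(fp)
  grid <- temperature_conditioned_grid(axes, band)
  amb <- band_temperature(axes$ambient_temperature, band)
  kitchen <- names(zone_kinds(fp))[zone_kinds(fp) == "kitchen"][1L]

  wind_levels <- axes$windspeed$levels
  win_levels <- axes$window_schedule$levels
  occ_levels <- axes$occupancy$levels
  patterns <- setdiff(unique(day_types$pattern), "none")

  # person-level unit responses per (windspeed, window, occupancy)
  lut <- list()
  for (wl in wind_levels) {
    for (vl in win_levels) {
      config <- sim_config(decay_rate = decay_rate,
                           ambient_temperature = amb,
                           windspeed = wl$m_s, conta_outdoor = conta_outdoor)
      wsched <- window_schedule_hours(vl$open_hours)
      sims <- lapply(patterns, function(p)
        simulate_day(fp, source_schedule(kitchen, cooking_pattern(p)),
                     config, window_schedule = wsched))
      names(sims) <- patterns
      for (ol in occ_levels) {
        occ <- build_occupancy_schedule(fp, ol$kitchen_min, ol$outdoor_min)
        key <- paste(wl$label, vl$label, ol$label, sep = "|")
        stove <- lapply(sims, function(s) {
          ps <- person_series(s, occ, "NO2_stove")
          c(chron = chronic_exposure(ps), acute = acute_exposure(ps))
        })
        pc <- person_series(sims[[1L]], occ, "CONTA")
        lut[[key]] <- list(
          stove = stove,
          conta = c(chron = chronic_exposure(pc), acute = acute_exposure(pc))
        )
      }
    }
  }

  ce <- vapply(axes$hood_use$levels, `[[`, 0, "capture_efficiency")
  names(ce) <- axis_labels(axes$hood_use)
  daily_mg <- vapply(axes$stove_use$levels, `[[`, 0, "daily_no2_mg")
  names(daily_mg) <- axis_labels(axes$stove_use)
  heavy <- vapply(axes$stove_use$levels, `[[`, NA, "heavy")
  names(heavy) <- axis_labels(axes$stove_use)

  n <- nrow(grid)
  chron_stove <- acute_stove <- chron_conta <- acute_conta <- numeric(n)
  day_rows <- vector("list", n)
  for (r in seq_len(n)) {
    key <- paste(grid$windspeed[r], grid$window_schedule[r],
                 grid$occupancy[r], sep = "|")
    u <- lut[[key]]
    scale0 <- daily_mg[[grid$stove_use[r]]] * (1 - ce[[grid$hood_use[r]]])
    cd <- ad <- numeric(nrow(day_types))
    for (d in seq_len(nrow(day_types))) {
      p <- day_types$pattern[d]
      if (p != "none") {
        sc <- scale0 * day_types$emission_multiplier[d]
        cd[d] <- u$stove[[p]]["chron"] * sc
        ad[d] <- u$stove[[p]]["acute"] * sc
      }
    }
    wk <- weekly_expectation(cd, ad, day_types$weight)
    chron_stove[r] <- wk$chron
    acute_stove[r] <- wk$acute
    chron_conta[r] <- u$conta["chron"]
    acute_conta[r] <- u$conta["acute"]
    day_rows[[r]] <- data.frame(
      scenario = r, day_type = day_types$day_type,
      weight = grid$weight[r] * day_types$weight,
      acute_stove_day = ad,
      is_heavy_week = heavy[[grid$stove_use[r]]]
    )
  }
  out <- cbind(grid,
               data.frame(chron_stove = chron_stove,
                          acute_stove = acute_stove,
                          chron_conta = chron_conta,
                          acute_conta = acute_conta))
  out$band <- band
  out$floorplan_id <- fp$floorplan_id
  attr(out, "day_level") <- do.call(rbind, day_rows)
  out
}
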