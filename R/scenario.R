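#' Define a scenario axis
#'
#' One behavioural or environmental dimension of the factorial scenario grid,
#' with weighted levels. Level weights must be non-negative and sum to 1.
#'
#' @param name Axis name; one of `"hood_use"`, `"stove_use"`, `"occupancy"`,
#'   `"windspeed"`, `"window_schedule"`, `"ambient_temperature"`.
#' @param levels A list of levels, each a list with `label`, `weight`, and any
#'   payload fields the level carries (e.g. `capture_efficiency` for hood
#'   levels).
#' @return A `scenario_axis` object.
#' @export
scenario_axis <- function(name, levels) {
  name <- match.arg(name, c("hood_use", "stove_use", "occupancy",
                            "windspeed", "window_schedule",
                            "ambient_temperature"))
  if (!length(levels)) stop("axis '", name, "' has no levels", call. = FALSE)
  w <- vapply(levels, `[[`, 0, "weight")
  if (any(w < 0)) stop("level weights must be >= 0", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9)
    stop("level weights on axis '", name, "' must sum to 1", call. = FALSE)
  labels <- vapply(levels, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate level labels", call. = FALSE)
  structure(list(name = name, levels = levels), class = "scenario_axis")
}

axis_labels <- function(axis) vapply(axis$levels, `[[`, "", "label")
axis_weights <- function(axis) vapply(axis$levels, `[[`, 0, "weight")

#' Replace the weights of an axis
#'
#' @param axis A [scenario_axis()].
#' @param weights New weights (same length as the levels; must sum to 1).
#' @return The axis with updated weights.
#' @export
set_axis_weights <- function(axis, weights) {
  stopifnot(inherits(axis, "scenario_axis"),
            length(weights) == length(axis$levels))
  levels <- Map(function(l, w) { l$weight <- w; l }, axis$levels, weights)
  scenario_axis(axis$name, levels)
}

# axes whose levels/weights do not vary with geography
GEO_INDEPENDENT_AXES <- c("hood_use", "stove_use", "occupancy", "windspeed")

#' Default scenario axes
#'
#' The six behavioural/environmental axes with default level counts
#' (4 hood-use, 3 stove-use, 5 occupancy, 3 windspeed, 3 window-schedule,
#' 4 ambient-temperature), giving the canonical grid sizes: a 180-scenario
#' geography-independent core, 540 scenarios per temperature band, and 2,160
#' per floorplan overall. Payload values are central defaults (e.g. hood-unused
#' probability 0.64, stove-use levels anchored at 0.64/31/199 mg NO2 per
#' typical cooking day for the 5th/50th/95th use percentiles, kitchen occupancy
#' 5/35/150 min/day); all are overridable by building axes directly.
#'
#' Window-schedule weights depend on the ambient-temperature band: windows stay
#' closed far more often in the cold (<15 C) band.
#'
#' @param band Temperature band for the window-schedule weights: `"cold"`
#'   (<15 C) or `"warm"` (>=15 C).
#' @param heavy_week_weight Prevalence of 95th-percentile stove-use weeks
#'   (default 0.10; 0.05 used as a sensitivity case).
#' @return A named list of six [scenario_axis()] objects.
#' @export
default_scenario_axes <- function(band = c("cold", "warm"),
                                  heavy_week_weight = 0.10) {
  band <- match.arg(band)
  if (heavy_week_weight < 0 || heavy_week_weight > 0.5)
    stop("heavy_week_weight must be in [0, 0.5]", call. = FALSE)
  hood <- scenario_axis("hood_use", list(
    list(label = "not_used", weight = 0.64, capture_efficiency = 0),
    list(label = "recirculating", weight = 0.12, capture_efficiency = 0),
    list(label = "moderate", weight = 0.16, capture_efficiency = 0.55),
    list(label = "high", weight = 0.08, capture_efficiency = 0.85)
  ))
  stove <- scenario_axis("stove_use", list(
    list(label = "p5", weight = 0.10, daily_no2_mg = 0.64, heavy = FALSE),
    list(label = "p50", weight = 0.90 - heavy_week_weight, daily_no2_mg = 31,
         heavy = FALSE),
    list(label = "p95", weight = heavy_week_weight, daily_no2_mg = 199,
         heavy = TRUE)
  ))
  occupancy <- scenario_axis("occupancy", list(
    list(label = "outdoor_heavy", weight = 0.10, kitchen_min = 5,
         outdoor_min = 600),
    list(label = "kitchen_p5", weight = 0.15, kitchen_min = 5,
         outdoor_min = 120),
    list(label = "kitchen_p50", weight = 0.50, kitchen_min = 35,
         outdoor_min = 120),
    list(label = "kitchen_p95", weight = 0.15, kitchen_min = 150,
         outdoor_min = 120),
    list(label = "homebody", weight = 0.10, kitchen_min = 35,
         outdoor_min = 0)
  ))
  windspeed <- scenario_axis("windspeed", list(
    list(label = "calm", weight = 0.45, m_s = 2),
    list(label = "moderate", weight = 0.40, m_s = 4.5),
    list(label = "windy", weight = 0.15, m_s = 9)
  ))
  win_w <- if (band == "cold") c(0.70, 0.25, 0.05) else c(0.35, 0.45, 0.20)
  windows <- scenario_axis("window_schedule", list(
    list(label = "closed", weight = win_w[1], open_hours = 0),
    list(label = "open_4h", weight = win_w[2], open_hours = 4),
    list(label = "open_12h", weight = win_w[3], open_hours = 12)
  ))
  temp_levels <- list(
    list(label = "t_-5", weight = 0.20, deg_c = -5),
    list(label = "t_7", weight = 0.30, deg_c = 7),
    list(label = "t_20", weight = 0.30, deg_c = 20),
    list(label = "t_28", weight = 0.20, deg_c = 28)
  )
  temperature <- scenario_axis("ambient_temperature", temp_levels)
  list(hood_use = hood, stove_use = stove, occupancy = occupancy,
       windspeed = windspeed, window_schedule = windows,
       ambient_temperature = temperature)
}

#' Build the weighted factorial scenario grid
#'
#' Full cartesian product of the given axes. Each scenario's weight is the
#' product of its level weights, renormalized to sum to 1.
#'
#' @param axes A named list of [scenario_axis()] objects.
#' @return A data frame with one row per scenario: one `<axis>` label column
#'   per axis plus a `weight` column summing to 1.
#' @export
build_grid <- function(axes) {
  stopifnot(length(axes) > 0)
  for (a in axes) stopifnot(inherits(a, "scenario_axis"))
  labels <- lapply(axes, axis_labels)
  names(labels) <- vapply(axes, `[[`, "", "name")
  grid <- expand.grid(labels, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  w <- Reduce(`*`, lapply(seq_along(axes), function(i) {
    axis_weights(axes[[i]])[match(grid[[i]], axis_labels(axes[[i]]))]
  }))
  grid$weight <- w / sum(w)
  grid
}

#' Build the 540-scenario temperature-conditioned grid
#'
#' The grid over the four geography-independent axes (hood use, stove use,
#' occupancy, windspeed; 180 scenarios) crossed with the three window
#' schedules, whose weights are set by the given temperature band — 540
#' weighted scenarios in total.
#'
#' @param axes A named list of the six axes (see [default_scenario_axes()]).
#' @param band `"cold"` (<15 C) or `"warm"` (>=15 C).
#' @return A scenario data frame as in [build_grid()].
#' @export
temperature_conditioned_grid <- function(axes = default_scenario_axes(band),
                                         band = c("cold", "warm")) {
  band <- match.arg(band)
  core <- axes[GEO_INDEPENDENT_AXES]
  if (any(vapply(core, is.null, NA)))
    stop("axes must include ", paste(GEO_INDEPENDENT_AXES, collapse = ", "),
         call. = FALSE)
  win <- axes$window_schedule
  if (is.null(win)) stop("axes must include window_schedule", call. = FALSE)
  defaults <- default_scenario_axes(band)
  win <- set_axis_weights(win, axis_weights(defaults$window_schedule)[
    match(axis_labels(win), axis_labels(defaults$window_schedule))])
  build_grid(c(core, list(window_schedule = win)))
}

#' Day-type weights within a week
#'
#' Converts per-week day-type prevalences (days out of 7) to normalized
#' weights, e.g. `c(2, 4, 1)` no-cook/typical/heavy days become
#' `c(2/7, 4/7, 1/7)`.
#'
#' @param days_per_week Numeric vector summing to 7.
#' @return `days_per_week / 7`.
#' @export
weekly_weights <- function(days_per_week) {
  if (any(days_per_week < 0) || abs(sum(days_per_week) - 7) > 1e-9)
    stop("day counts must be non-negative and sum to 7", call. = FALSE)
  days_per_week / 7
}

#' Default day types within a stove-use week
#'
#' A week at a given stove-use level is made of 2 no-cook days, 4 typical
#' cooking days, and 1 heavy cooking day (weighted 2/7, 4/7, 1/7). Typical
#' days emit the level's daily amount over a standard meal pattern; heavy days
#' emit three times that over a longer pattern, so the weekly mean equals the
#' level's daily amount.
#'
#' @return A data frame with `day_type`, `days_per_week`, `weight`,
#'   `emission_multiplier`, `pattern`.
#' @export
default_day_types <- function() {
  data.frame(
    day_type = c("no_cook", "typical", "heavy"),
    days_per_week = c(2, 4, 1),
    weight = weekly_weights(c(2, 4, 1)),
    emission_multiplier = c(0, 1, 3),
    pattern = c("none", "typical", "heavy"),
    stringsAsFactors = FALSE
  )
}
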