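# Small floorplans built in code for the simulator tests.

# Single zone with leakage sized so the air-exchange rate equals `k` per hour
# at unit flow driver (10 m/s wind, 25 K indoor-outdoor difference).
one_zone_fp <- function(k = 0.76, volume = 250) {
  floorplan("one",
            list(zone("kitchen", volume, "kitchen", has_window = TRUE)),
            list(flow_path("kitchen", outdoors_label(), "leakage",
                           k * volume),
                 flow_path("kitchen", outdoors_label(), "open_window", 100)),
            home_type = "single_detached")
}

# Two zones joined by an interzone opening, each leaking outdoors.
two_zone_fp <- function(leak1 = 60, leak2 = 40, mix = 120) {
  floorplan("two",
            list(zone("kitchen", 40, "kitchen", has_window = TRUE),
                 zone("living", 80, "living", has_window = TRUE)),
            list(flow_path("kitchen", "living", "interzone_opening", mix),
                 flow_path("kitchen", outdoors_label(), "leakage", leak1),
                 flow_path("living", outdoors_label(), "leakage", leak2),
                 flow_path("living", outdoors_label(), "open_window", 150)),
            home_type = "multifamily")
}

# Three zones in a chain: kitchen - hall - bed; only kitchen and bed leak.
three_zone_fp <- function(leak_k = 50, leak_b = 30, mix = 100) {
  floorplan("three",
            list(zone("kitchen", 35, "kitchen", has_window = TRUE),
                 zone("hall", 25, "hallway"),
                 zone("bed", 60, "bedroom", has_window = TRUE)),
            list(flow_path("kitchen", "hall", "interzone_opening", mix),
                 flow_path("hall", "bed", "interzone_opening", mix),
                 flow_path("kitchen", outdoors_label(), "leakage", leak_k),
                 flow_path("bed", outdoors_label(), "leakage", leak_b)),
            home_type = "single_attached")
}

# Closed system (zero leakage) for mass-conservation checks.
closed_fp <- function() {
  floorplan("closed",
            list(zone("kitchen", 30, "kitchen"),
                 zone("hall", 20, "hallway"),
                 zone("bed", 50, "bedroom")),
            list(flow_path("kitchen", "hall", "interzone_opening", 90),
                 flow_path("hall", "bed", "interzone_opening", 70),
                 flow_path("kitchen", outdoors_label(), "leakage", 0)),
            home_type = "single_detached")
}

# config whose flow driver is exactly 1 (so leakage flows = reference flows)
unit_driver_config <- function(...) {
  sim_config(windspeed = 10, ambient_temperature = -5, ...)
}

# Independent ODE oracle: solve the multizone system with deSolve::lsoda and
# return interval means computed from a fine (30 s) trajectory. Mirrors the
# physics from first principles: flows from compute_flows(), well-mixed
# balance equations written out directly.
desolve_oracle <- function(fp, config, emission = NULL, window_schedule = NULL,
                           species = c("NO2_stove", "CONTA", "CONTB")) {
  species <- match.arg(species)
  ids <- names(no2home:::zone_volumes(fp))
  vols <- no2home:::zone_volumes(fp)
  n <- length(ids)
  if (is.null(window_schedule)) window_schedule <- rep(FALSE, 144)
  if (is.null(emission)) emission <- rep(0, 144)
  decay <- if (species == "CONTB") 0 else config$decay_rate
  c_out <- if (species == "NO2_stove") 0 else config$conta_outdoor
  qs <- lapply(c(FALSE, TRUE), function(w) compute_flows(fp, config, w))
  names(qs) <- c("FALSE", "TRUE")
  deriv <- function(t, y, parms) {
    i <- pmin(floor(t / (1 / 6)) + 1, 144)
    q <- qs[[as.character(window_schedule[i])]]
    dy <- numeric(n)
    for (z in seq_len(n)) {
      inflow <- sum(q[ids[-z], ids[z]] * y[-z]) +
        q[outdoors_label(), ids[z]] * c_out
      outflow <- sum(q[ids[z], c(ids[-z], outdoors_label())]) * y[z]
      s <- if (species == "NO2_stove" && ids[z] == "kitchen") emission[i] else 0
      dy[z] <- (inflow - outflow + s) / vols[z] + decay * y[z]
    }
    list(dy)
  }
  y0 <- if (species == "CONTA") {
    # steady state under initial flows
    q <- qs[[as.character(window_schedule[1])]]
    a <- no2home:::state_matrix(q, vols, decay)
    as.numeric(solve(a, -q[outdoors_label(), ids] * c_out / vols))
  } else rep(0, n)
  times <- seq(0, 24, by = 30 / 3600)
  sol <- deSolve::lsoda(y0, times, deriv, NULL, rtol = 1e-10, atol = 1e-12)
  if (species == "NO2_stove")   # sources are mg/h, outputs ppbv
    sol[, -1] <- no2home:::mgm3_to_ppbv(
      sol[, -1, drop = FALSE],
      gas_conditions(config$indoor_temperature))
  # 10-min interval means from the 30-s grid (trapezoid)
  out <- matrix(0, n, 144, dimnames = list(ids, NULL))
  per <- 20  # 30-s steps per 10 min
  for (i in seq_len(144)) {
    rows <- ((i - 1) * per + 1):(i * per + 1)
    for (z in seq_len(n)) {
      v <- sol[rows, z + 1]
      out[z, i] <- (sum(v) - (v[1] + v[length(v)]) / 2) / per
    }
  }
  out
}
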