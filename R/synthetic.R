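#' Configuration for the synthetic-data generators
#'
#' Defaults encode the study conditions the generators emulate: right-skewed
#' ZIP-level outdoor NO2 (lognormal solved from a 4.9 ppbv median and 7.7 ppbv
#' mean), a ~40% national gas/propane-stove share, denser ZIP codes having
#' higher outdoor NO2 (r2 of the NO2 vs log-density regression near 0.2) and
#' more multifamily/small-area housing, and a 24-floorplan library spanning
#' the housing-stock cells.
#'
#' @param n_zips Number of synthetic ZIP codes.
#' @param seed Integer seed; all generators are deterministic given it.
#' @param outdoor_median,outdoor_mean Lognormal anchors for outdoor NO2, ppbv.
#' @param gas_fraction_mean,gas_fraction_conc Beta mean and concentration for
#'   the per-ZIP gas-stove fraction.
#' @param density_no2_rho Correlation between the log-density factor and log
#'   outdoor NO2 (in `[0, 1)`).
#' @param n_floorplans Number of floorplans to generate (4-24).
#' @param zips_per_county ZIP codes per synthetic county.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_zips = 200, seed = 1,
                         outdoor_median = 4.9, outdoor_mean = 7.7,
                         gas_fraction_mean = 0.4, gas_fraction_conc = 10,
                         density_no2_rho = 0.58,
                         n_floorplans = 24, zips_per_county = 10) {
  stopifnot(n_zips > 0, n_floorplans >= 4, n_floorplans <= 24,
            zips_per_county > 0)
  if (outdoor_mean <= outdoor_median)
    stop("right skew requires outdoor_mean > outdoor_median", call. = FALSE)
  if (density_no2_rho < 0 || density_no2_rho >= 1)
    stop("density_no2_rho must be in [0, 1)", call. = FALSE)
  structure(
    list(n_zips = as.integer(n_zips), seed = as.integer(seed),
         outdoor_median = outdoor_median, outdoor_mean = outdoor_mean,
         gas_fraction_mean = gas_fraction_mean,
         gas_fraction_conc = gas_fraction_conc,
         density_no2_rho = density_no2_rho,
         n_floorplans = as.integer(n_floorplans),
         zips_per_county = as.integer(zips_per_county)),
    class = "synth_config"
  )
}

# the 24-row floorplan design: home types x area classes x stories x forced
# air, with a few shared cells so the equal-split weighting rule is exercised
floorplan_design <- function() {
  read.csv(text = "home_type,floor_area_class,stories,forced_air,bedrooms
mobile,0-1499,1,FALSE,2
mobile,0-1499,1,TRUE,2
single_detached,0-1499,1,FALSE,2
single_detached,0-1499,1,TRUE,2
single_detached,1500-2499,1,TRUE,3
single_detached,1500-2499,1,FALSE,3
single_detached,1500-2499,2,TRUE,3
single_detached,2500-3999,1,TRUE,4
single_detached,2500-3999,2,TRUE,4
single_detached,2500-3999,2,FALSE,4
single_detached,>=4000,2,TRUE,5
single_detached,>=4000,2,FALSE,5
single_attached,0-1499,1,FALSE,2
single_attached,0-1499,2,TRUE,2
single_attached,1500-2499,2,TRUE,3
single_attached,1500-2499,2,FALSE,3
multifamily,0-1499,1,FALSE,1
multifamily,0-1499,1,TRUE,1
multifamily,1500-2499,1,FALSE,2
multifamily,1500-2499,1,TRUE,2
mobile,1500-2499,1,FALSE,3
single_attached,0-1499,1,TRUE,2
single_detached,1500-2499,2,FALSE,3
multifamily,0-1499,1,TRUE,1
", stringsAsFactors = FALSE)
}

# area-class midpoints, ft2
AREA_MIDPOINT <- c("0-1499" = 1000, "1500-2499" = 2000, "2500-3999" = 3200,
                   ">=4000" = 5000)

#' Generate the synthetic floorplan library
#'
#' Builds `n_floorplans` connected multizone floorplans spanning home types,
#' floor-area classes, stories and forced-air presence, each with one kitchen,
#' a living room, a hallway hub and bedrooms; kitchen, living room and
#' bedrooms carry operable windows. Leakage and window reference flows are
#' sized so the whole-dwelling air exchange is 1.5 per hour from leakage at
#' the reference driver (10 m/s wind, 25 K indoor-outdoor difference) plus
#' 4.5 per hour from open windows — 6.0 per hour total at that driving point
#' and ~0 in still air at equal temperatures with windows closed.
#'
#' @param config A [synth_config()].
#' @return A list of validated [floorplan()] objects.
#' @export
generate_floorplans <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  design <- floorplan_design()[seq_len(config$n_floorplans), ]
  lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    vol_total <- AREA_MIDPOINT[[d$floor_area_class]] * 0.0929 * 2.44  # m3
    n_bed <- d$bedrooms
    v_kitchen <- 0.10 * vol_total
    v_living <- 0.25 * vol_total
    v_hall <- 0.10 * vol_total
    v_bed <- (vol_total - v_kitchen - v_living - v_hall) / n_bed
    zones <- c(
      list(zone("kitchen", v_kitchen, "kitchen", has_window = TRUE),
           zone("living", v_living, "living", has_window = TRUE),
           zone("hall", v_hall, "hallway")),
      lapply(seq_len(n_bed), function(b)
        zone(paste0("bed", b), v_bed, "bedroom", has_window = TRUE))
    )
    ids <- vapply(zones, `[[`, "", "zone_id")
    vols <- vapply(zones, `[[`, 0, "volume")
    ext <- ids != "hall"
    leak_total <- 1.5 * vol_total            # m3/h at unit driver
    win_zones <- ids[vapply(zones, `[[`, NA, "has_window")]
    win_each <- 4.5 * vol_total / length(win_zones)
    paths <- c(
      lapply(setdiff(ids, "hall"), function(z)
        flow_path("hall", z, "interzone_opening", 150)),
      lapply(ids[ext], function(z)
        flow_path(z, OUTDOORS, "leakage",
                  leak_total * vols[ids == z] / sum(vols[ext]))),
      lapply(win_zones, function(z)
        flow_path(z, OUTDOORS, "open_window", win_each))
    )
    floorplan(
      floorplan_id = sprintf("FP%02d", i),
      zones = zones, paths = paths, stories = d$stories,
      home_type = d$home_type, floor_area_class = d$floor_area_class,
      has_forced_air = d$forced_air
    )
  })
}

#' Generate the synthetic ZIP-code table
#'
#' Produces `n_zips` rows with population, population density, annual-mean
#' outdoor NO2, gas-stove fraction, a cold-band climate weight, a county
#' assignment, and a long-format housing mix over the floorplan library's
#' housing-stock cells. Outdoor NO2 is lognormal (median/mean anchors from the
#' config) and shares a Gaussian factor with log density; denser ZIP codes get
#' more multifamily and small-floor-area housing through a log-linear tilt.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @param floorplans The floorplan library whose cells the housing mix covers
#'   (default: generated from the same config).
#' @return A list of class `synth_zip_table`: `zips` (one row per ZIP),
#'   `housing_mix` (long, one row per ZIP x cell) and `counties` (crosswalk).
#' @export
generate_zip_table <- function(config = synth_config(),
                               floorplans = generate_floorplans(config)) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_zips
  meanlog <- log(config$outdoor_median)
  sdlog <- sqrt(2 * log(config$outdoor_mean / config$outdoor_median))
  z_d <- rnorm(n)                          # shared density factor
  eps <- rnorm(n)
  rho <- config$density_no2_rho
  outdoor_no2 <- exp(meanlog + sdlog * (rho * z_d + sqrt(1 - rho^2) * eps))
  density <- exp(log(300) + 1.2 * z_d)     # persons/km2
  area_km2 <- rlnorm(n, log(30), 0.7)
  population <- pmax(1, round(density * area_km2))
  m <- config$gas_fraction_mean
  k <- config$gas_fraction_conc
  gas_fraction <- rbeta(n, m * k, (1 - m) * k)
  cold_weight <- runif(n, 0.3, 0.7)
  county_id <- sprintf("C%03d", ceiling(seq_len(n) / config$zips_per_county))
  zips <- data.frame(
    zip_id = sprintf("Z%05d", seq_len(n)),
    population = population, density = density,
    outdoor_no2 = outdoor_no2, gas_stove_fraction = gas_fraction,
    cold_weight = cold_weight, county_id = county_id,
    stringsAsFactors = FALSE
  )

  # housing mix over the cells covered by the floorplan library
  cells <- unique(data.frame(
    home_type = vapply(floorplans, `[[`, "", "home_type"),
    floor_area_class = vapply(floorplans, `[[`, "", "floor_area_class"),
    stories = vapply(floorplans, `[[`, 0L, "stories"),
    forced_air = vapply(floorplans, `[[`, NA, "has_forced_air"),
    stringsAsFactors = FALSE
  ))
  base_type <- c(single_detached = 0.62, multifamily = 0.26,
                 single_attached = 0.06, mobile = 0.06)
  tilt_type <- c(single_detached = -0.35, multifamily = 0.9,
                 single_attached = 0.3, mobile = -0.6)
  tilt_area <- c("0-1499" = 0.3, "1500-2499" = 0, "2500-3999" = -0.15,
                 ">=4000" = -0.3)
  n_type <- table(cells$home_type)
  base_cell <- base_type[cells$home_type] / as.numeric(n_type[cells$home_type])
  tilt <- tilt_type[cells$home_type] + tilt_area[cells$floor_area_class]
  w <- exp(outer(z_d, tilt)) * rep(base_cell, each = n)  # n x cells
  w <- w / rowSums(w)
  mix <- data.frame(
    zip_id = rep(zips$zip_id, times = nrow(cells)),
    cells[rep(seq_len(nrow(cells)), each = n), ],
    share = as.vector(w),
    row.names = NULL, stringsAsFactors = FALSE
  )
  counties <- unique(zips[, c("county_id", "zip_id")])
  structure(list(zips = zips, housing_mix = mix, counties = counties),
            class = "synth_zip_table")
}

#' Generate behavioral samplers and their empirical tables
#'
#' Builds the samplers the scenario and uncertainty modules draw from:
#'
#' * `cooking_minutes(n)`: daily cooktop minutes with 5th/50th/95th percentiles
#'   at 5/35/150 min/day (log-linear interpolation of anchor quantiles);
#' * `hood_used(n, dwelling)`: hood-use indicator with non-use probability
#'   0.64 in houses and 0.72 in apartments;
#' * `capture_efficiency(n)`: resampling from a 15-hood spectrum of capture
#'   efficiencies;
#' * `emission_factor(n)`: resampling from a synthetic table of 50 measured
#'   burner emission factors centered on 48 mg/h.
#'
#' Table construction is deterministic given `config$seed`; the samplers
#' themselves consume the caller's RNG stream.
#'
#' @param config A [synth_config()].
#' @return A list of sampler closures plus the underlying `tables`.
#' @export
generate_behavior_samplers <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  anchors_p <- c(0.01, 0.05, 0.50, 0.95, 0.99)
  anchors_q <- c(2, 5, 35, 150, 300)
  if (any(diff(anchors_q) <= 0))
    stop("cooking-minute percentile anchors must be increasing", call. = FALSE)
  ef_table <- rnorm(50, 48, 12)
  while (any(bad <- ef_table < 5)) ef_table[bad] <- rnorm(sum(bad), 48, 12)
  ce_table <- c(0, 0.10, 0.22, 0.34, 0.45, 0.55, 0.64, 0.70, 0.76, 0.80,
                0.84, 0.88, 0.90, 0.93, 0.95)
  hood_not_used <- c(house = 0.64, apartment = 0.72)
  cooking_q <- function(p) {
    exp(approx(anchors_p, log(anchors_q), xout = pmin(pmax(p, 0.01), 0.99),
               rule = 2)$y)
  }
  list(
    cooking_minutes = function(n) cooking_q(runif(n)),
    cooking_quantile = cooking_q,
    hood_used = function(n, dwelling = c("house", "apartment")) {
      dwelling <- match.arg(dwelling)
      runif(n) > hood_not_used[[dwelling]]
    },
    capture_efficiency = function(n) sample(ce_table, n, replace = TRUE),
    emission_factor = function(n) sample(ef_table, n, replace = TRUE),
    tables = list(emission_factor = ef_table, capture_efficiency = ce_table,
                  hood_not_used = hood_not_used,
                  cooking_anchors = data.frame(p = anchors_p, q = anchors_q))
  )
}
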