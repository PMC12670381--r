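#' Run the full exposure pipeline
#'
#' Orchestrates the stages end to end on synthetic inputs:
#'
#' 1. `synth` — generate the ZIP table, housing mix, county crosswalk,
#'    floorplan library and behavioral tables (`zips.csv`, `housing_mix.csv`,
#'    `counties.csv`, `floorplans.json`, `samplers.json`);
#' 2. `simulate` — multizone simulation and exposure statistics for every
#'    floorplan and temperature band (`scenario_exposures.csv`,
#'    `day_exposures.csv`);
#' 3. `uncertainty` — Monte Carlo multipliers (`multipliers.json`);
#' 4. `aggregate` — per-ZIP exposure with CI bounds, county roll-up
#'    (`zip_exposure.csv`, `county_exposure.csv`);
#' 5. `report` — national population-weighted summary and benchmark
#'    classification counts (`national.json`).
#'
#' Each stage is skipped when its outputs already exist (unless
#' `force = TRUE`), so later stages can be re-run from cached intermediates.
#' All intermediates are plain CSV/JSON. A `manifest.json` recording the seed,
#' configuration and MD5 checksum of every output is written at the end;
#' identical config and seed give identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for all randomness.
#' @param config A [synth_config()]; its `seed` is overridden by `seed`.
#' @param stages Stages to run, in order.
#' @param mc_iterations Monte Carlo iterations for the multipliers.
#' @param threshold_chron,threshold_acute Benchmarks, ppbv.
#' @param force Re-run stages even if outputs exist.
#' @param quiet Suppress per-stage messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         config = synth_config(n_zips = 200,
                                               n_floorplans = 8),
                         stages = c("synth", "simulate", "uncertainty",
                                    "aggregate", "report"),
                         mc_iterations = 10000,
                         threshold_chron = 5.2, threshold_acute = 100,
                         force = FALSE, quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  p <- function(f) file.path(out_dir, f)
  done <- function(...) all(file.exists(vapply(list(...), p, "")))

  if ("synth" %in% stages && (force || !done("zips.csv", "floorplans.json"))) {
    t0 <- Sys.time()
    fps <- generate_floorplans(config)
    tab <- generate_zip_table(config, fps)
    samplers <- generate_behavior_samplers(config)
    write.csv(tab$zips, p("zips.csv"), row.names = FALSE)
    write.csv(tab$housing_mix, p("housing_mix.csv"), row.names = FALSE)
    write.csv(tab$counties, p("counties.csv"), row.names = FALSE)
    write_floorplans_json(fps, p("floorplans.json"))
    jsonlite::write_json(samplers$tables, p("samplers.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("synth: %d ZIPs, %d floorplans [%.1fs]", nrow(tab$zips), length(fps),
        as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("simulate" %in% stages && (force || !done("scenario_exposures.csv"))) {
    t0 <- Sys.time()
    fps <- read_floorplans_json(p("floorplans.json"))
    se <- list(); dl <- list()
    for (fp in fps) {
      for (band in c("cold", "warm")) {
        x <- floorplan_scenario_exposures(fp, band)
        d <- attr(x, "day_level")
        d$band <- band
        d$floorplan_id <- fp$floorplan_id
        se[[paste(fp$floorplan_id, band)]] <- x
        dl[[paste(fp$floorplan_id, band)]] <- d
      }
    }
    se <- do.call(rbind, se)
    write.csv(se, p("scenario_exposures.csv"), row.names = FALSE)
    write.csv(do.call(rbind, dl), p("day_exposures.csv"), row.names = FALSE)
    say("simulate: %d scenario rows across %d floorplans [%.1fs]", nrow(se),
        length(fps), as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("uncertainty" %in% stages && (force || !done("multipliers.json"))) {
    t0 <- Sys.time()
    set.seed(config$seed + 2L)
    mult <- mc_multipliers(mc_input_distributions(), mc_iterations)
    jsonlite::write_json(
      list(stove = as.list(mult$stove), outdoor = as.list(mult$outdoor),
           iterations = mult$iterations, seed = config$seed + 2L),
      p("multipliers.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("uncertainty: %d MC iterations [%.1fs]", mc_iterations,
        as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("aggregate" %in% stages && (force || !done("zip_exposure.csv"))) {
    t0 <- Sys.time()
    zips <- read.csv(p("zips.csv"), stringsAsFactors = FALSE)
    mix <- read.csv(p("housing_mix.csv"), stringsAsFactors = FALSE)
    se <- read.csv(p("scenario_exposures.csv"), stringsAsFactors = FALSE)
    fps <- read_floorplans_json(p("floorplans.json"))
    mu <- jsonlite::read_json(p("multipliers.json"), simplifyVector = TRUE)
    mix_by_zip <- split(mix, mix$zip_id)
    rows <- lapply(seq_len(nrow(zips)), function(i) {
      z <- zips[i, ]
      fw <- floorplan_weights(mix_by_zip[[z$zip_id]], fps)
      variants <- list(
        central = c(1, 1),
        lower = c(mu$stove$lower, mu$outdoor$lower),
        upper = c(mu$stove$upper, mu$outdoor$upper)
      )
      out <- lapply(names(variants), function(v) {
        m <- variants[[v]]
        e <- zip_exposure(fw, se, z$outdoor_no2, cold_weight = z$cold_weight,
                          threshold_chron = threshold_chron,
                          threshold_acute = threshold_acute,
                          mult_stove = m[1], mult_outdoor = m[2])
        names(e) <- paste0(names(e), "_", v)
        e
      })
      cbind(data.frame(zip_id = z$zip_id), do.call(cbind, out))
    })
    ze <- do.call(rbind, rows)
    ze$benchmark_class <- as.character(classify_benchmark(
      ze$chron_outdoor_central, ze$chron_stove_central, threshold_chron))
    write.csv(ze, p("zip_exposure.csv"), row.names = FALSE)

    zj <- merge(ze, zips[, c("zip_id", "population", "county_id")],
                by = "zip_id")
    metrics <- grep("_(central|lower|upper)$", names(ze), value = TRUE)
    cty <- do.call(rbind, lapply(split(zj, zj$county_id), function(g) {
      v <- lapply(metrics, function(mcol) rollup(g[[mcol]], g$population))
      cbind(data.frame(county_id = g$county_id[1],
                       population = sum(g$population)),
            setNames(as.data.frame(v), metrics))
    }))
    cty$benchmark_class <- as.character(classify_benchmark(
      cty$chron_outdoor_central, cty$chron_stove_central, threshold_chron))
    write.csv(cty, p("county_exposure.csv"), row.names = FALSE)
    say("aggregate: %d ZIPs, %d counties [%.1fs]", nrow(ze), nrow(cty),
        as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("report" %in% stages && (force || !done("national.json"))) {
    zips <- read.csv(p("zips.csv"), stringsAsFactors = FALSE)
    ze <- merge(read.csv(p("zip_exposure.csv"), stringsAsFactors = FALSE),
                zips[, c("zip_id", "population", "gas_stove_fraction")],
                by = "zip_id")
    pw <- function(col) rollup(ze[[col]], ze$population)
    nat <- list(
      chron_stove_gas_households = lapply(
        c(central = "chron_stove_central", lower = "chron_stove_lower",
          upper = "chron_stove_upper"), pw),
      chron_outdoor = lapply(
        c(central = "chron_outdoor_central", lower = "chron_outdoor_lower",
          upper = "chron_outdoor_upper"), pw),
      chron_total_gas_households = lapply(
        c(central = "chron_total_central", lower = "chron_total_lower",
          upper = "chron_total_upper"), pw),
      chron_stove_whole_population = rollup(
        whole_population_mean(ze$chron_stove_central, ze$gas_stove_fraction),
        ze$population),
      exceed_chron = pw("exceed_chron_central"),
      exceed_acute = pw("exceed_acute_central"),
      benchmark_class_counts = as.list(table(ze$benchmark_class)),
      mean_gas_fraction = rollup(ze$gas_stove_fraction, ze$population)
    )
    jsonlite::write_json(nat, p("national.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("report: national summary written")
  }

  files <- list.files(out_dir, pattern = "\\.(csv|json)$")
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("no2home")),
    seed = config$seed,
    config = unclass(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(files, function(f)
      list(file = f, md5 = unname(tools::md5sum(file.path(out_dir, f)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
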