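housing_cell_key <- function(home_type, floor_area_class, stories, forced_air) {
  paste(home_type, floor_area_class, pmin(as.integer(stories), 2L),
        as.logical(forced_air), sep = "|")
}

fp_cell_key <- function(fp) {
  housing_cell_key(fp$home_type, fp$floor_area_class, fp$stories,
                   fp$has_forced_air)
}

#' Floorplan weights for a ZIP code's housing stock
#'
#' Each floorplan represents a housing-stock cell (home type x floor-area
#' class x stories x forced-air presence). A ZIP code's floorplan weight is
#' the prevalence of the floorplan's cell in that ZIP's housing mix, split
#' equally among floorplans sharing the cell, then normalized to sum to 1.
#'
#' @param housing_mix Data frame with columns `home_type`, `floor_area_class`,
#'   `stories`, `forced_air`, `share` (shares summing to 1) for one ZIP code.
#' @param floorplans List of [floorplan()] objects.
#' @return Named numeric vector of weights (one per floorplan, sum 1).
#' @export
floorplan_weights <- function(housing_mix, floorplans) {
  share <- housing_mix$share
  if (any(share < 0) || abs(sum(share) - 1) > 1e-6)
    stop("housing mix shares must be non-negative and sum to 1",
         call. = FALSE)
  mix_keys <- housing_cell_key(housing_mix$home_type,
                               housing_mix$floor_area_class,
                               housing_mix$stories, housing_mix$forced_air)
  fp_keys <- vapply(floorplans, fp_cell_key, "")
  unmapped <- setdiff(mix_keys[share > 0], fp_keys)
  if (length(unmapped))
    stop("housing-mix cell(s) with no matching floorplan: ",
         paste(unmapped, collapse = "; "), call. = FALSE)
  per_cell <- tapply(share, mix_keys, sum)
  n_in_cell <- table(fp_keys)
  w <- as.numeric(per_cell[fp_keys]) / as.numeric(n_in_cell[fp_keys])
  w[is.na(w)] <- 0
  w <- w / sum(w)
  setNames(w, vapply(floorplans, `[[`, "", "floorplan_id"))
}

#' Aggregate scenario exposures to one ZIP code
#'
#' Double-weighted sum over floorplans and scenarios,
#' `sum_i sum_j Exp[i,j] * WScenario[j] * WFloorplan[i]`, applied to the
#' stove channel, the outdoor channel (tracer infiltration scaled by the ZIP's
#' outdoor NO2 through [outdoor_attributable()]), and the benchmark-exceedance
#' indicators `f(conc, threshold) = 1` iff `conc >= threshold`, evaluated on
#' total (stove + outdoor) exposure per scenario. Cold- and warm-band
#' distributions are mixed by the ZIP's `cold_weight` (default 50/50).
#'
#' @param fp_weights Named floorplan weights from [floorplan_weights()].
#' @param scenario_exposures Data frame stacking
#'   [floorplan_scenario_exposures()] results for all floorplans and both
#'   bands (columns `floorplan_id`, `band`, `weight`, `chron_stove`,
#'   `acute_stove`, `chron_conta`, `acute_conta`).
#' @param outdoor_no2 The ZIP's annual-mean outdoor NO2, ppbv.
#' @param cold_weight Weight on the cold-band distribution (default 0.5).
#' @param threshold_chron Long-term benchmark, ppbv (WHO guideline 5.2).
#' @param threshold_acute Short-term benchmark, ppbv (100).
#' @param conta_reference Outdoor tracer level, ppbv.
#' @param mult_stove,mult_outdoor Uncertainty multipliers applied to every
#'   scenario's stove and outdoor exposure before summing and thresholding
#'   (1 for the central estimate; a lower/upper multiplier from
#'   [mc_multipliers()] for the CI bounds).
#' @return A one-row data frame: `chron_stove`, `chron_outdoor`, `chron_total`,
#'   `acute_stove`, `acute_outdoor`, `acute_total` (ppbv), `exceed_chron`,
#'   `exceed_acute` (weighted fractions in `[0, 1]`).
#' @export
zip_exposure <- function(fp_weights, scenario_exposures, outdoor_no2,
                         cold_weight = 0.5, threshold_chron = 5.2,
                         threshold_acute = 100, conta_reference = 100,
                         mult_stove = 1, mult_outdoor = 1) {
  se <- scenario_exposures
  if (abs(sum(fp_weights) - 1) > 1e-6)
    stop("floorplan weights must be normalized", call. = FALSE)
  if (cold_weight < 0 || cold_weight > 1)
    stop("cold_weight must be in [0, 1]", call. = FALSE)
  missing_fp <- setdiff(names(fp_weights)[fp_weights > 0],
                        unique(se$floorplan_id))
  if (length(missing_fp))
    stop("no scenario exposures for floorplan(s): ",
         paste(missing_fp, collapse = ", "), call. = FALSE)
  w_band <- ifelse(se$band == "cold", cold_weight, 1 - cold_weight)
  wfp <- fp_weights[se$floorplan_id]
  wfp[is.na(wfp)] <- 0
  w <- wfp * se$weight * w_band
  # per-band scenario weights each sum to 1, so w must sum to 1 overall
  if (abs(sum(w) - 1) > 1e-6)
    stop("scenario/floorplan weights do not form a normalized distribution",
         call. = FALSE)
  chron_out <- outdoor_attributable(se$chron_conta, outdoor_no2,
                                    conta_reference) * mult_outdoor
  acute_out <- outdoor_attributable(se$acute_conta, outdoor_no2,
                                    conta_reference) * mult_outdoor
  chron_stove <- se$chron_stove * mult_stove
  acute_stove <- se$acute_stove * mult_stove
  chron_tot <- chron_stove + chron_out
  acute_tot <- acute_stove + acute_out
  data.frame(
    chron_stove = sum(w * chron_stove),
    chron_outdoor = sum(w * chron_out),
    chron_total = sum(w * chron_tot),
    acute_stove = sum(w * acute_stove),
    acute_outdoor = sum(w * acute_out),
    acute_total = sum(w * acute_tot),
    exceed_chron = sum(w * (chron_tot >= threshold_chron)),
    exceed_acute = sum(w * (acute_tot >= threshold_acute))
  )
}

#' Whole-population stove-attributable mean
#'
#' Converts a mean over gas-stove households to a mean over the whole
#' population: households with electric stoves contribute zero
#' stove-attributable exposure, so the population mean is the gas-household
#' value times the gas-stove fraction. The literal division reading is kept
#' behind `divide = TRUE` for comparison (it inflates rather than dilutes and
#' is inconsistent with stoves contributing ~10% of total exposure at a ~40%
#' gas share).
#'
#' @param stove_value Mean stove-attributable exposure among gas-stove
#'   households, ppbv.
#' @param gas_fraction Fraction of the population with gas/propane stoves.
#' @param divide Use the division form instead (not recommended).
#' @return Whole-population mean, ppbv.
#' @export
whole_population_mean <- function(stove_value, gas_fraction, divide = FALSE) {
  if (any(gas_fraction < 0) || any(gas_fraction > 1))
    stop("gas_fraction must be in [0, 1]", call. = FALSE)
  if (divide) stove_value / gas_fraction else stove_value * gas_fraction
}

#' Population-weighted roll-up of ZIP values
#'
#' `sum(value_i * population_i) / sum(population_i)` over the ZIP codes of a
#' county or the nation.
#'
#' @param values Per-ZIP exposure values (any exposure or exceedance metric).
#' @param populations Per-ZIP populations (non-negative, not all zero).
#' @return The population-weighted mean.
#' @export
rollup <- function(values, populations) {
  stopifnot(length(values) == length(populations))
  if (any(populations < 0)) stop("populations must be >= 0", call. = FALSE)
  if (sum(populations) == 0)
    stop("total population is zero", call. = FALSE)
  sum(values * populations) / sum(populations)
}

#' Classify a geography against a long-term benchmark
#'
#' Three mutually exclusive classes at a given threshold: outdoor-attributable
#' exposure alone already exceeds it; outdoor alone is below but adding the
#' stove pushes the total over; or the total stays below even with the stove.
#'
#' @param outdoor Outdoor-attributable exposure, ppbv (>= 0).
#' @param stove Stove-attributable exposure, ppbv (>= 0).
#' @param threshold Benchmark, ppbv (default WHO long-term guideline 5.2).
#' @return Factor with levels `outdoor_alone_exceeds`, `stove_pushes_over`,
#'   `below_with_stove` (vectorized).
#' @export
classify_benchmark <- function(outdoor, stove, threshold = 5.2) {
  if (any(outdoor < 0) || any(stove < 0))
    stop("exposures must be non-negative", call. = FALSE)
  cls <- ifelse(outdoor >= threshold, "outdoor_alone_exceeds",
                ifelse(outdoor + stove >= threshold, "stove_pushes_over",
                       "below_with_stove"))
  factor(cls, levels = c("outdoor_alone_exceeds", "stove_pushes_over",
                         "below_with_stove"))
}
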