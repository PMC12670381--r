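mix_row <- function(fp, share) {
  data.frame(home_type = fp$home_type, floor_area_class = fp$floor_area_class,
             stories = fp$stories, forced_air = fp$has_forced_air,
             share = share, stringsAsFactors = FALSE)
}

test_that("floorplan weights follow housing-stock prevalence with equal splits", {
  fps <- generate_floorplans(synth_config())
  # 100% of stock in one cell with a single matching floorplan
  m <- mix_row(fps[[5]], 1)
  w <- floorplan_weights(m, fps)
  expect_equal(unname(w[fps[[5]]$floorplan_id]), 1)
  expect_equal(sum(w), 1)
  # FP18 and FP24 share the multifamily/0-1499/1/TRUE cell -> equal split
  shared <- fps[c(18, 24)]
  expect_identical(no2home:::fp_cell_key(shared[[1]]),
                   no2home:::fp_cell_key(shared[[2]]))
  m2 <- rbind(mix_row(shared[[1]], 0.6), mix_row(fps[[5]], 0.4))
  w2 <- floorplan_weights(m2, fps)
  expect_equal(unname(w2[shared[[1]]$floorplan_id]), 0.3)
  expect_equal(unname(w2[shared[[2]]$floorplan_id]), 0.3)
  expect_equal(unname(w2[fps[[5]]$floorplan_id]), 0.4)
  expect_equal(sum(w2), 1)
  # unmapped cell
  m3 <- data.frame(home_type = "mobile", floor_area_class = ">=4000",
                   stories = 1, forced_air = FALSE, share = 1)
  expect_error(floorplan_weights(m3, fps), "no matching floorplan")
  expect_error(floorplan_weights(mix_row(fps[[1]], 0.7), fps), "sum to 1")
})

toy_scenarios <- function() {
  # 2 floorplans x 3 scenarios x 2 bands with simple numbers
  se <- expand.grid(floorplan_id = c("A", "B"), scenario = 1:3,
                    band = c("cold", "warm"), stringsAsFactors = FALSE)
  se$weight <- rep(c(0.2, 0.3, 0.5), each = 2, times = 2)
  se$chron_stove <- seq_len(nrow(se)) / 10
  se$acute_stove <- se$chron_stove * 8
  se$chron_conta <- 40 + 2 * seq_len(nrow(se))
  se$acute_conta <- pmin(100, se$chron_conta + 10)
  se
}

test_that("zip exposure equals the brute-force double-weighted sum", {
  se <- toy_scenarios()
  fw <- c(A = 0.25, B = 0.75)
  no2 <- 9
  got <- zip_exposure(fw, se, no2, cold_weight = 0.5, threshold_chron = 5.2,
                      threshold_acute = 20)
  wb <- ifelse(se$band == "cold", 0.5, 0.5)
  w <- fw[se$floorplan_id] * se$weight * wb
  chron_tot <- se$chron_stove + se$chron_conta * no2 / 100
  acute_tot <- se$acute_stove + se$acute_conta * no2 / 100
  expect_equal(got$chron_stove, sum(w * se$chron_stove))
  expect_equal(got$chron_outdoor, sum(w * se$chron_conta * no2 / 100))
  expect_equal(got$chron_total, sum(w * chron_tot))
  expect_equal(got$exceed_chron, sum(w * (chron_tot >= 5.2)))
  expect_equal(got$exceed_acute, sum(w * (acute_tot >= 20)))
})

test_that("zip exposure is convex and threshold-saturating", {
  se <- toy_scenarios()
  se$chron_stove <- 3; se$acute_stove <- 3
  se$chron_conta <- 50; se$acute_conta <- 50
  got <- zip_exposure(c(A = 0.5, B = 0.5), se, outdoor_no2 = 10,
                      threshold_chron = 0.1)
  expect_equal(got$chron_stove, 3)
  expect_equal(got$chron_total, 3 + 5)
  expect_equal(got$exceed_chron, 1)  # threshold below every value
  expect_error(zip_exposure(c(A = 0.5, B = 0.2), se, 10), "normalized")
})

test_that("zip exposure responds linearly to a single scenario's value", {
  se <- toy_scenarios()
  fw <- c(A = 0.5, B = 0.5)
  base <- zip_exposure(fw, se, 8)$chron_stove
  se2 <- se
  se2$chron_stove[1] <- se2$chron_stove[1] + 2
  bumped <- zip_exposure(fw, se2, 8)$chron_stove
  w1 <- fw[["A"]] * se$weight[1] * 0.5
  expect_equal(bumped - base, 2 * w1)
})

test_that("whole-population mean dilutes by the gas-stove share", {
  expect_identical(whole_population_mean(2.4, 1), 2.4)
  expect_identical(whole_population_mean(2.4, 0), 0)
  # stoves at a ~40% share contribute ~10% of total national exposure
  stove_pop <- whole_population_mean(2.4, 0.4)
  share <- stove_pop / (7.7 + stove_pop)
  expect_equal(share, 0.10, tolerance = 0.15)
  expect_error(whole_population_mean(1, 1.2), "\\[0, 1\\]")
  # the literal division reading inflates instead
  expect_equal(whole_population_mean(2.4, 0.4, divide = TRUE), 6)
})

test_that("rollup is the population-weighted mean with the expected bounds", {
  expect_equal(rollup(c(1, 2, 3), c(5, 5, 5)), 2)
  expect_equal(rollup(c(1, 100), c(1e9, 1)), 100 / (1e9 + 1) + 1e9 / (1e9 + 1),
               tolerance = 1e-6)
  vals <- c(2.1, 7.4, 5.0, 3.3, 9.9)
  pops <- c(100, 250, 50, 400, 200)
  expect_equal(rollup(vals, pops), sum(vals * pops) / sum(pops))
  expect_equal(rollup(vals, pops * 17), rollup(vals, pops))
  expect_gte(rollup(vals, pops), min(vals))
  expect_lte(rollup(vals, pops), max(vals))
  expect_error(rollup(vals, rep(0, 5)), "zero")
  expect_error(rollup(vals, c(-1, 1, 1, 1, 1)), ">= 0")
})

test_that("benchmark classification partitions all non-negative inputs", {
  expect_identical(as.character(classify_benchmark(6.0, 1.0, 5.2)),
                   "outdoor_alone_exceeds")
  expect_identical(as.character(classify_benchmark(4.9, 1.0, 5.2)),
                   "stove_pushes_over")
  expect_identical(as.character(classify_benchmark(3.0, 1.0, 5.2)),
                   "below_with_stove")
  set.seed(15)
  o <- runif(200, 0, 12); s <- runif(200, 0, 6)
  cls <- classify_benchmark(o, s, 5.2)
  expect_false(anyNA(cls))
  expect_true(all((o >= 5.2) == (cls == "outdoor_alone_exceeds")))
  expect_true(all((o < 5.2 & o + s >= 5.2) == (cls == "stove_pushes_over")))
  expect_true(all((o + s < 5.2) == (cls == "below_with_stove")))
  expect_error(classify_benchmark(-1, 0), "non-negative")
})
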