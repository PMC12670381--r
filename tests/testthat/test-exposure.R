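test_that("person_series follows the occupied zone", {
  co <- sim_config(windspeed = 3)
  s <- simulate_day(two_zone_fp(),
                    source_schedule("kitchen", cooking_pattern("typical") * 31),
                    co)
  # fixed in one zone: identical to that zone's series
  occ_fixed <- rep("kitchen", 144)
  expect_identical(person_series(s, occ_fixed, "NO2_stove"),
                   as.vector(s["kitchen", "NO2_stove", ]))
  # outdoors all day: stove exposure zero, tracer at outdoor level
  occ_out <- rep(outdoors_label(), 144)
  expect_identical(chronic_exposure(person_series(s, occ_out, "NO2_stove")), 0)
  expect_identical(person_series(s, occ_out, "CONTA"), rep(100, 144))
  # alternating schedule interleaves elementwise
  occ_alt <- rep(c("kitchen", "living"), 72)
  ps <- person_series(s, occ_alt, "NO2_stove")
  odd <- seq(1, 143, by = 2)
  expect_identical(ps[odd], as.vector(s["kitchen", "NO2_stove", odd]))
  expect_identical(ps[odd + 1], as.vector(s["living", "NO2_stove", odd + 1]))
  expect_error(person_series(s, rep("garage", 144)), "unknown zone")
})

test_that("chronic exposure is the 24-h mean", {
  expect_identical(chronic_exposure(rep(10, 144)), 10)
  expect_identical(chronic_exposure(c(rep(0, 143), 144)), 1)
  set.seed(11)
  x <- rlnorm(144)
  expect_equal(chronic_exposure(x), sum(x) / 144)
  expect_error(chronic_exposure(1:10), "144")
})

test_that("acute exposure is the max over complete 1-h windows", {
  expect_identical(acute_exposure(rep(10, 144)), 10)
  spike <- rep(0, 144); spike[80] <- 600
  expect_equal(acute_exposure(spike), 100)
  # brute-force oracle over the 139 complete windows
  set.seed(12)
  for (rep_i in 1:5) {
    x <- rlnorm(144, sdlog = 1.5)
    brute <- max(vapply(1:139, function(i) mean(x[i:(i + 5)]), 0))
    expect_equal(acute_exposure(x), brute)
  }
  # shift invariance
  x <- rlnorm(144)
  expect_equal(acute_exposure(x + 7), acute_exposure(x) + 7)
})

test_that("chronic <= acute <= max 10-min value on random series", {
  set.seed(13)
  for (rep_i in 1:20) {
    x <- rlnorm(144, sdlog = runif(1, 0.2, 2))
    expect_lte(chronic_exposure(x), acute_exposure(x) + 1e-12)
    expect_lte(acute_exposure(x), max(x) + 1e-12)
  }
})

test_that("outdoor-attributable exposure scales tracer infiltration", {
  expect_identical(outdoor_attributable(100, 8), 8)
  expect_identical(outdoor_attributable(0, 12), 0)
  expect_identical(outdoor_attributable(50, 10), 5)
  # linear in both arguments
  expect_equal(outdoor_attributable(37, 22), 37 * 22 / 100)
  expect_equal(outdoor_attributable(2 * 30, 5), 2 * outdoor_attributable(30, 5))
  expect_error(outdoor_attributable(101, 5), "\\[0, 100\\]")
})

test_that("weekly expectation weights day values by prevalence", {
  w <- weekly_weights(c(2, 4, 1))
  e <- weekly_expectation(c(1, 2, 3), c(10, 20, 30), w)
  expect_equal(e$chron, (2 * 1 + 4 * 2 + 1 * 3) / 7)
  expect_equal(e$acute, (2 * 10 + 4 * 20 + 1 * 30) / 7)
  expect_equal(weekly_expectation(5, 9, 1), list(chron = 5, acute = 9))
  # lies within the day range
  expect_gte(e$chron, 1); expect_lte(e$chron, 3)
  expect_error(weekly_expectation(c(1, 2), c(1, 2, 3), w), "equal length")
  expect_error(weekly_expectation(c(1, 2), c(1, 2), c(0.5, 0.6)), "normalized")
})

test_that("exceedance days per year follow the weighted fraction times 365", {
  # no exceedances
  expect_equal(
    unname(exceedance_days_per_year(c(10, 20), c(0.5, 0.5), c(FALSE, TRUE))),
    c(0, 0))
  # a 2% weighted fraction of days gives 7.3 days/year (reported as 7)
  d <- exceedance_days_per_year(
    acute_day = c(150, 50), weight = c(0.02, 0.98),
    is_heavy_week = c(FALSE, FALSE), threshold = 100,
    heavy_week_weights = 0.10)
  expect_equal(unname(d), 0.02 * 365)
  expect_identical(round(unname(d)), 7)
  # reweighting the heavy-week mass matches a brute-force reweighting
  set.seed(14)
  acute <- rlnorm(30, log(60), 1)
  w <- runif(30); heavy <- rep(c(TRUE, FALSE), 15)
  got <- exceedance_days_per_year(acute, w, heavy, 100, c(0.10, 0.05))
  for (i in 1:2) {
    hw <- c(0.10, 0.05)[i]
    wn <- w / sum(w)
    wn[heavy] <- wn[heavy] * hw / sum(wn[heavy])
    wn[!heavy] <- wn[!heavy] * (1 - hw) / sum(wn[!heavy])
    expect_equal(unname(got[i]), 365 * sum(wn[acute > 100]))
  }
  expect_error(exceedance_days_per_year(numeric(), numeric(), logical()),
               "no modeled days")
})
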