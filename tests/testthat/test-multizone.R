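test_that("flow matrices balance every zone by construction", {
  fps <- list(one_zone_fp(), two_zone_fp(), three_zone_fp())
  configs <- list(sim_config(),
                  sim_config(windspeed = 7, ambient_temperature = -3),
                  unit_driver_config(forced_air_on = TRUE))
  for (fp in fps) {
    for (co in configs) {
      for (w in c(FALSE, TRUE)) {
        q <- compute_flows(fp, co, window_state = w)
        imbalance <- abs(rowSums(q) - colSums(q))
        expect_lt(max(imbalance), 1e-9)
      }
    }
  }
})

test_that("air exchange spans the calibrated 0 to 6 per hour range", {
  fps <- generate_floorplans(synth_config(n_floorplans = 6))
  for (fp in fps) {
    calm <- sim_config(windspeed = 0, ambient_temperature = 20)
    expect_equal(whole_house_aer(compute_flows(fp, calm, FALSE), fp), 0)
    stormy <- unit_driver_config()
    expect_equal(whole_house_aer(compute_flows(fp, stormy, TRUE), fp), 6.0,
                 tolerance = 1e-9)
  }
})

test_that("zero emission gives an identically zero stove series", {
  s <- simulate_day(two_zone_fp(), sources = NULL,
                    config = sim_config(windspeed = 3))
  expect_true(all(s[, "NO2_stove", ] == 0))
})

test_that("one-zone constant source reaches the analytic steady state", {
  # dC/dt = S/V - (a + |d|) C  =>  C* = S / (V (a + |d|))
  k <- 2; V <- 250; S <- 40 # mg/h
  fp <- one_zone_fp(k, V)
  co <- unit_driver_config(decay_rate = -0.86)
  s <- simulate_day(fp, source_schedule("kitchen", S), co)
  cstar_mgm3 <- S / (V * (k + 0.86))
  cstar_ppbv <- no2home:::mgm3_to_ppbv(cstar_mgm3)
  # time constant 1/(a+|d|) = 0.35 h; by hour 24 the series has converged
  expect_equal(s["kitchen", "NO2_stove", 144], cstar_ppbv, tolerance = 0.01)
})

test_that("simulator matches an independent deSolve solution on 1-3 zones", {
  skip_if_not_installed("deSolve")
  co <- sim_config(windspeed = 4, ambient_temperature = 5)
  wsched <- rep(FALSE, 144); wsched[61:90] <- TRUE  # windows open 10:00-15:00
  emission <- cooking_pattern("typical") * 31
  for (fp in list(one_zone_fp(0.76), two_zone_fp(), three_zone_fp())) {
    sim <- simulate_day(fp, source_schedule("kitchen", emission), co,
                        window_schedule = wsched)
    for (sp in c("NO2_stove", "CONTA", "CONTB")) {
      ref <- desolve_oracle(fp, co, emission, wsched, species = sp)
      got <- matrix(sim[, sp, ], nrow = dim(sim)[1])
      scale <- max(abs(ref))
      rms <- sqrt(mean((got - ref)^2)) / scale
      expect_lt(rms, 0.005)
    }
  }
})

test_that("closed systems conserve tracer mass to 0.1% with zero decay", {
  fp <- closed_fp()
  co <- sim_config(decay_rate = 0)
  emission <- rep(0, 144); emission[1:12] <- 24  # source for the first 2 h
  s <- simulate_day(fp, source_schedule("kitchen", emission), co)
  vols <- no2home:::zone_volumes(fp)
  mass <- apply(s[, "NO2_stove", ], 2, function(v) sum(v * vols))
  after <- mass[18:144]  # once the source is off and the interval means settle
  expect_lt(diff(range(after)) / mean(after), 0.001)
})

test_that("all concentrations are non-negative and CONTA stays within bounds", {
  co <- sim_config(windspeed = 5, ambient_temperature = 0)
  s <- simulate_day(three_zone_fp(), source_schedule("kitchen", 100), co)
  expect_gte(min(s), 0)
  expect_lte(max(s[, "CONTA", ]), 100 + 1e-9)
  # zero decay: CONTA is at steady state with the full outdoor level
  s0 <- simulate_day(three_zone_fp(), config = sim_config(decay_rate = 0,
                                                          windspeed = 5))
  expect_equal(as.vector(s0[, "CONTA", ]),
               rep(100, length(s0[, "CONTA", ])), tolerance = 1e-6)
})

test_that("stove concentrations are linear in emission rate", {
  co <- sim_config(windspeed = 3)
  s1 <- simulate_day(two_zone_fp(), source_schedule("kitchen", 20), co)
  s2 <- simulate_day(two_zone_fp(), source_schedule("kitchen", 40), co)
  expect_equal(2 * s1[, "NO2_stove", ], s2[, "NO2_stove", ],
               tolerance = 1e-9)
})

test_that("raising capture efficiency never raises any stove concentration", {
  co <- sim_config(windspeed = 3)
  hood_on <- cooking_intervals("typical")
  emission <- cooking_pattern("typical") * 199
  prev <- NULL
  for (ce in c(0, 0.3, 0.6, 0.9)) {
    s <- simulate_day(two_zone_fp(),
                      source_schedule("kitchen", emission, ce), co,
                      hood_schedule = hood_on)
    if (!is.null(prev))
      expect_true(all(s[, "NO2_stove", ] <= prev[, "NO2_stove", ] + 1e-12))
    prev <- s
  }
})

test_that("air_exchange_constant recovers known single-zone rates within 2%", {
  co <- unit_driver_config()
  for (k in c(0.1, 0.76, 2, 6)) {
    s <- simulate_day(one_zone_fp(k), config = co)
    est <- air_exchange_constant(s, co)
    expect_false(est$censored)
    expect_equal(est$k, k, tolerance = 0.02)
  }
})

test_that("doubling all flows doubles the recovered air-exchange constant", {
  co <- unit_driver_config()
  k1 <- air_exchange_constant(simulate_day(two_zone_fp(60, 40, 120),
                                           config = co), co)$k
  k2 <- air_exchange_constant(simulate_day(two_zone_fp(120, 80, 240),
                                           config = co), co)$k
  expect_equal(k2 / k1, 2, tolerance = 0.02)
})

test_that("a sealed dwelling yields the censored lower-bound flag", {
  fp <- one_zone_fp(1e-6)
  est <- air_exchange_constant(simulate_day(fp, config = unit_driver_config()),
                               unit_driver_config())
  expect_true(est$censored)
  expect_true(is.na(est$k))
  expect_gt(est$k_lower_bound, 0)
})

test_that("interval means are exact, not instantaneous samples", {
  # for a pure exponential rise the first 10-min mean is 1 - (1-e^-kh)/(kh),
  # below the instantaneous endpoint value 1 - e^-kh
  k <- 2
  s <- simulate_day(one_zone_fp(k), config = unit_driver_config())
  h <- 1 / 6
  frac1 <- s["kitchen", "CONTB", 1] / 100
  expect_equal(frac1, 1 - (1 - exp(-k * h)) / (k * h), tolerance = 1e-6)
})
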