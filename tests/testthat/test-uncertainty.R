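test_that("decay sampler matches its three quantile anchors", {
  set.seed(101)
  x <- sample_decay(10000)
  expect_equal(median(x), -0.86, tolerance = 0.025)
  expect_equal(mean(x >= -2.07 & x <= -0.17), 0.95, tolerance = 0.011)
  expect_true(all(quantile(x, c(0.025, 0.975)) < 0))
})

test_that("symmetric anchors give a symmetric (zero-skew) fit", {
  p <- fit_skew_normal(0, -1.96, 1.96)
  expect_equal(p$alpha, 0, tolerance = 5e-3)
  expect_equal(p$xi, 0, tolerance = 1e-3)
  expect_equal(p$omega, 1, tolerance = 1e-3)
  expect_error(fit_skew_normal(0, 1, 2), "q_low < median")
})

degenerate_dists <- function(ef = 48, dr = -0.86, bi = 0.5, ce = 0.3,
                             u = 35) {
  mc_input_distributions(
    ef = function(n) rep(ef, n), dr = function(n) rep(dr, n),
    bi = function(n) rep(bi, n), ce = function(n) rep(ce, n),
    u = function(n) rep(u, n))
}

test_that("point-mass inputs give unit multipliers", {
  m <- mc_multipliers(degenerate_dists(), iterations = 1000)
  expect_equal(unname(m$stove), c(1, 1, 1))
  expect_equal(unname(m$outdoor), c(1, 1, 1))
})

test_that("multipliers have unit median and ordered percentiles", {
  set.seed(102)
  m <- mc_multipliers(iterations = 5000)
  for (ch in list(m$stove, m$outdoor)) {
    expect_equal(unname(ch["central"]), 1, tolerance = 1e-12)
    expect_lte(ch[["lower"]], 1)
    expect_gte(ch[["upper"]], 1)
  }
  # the stove product has the outdoor factors plus extra independent ones
  stove_width <- m$stove[["upper"]] / m$stove[["lower"]]
  outdoor_width <- m$outdoor[["upper"]] / m$outdoor[["lower"]]
  expect_gte(stove_width, outdoor_width)
})

test_that("multiplier runs are reproducible and scale-free in EF", {
  set.seed(103)
  m1 <- mc_multipliers(iterations = 2000)
  set.seed(103)
  m2 <- mc_multipliers(iterations = 2000)
  expect_identical(m1, m2)
  # doubling the emission factor doubles the raw product percentiles, so the
  # median-scaled multipliers are unchanged
  base <- degenerate_dists()
  set.seed(104)
  a <- mc_multipliers(mc_input_distributions(
    ef = function(n) runif(n, 20, 80), dr = base$dr, bi = base$bi,
    ce = base$ce, u = base$u), 2000)
  set.seed(104)
  b <- mc_multipliers(mc_input_distributions(
    ef = function(n) 2 * runif(n, 20, 80), dr = base$dr, bi = base$bi,
    ce = base$ce, u = base$u), 2000)
  expect_equal(a$stove, b$stove, tolerance = 1e-12)
})

test_that("CI construction and summaries keep their ordering", {
  expect_equal(unclass(apply_ci(0, c(lower = 0.5, central = 1, upper = 2))),
               c(lower = 0, central = 0, upper = 0))
  ci <- apply_ci(2.4, c(lower = 0.5, central = 1, upper = 2))
  expect_equal(unclass(ci), c(lower = 1.2, central = 2.4, upper = 4.8))
  expect_error(ci_value(2, 1, 3), "ordering")
  cis <- list(ci_value(1, 2, 3), ci_value(2, 4, 6), ci_value(3, 6, 9))
  expect_equal(unclass(summarize_ci(mean, cis)),
               c(lower = 2, central = 4, upper = 6))
  expect_equal(unclass(summarize_ci(max, cis)),
               c(lower = 3, central = 6, upper = 9))
  expect_equal(unclass(summarize_ci(mean, cis[2])),
               c(lower = 2, central = 4, upper = 6))
  expect_warning(summarize_ci(function(v) -mean(v), cis), "not monotone")
})

test_that("the 95% multiplier interval covers draws from the same process", {
  set.seed(105)
  dists <- mc_input_distributions()
  m <- mc_multipliers(dists, iterations = 10000)
  # synthetic truth: fresh draws of the same scaled product
  ef <- dists$ef(1000); dr <- dists$dr(1000); bi <- dists$bi(1000)
  ce <- dists$ce(1000); u <- dists$u(1000)
  prod <- ef * dr * bi * (1 - ce) * u
  scaled <- prod / median(prod)
  covered <- mean(scaled >= m$stove[["lower"]] & scaled <= m$stove[["upper"]])
  expect_equal(covered, 0.95, tolerance = 0.025)
})
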