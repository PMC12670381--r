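# --- skew-normal distribution -------------------------------------------
# density 2/omega * phi(z) * Phi(alpha z), z = (x - xi)/omega.
# CDF evaluated by quadrature of the standardized density; accurate far
# beyond the 1e-6 level needed for quantile work here.

sn_pdf_std <- function(z, alpha) 2 * dnorm(z) * pnorm(alpha * z)

sn_cdf_std <- function(z, alpha) {
  vapply(z, function(zi) {
    if (zi < -12) return(0)
    integrate(sn_pdf_std, lower = -12, upper = zi, alpha = alpha,
              rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, 0)
}

sn_quantile_std <- function(p, alpha) {
  vapply(p, function(pi) {
    uniroot(function(z) sn_cdf_std(z, alpha) - pi, lower = -12, upper = 12,
            tol = 1e-10)$root
  }, 0)
}

#' Fit a skew-normal distribution to three quantile anchors
#'
#' Solves location `xi`, scale `omega` and shape `alpha` so the distribution
#' has the given median and equal-tailed central interval: `P(X < q_low) =
#' (1 - level)/2` and `P(X > q_high) = (1 - level)/2`.
#'
#' @param median Target median.
#' @param q_low,q_high Central-interval endpoints (`q_low < median < q_high`).
#' @param level Central-interval probability mass (default 0.95).
#' @return List with `xi`, `omega`, `alpha`.
#' @export
fit_skew_normal <- function(median, q_low, q_high, level = 0.95) {
  if (!(q_low < median && median < q_high))
    stop("anchors must satisfy q_low < median < q_high", call. = FALSE)
  p <- (1 - level) / 2
  target_ratio <- (q_high - median) / (median - q_low)
  ratio <- function(alpha) {
    z <- sn_quantile_std(c(p, 0.5, 1 - p), alpha)
    (z[3] - z[2]) / (z[2] - z[1])
  }
  root <- tryCatch(
    uniroot(function(a) ratio(a) - target_ratio, lower = -40, upper = 40,
            tol = 1e-8),
    error = function(e) stop("skew-normal parameter solve failed to ",
                             "converge: ", conditionMessage(e), call. = FALSE)
  )
  alpha <- root$root
  z <- sn_quantile_std(c(p, 0.5, 1 - p), alpha)
  omega <- (q_high - q_low) / (z[3] - z[1])
  xi <- median - omega * z[2]
  list(xi = xi, omega = omega, alpha = alpha)
}

#' Sample from a skew-normal distribution
#'
#' Uses the standard construction `Z = delta |Z0| + sqrt(1 - delta^2) Z1` with
#' `delta = alpha / sqrt(1 + alpha^2)`.
#'
#' @param n Number of draws.
#' @param xi,omega,alpha Location, scale (> 0), shape.
#' @return Numeric vector of `n` draws.
#' @export
rskewnorm <- function(n, xi = 0, omega = 1, alpha = 0) {
  stopifnot(n > 0, omega > 0)
  delta <- alpha / sqrt(1 + alpha^2)
  z0 <- abs(rnorm(n))
  z1 <- rnorm(n)
  xi + omega * (delta * z0 + sqrt(1 - delta^2) * z1)
}

#' Sample the indoor NO2 decay rate
#'
#' Draws from a skew-normal distribution fitted so the median is -0.86 per
#' hour and 95% of the mass lies between -2.07 and -0.17 per hour (the central
#' literature value and the spread of reported surface-loss rates).
#'
#' @param n Number of draws.
#' @param median Median decay rate, per hour.
#' @param q_low,q_high 2.5th and 97.5th percentile anchors, per hour.
#' @return Numeric vector of `n` negative rates, per hour.
#' @export
sample_decay <- function(n, median = -0.86, q_low = -2.07, q_high = -0.17) {
  par <- fit_skew_normal(median, q_low, q_high)
  rskewnorm(n, par$xi, par$omega, par$alpha)
}

# --- Monte Carlo multipliers --------------------------------------------

#' Monte Carlo input distributions
#'
#' Samplers for the five multiplicative uncertainty factors: emission factor
#' (EF), decay rate (DR), burner intensity (BI, normal with mean 0.5 and
#' sd 0.1 as a fraction of a high burner, truncated to (0, 1]), hood capture
#' efficiency (CE, in `[0, 1]`) and cooking minutes (U). EF, CE and U default
#' to resampling with replacement from the synthetic empirical tables in
#' [generate_behavior_samplers()].
#'
#' @param ef,dr,bi,ce,u Functions of `n` returning `n` draws.
#' @return A `mc_input_distributions` object.
#' @export
mc_input_distributions <- function(ef = NULL, dr = NULL, bi = NULL,
                                   ce = NULL, u = NULL) {
  samplers <- generate_behavior_samplers(synth_config())
  if (is.null(ef)) ef <- samplers$emission_factor
  if (is.null(dr)) dr <- sample_decay
  if (is.null(bi)) bi <- function(n) {
    x <- rnorm(n, 0.5, 0.1)
    while (any(bad <- x <= 0 | x > 1)) x[bad] <- rnorm(sum(bad), 0.5, 0.1)
    x
  }
  if (is.null(ce)) ce <- samplers$capture_efficiency
  if (is.null(u)) u <- samplers$cooking_minutes
  structure(list(ef = ef, dr = dr, bi = bi, ce = ce, u = u),
            class = "mc_input_distributions")
}

#' Monte Carlo uncertainty multipliers
#'
#' For each iteration, draws one value from each factor distribution and forms
#' the stove product `EF * DR * BI * (1 - CE) * U` and the outdoor product
#' `DR * (1 - CE)`; across iterations, takes the 2.5th/50th/97.5th percentiles
#' and divides by the median so the scaled median equals 1. (The decay-rate
#' draws are negative; scaling by the median makes the multipliers sign-free.)
#'
#' @param dists A [mc_input_distributions()] object.
#' @param iterations Number of iterations (>= 1000; default 10,000).
#' @return A `mc_multipliers` object: list with `stove` and `outdoor`, each a
#'   named vector `c(lower, central, upper)` with `central == 1`.
#' @export
mc_multipliers <- function(dists = mc_input_distributions(),
                           iterations = 10000) {
  stopifnot(inherits(dists, "mc_input_distributions"), iterations >= 1000)
  ef <- dists$ef(iterations)
  dr <- dists$dr(iterations)
  bi <- dists$bi(iterations)
  ce <- dists$ce(iterations)
  u <- dists$u(iterations)
  if (any(ce < 0 | ce > 1))
    stop("capture-efficiency draws must lie in [0, 1]", call. = FALSE)
  scaled_percentiles <- function(x) {
    med <- median(x)
    if (med == 0) stop("degenerate factor distribution (median 0)",
                       call. = FALSE)
    s <- x / med
    q <- quantile(s, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    setNames(q, c("lower", "central", "upper"))
  }
  structure(
    list(stove = scaled_percentiles(ef * dr * bi * (1 - ce) * u),
         outdoor = scaled_percentiles(dr * (1 - ce)),
         iterations = iterations),
    class = "mc_multipliers"
  )
}

#' Confidence-interval triple
#'
#' @param lower,central,upper Values with `lower <= central <= upper`.
#' @return A `ci_value`: named numeric vector of length 3.
#' @export
ci_value <- function(lower, central, upper) {
  if (!(lower <= central && central <= upper))
    stop("CI ordering violated: need lower <= central <= upper",
         call. = FALSE)
  structure(c(lower = lower, central = central, upper = upper),
            class = "ci_value")
}

#' Apply multiplier percentiles to a central estimate
#'
#' Returns `(central * lower_mult, central, central * upper_mult)`.
#'
#' @param central Central exposure estimate, ppbv (>= 0).
#' @param mult A 3-vector of scaled multipliers (`stove` or `outdoor` channel
#'   of [mc_multipliers()]).
#' @return A [ci_value()].
#' @export
apply_ci <- function(central, mult) {
  if (central < 0) stop("central estimate must be >= 0", call. = FALSE)
  ci_value(central * mult[["lower"]], central * mult[["central"]],
           central * mult[["upper"]])
}

#' Summarize confidence intervals across ZIP codes
#'
#' Applies a summary function separately to the lower bounds, the central
#' estimates, and the upper bounds — e.g. the lower bound of the average of
#' three ZIP codes is the average of their lower bounds. Valid for summary
#' functions monotone in each argument; a warning is raised if the resulting
#' triple is not ordered.
#'
#' @param f Summary function taking a numeric vector (e.g. `mean`, `max`) or
#'   one taking extra arguments passed via `...`.
#' @param cis A list of [ci_value()] objects.
#' @param ... Passed on to `f`.
#' @return A [ci_value()].
#' @export
summarize_ci <- function(f, cis, ...) {
  stopifnot(length(cis) > 0)
  m <- do.call(rbind, lapply(cis, unclass))
  lo <- f(m[, "lower"], ...)
  ce <- f(m[, "central"], ...)
  up <- f(m[, "upper"], ...)
  if (!(lo <= ce && ce <= up)) {
    warning("summary function is not monotone on these intervals; ",
            "returned bounds are not ordered", call. = FALSE)
    return(structure(c(lower = lo, central = ce, upper = up),
                     class = "ci_value"))
  }
  ci_value(lo, ce, up)
}
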