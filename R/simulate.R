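#' Stove source schedule
#'
#' Emission schedule for the NO2 stove source, placed in one zone (normally the
#' kitchen). While the range hood is on, the emission rate is multiplied by
#' `1 - capture_efficiency`: hoods are modeled as source scaling, never as
#' exhaust fans, because hood exhaust removes air that is not yet well-mixed.
#' Recirculating hoods are represented by `capture_efficiency = 0`.
#'
#' @param zone_id Zone receiving the emission.
#' @param emission_rate mg/h; a scalar or a vector of 144 10-min values.
#' @param capture_efficiency Fraction of emissions removed while the hood is
#'   on, in `[0, 1]`.
#' @return A `source_schedule` object.
#' @export
source_schedule <- function(zone_id, emission_rate, capture_efficiency = 0) {
  if (length(emission_rate) == 1L)
    emission_rate <- rep(emission_rate, N_INTERVALS)
  if (length(emission_rate) != N_INTERVALS)
    stop("emission_rate must have length 1 or 144", call. = FALSE)
  if (any(emission_rate < 0)) stop("emissions must be >= 0", call. = FALSE)
  if (capture_efficiency < 0 || capture_efficiency > 1)
    stop("capture_efficiency must be in [0, 1]", call. = FALSE)
  structure(list(zone_id = zone_id, emission_rate = emission_rate,
                 capture_efficiency = capture_efficiency),
            class = "source_schedule")
}

# Van Loan augmented-block matrix exponential: for dC/dt = A C + b over a step
# of length h (b constant within the step),
#   C(h)            = Phi C0 + G1 b,   mean over the step = (G1 C0 + G2 b) / h
# with Phi = e^(A h), G1 = int_0^h e^(A s) ds, G2 = int_0^h (h - s) e^(A s) ds.
# Valid for singular A (closed systems), unlike the resolvent form.
step_operator <- function(a, h) {
  n <- nrow(a)
  m <- matrix(0, 3L * n, 3L * n)
  m[1:n, 1:n] <- a
  m[1:n, (n + 1):(2L * n)] <- diag(n)
  m[(n + 1):(2L * n), (2L * n + 1):(3L * n)] <- diag(n)
  e <- as.matrix(Matrix::expm(m * h))
  list(phi = e[1:n, 1:n, drop = FALSE],
       g1 = e[1:n, (n + 1):(2L * n), drop = FALSE],
       g2 = e[1:n, (2L * n + 1):(3L * n), drop = FALSE])
}

# state matrix for one species: A[z,y] = Q[y,z]/Vz (y != z),
# A[z,z] = -(sum of outflows)/Vz + decay
state_matrix <- function(q, vols, decay) {
  ids <- names(vols)
  a <- t(q[ids, ids, drop = FALSE]) / vols
  diag(a) <- -(rowSums(q[ids, , drop = FALSE])) / vols + decay
  a
}

#' Simulate one 24-h day in a multizone dwelling
#'
#' Integrates the linear well-mixed mass-balance system
#' \deqn{dC_z/dt = (1/V_z)\left[\sum_y Q_{yz} C_y - \sum_y Q_{zy} C_z +
#'   Q_{out,z} C_{out}\right] + S_z/V_z + d\,C_z}
#' for three species: `NO2_stove` (indoor stove source, zero outdoors, decays
#' at `config$decay_rate`), the infiltration tracer `CONTA` (no indoor source,
#' 100 ppbv outdoors, decays like NO2, initialized at its steady state so its
#' 24-h mean reads directly as percent infiltration), and the inert air-
#' exchange tracer `CONTB` (100 ppbv outdoors, no decay, starts at 0 indoors).
#'
#' Each 10-min output is the exact interval mean of the matrix-exponential
#' solution (sources and flows are constant within an interval), not an
#' instantaneous sample.
#'
#' @param fp A [floorplan()].
#' @param sources A [source_schedule()] (or `NULL` for no stove source).
#' @param config A [sim_config()].
#' @param window_schedule Logical vector of 144 (or scalar): when `TRUE`,
#'   every operable window (kitchen, bedrooms, living room) is open together.
#' @param hood_schedule Logical vector of 144 (or scalar): range hood on.
#' @return A `concentration_series`: array `[zone, species, interval]` in ppbv
#'   with the zone volumes, outdoor tracer level and config kept as attributes.
#' @export
simulate_day <- function(fp, sources = NULL, config = sim_config(),
                         window_schedule = FALSE, hood_schedule = FALSE) {
  validate_floorplan(fp)
  stopifnot(inherits(config, "sim_config"))
  if (length(window_schedule) == 1L)
    window_schedule <- rep(isTRUE(window_schedule), N_INTERVALS)
  if (length(hood_schedule) == 1L)
    hood_schedule <- rep(isTRUE(hood_schedule), N_INTERVALS)
  stopifnot(length(window_schedule) == N_INTERVALS,
            length(hood_schedule) == N_INTERVALS)
  ids <- zone_ids(fp)
  vols <- zone_volumes(fp)
  n <- length(ids)
  h <- config$output_interval / 3600  # hours

  emis <- rep(0, N_INTERVALS)
  src_zone <- NULL
  ce <- 0
  if (!is.null(sources)) {
    stopifnot(inherits(sources, "source_schedule"))
    if (!sources$zone_id %in% ids)
      stop("source zone not in floorplan", call. = FALSE)
    emis <- sources$emission_rate
    src_zone <- sources$zone_id
    ce <- sources$capture_efficiency
  }

  # flow matrices and step operators per window state actually used
  states <- unique(window_schedule)
  ops <- list()
  for (w in states) {
    q <- compute_flows(fp, config, window_state = w)
    key <- as.character(w)
    a_decay <- state_matrix(q, vols, config$decay_rate)
    a_inert <- state_matrix(q, vols, 0)
    ops[[key]] <- list(
      q_in = q[OUTDOORS, ids] / vols,   # outdoor inflow per unit outdoor conc
      decay = c(list(a = a_decay), step_operator(a_decay, h)),
      inert = c(list(a = a_inert), step_operator(a_inert, h))
    )
  }

  out <- array(0, dim = c(n, 3L, N_INTERVALS),
               dimnames = list(zone = ids,
                               species = c("NO2_stove", "CONTA", "CONTB"),
                               interval = NULL))

  # CONTA initial condition: steady state under the first interval's flows
  op0 <- ops[[as.character(window_schedule[1L])]]
  b_conta0 <- op0$q_in * config$conta_outdoor
  conta0 <- if (max(abs(b_conta0)) == 0) rep(0, n) else tryCatch(
    solve(op0$decay$a, -b_conta0),
    error = function(e) stop("cannot initialize CONTA steady state: ",
                             conditionMessage(e), call. = FALSE)
  )

  c_no2 <- rep(0, n)          # mg/m3
  c_conta <- as.numeric(conta0)  # ppbv
  c_contb <- rep(0, n)        # ppbv
  for (i in seq_len(N_INTERVALS)) {
    op <- ops[[as.character(window_schedule[i])]]
    s <- rep(0, n)
    if (!is.null(src_zone)) {
      rate <- emis[i] * (if (hood_schedule[i]) 1 - ce else 1)
      s[match(src_zone, ids)] <- rate / vols[[src_zone]]  # mg/m3/h
    }
    b_conta <- op$q_in * config$conta_outdoor
    b_contb <- op$q_in * config$conta_outdoor

    d <- op$decay
    out[, "NO2_stove", i] <- (d$g1 %*% c_no2 + d$g2 %*% s) / h
    c_no2 <- as.numeric(d$phi %*% c_no2 + d$g1 %*% s)
    out[, "CONTA", i] <- (d$g1 %*% c_conta + d$g2 %*% b_conta) / h
    c_conta <- as.numeric(d$phi %*% c_conta + d$g1 %*% b_conta)
    ii <- op$inert
    out[, "CONTB", i] <- (ii$g1 %*% c_contb + ii$g2 %*% b_contb) / h
    c_contb <- as.numeric(ii$phi %*% c_contb + ii$g1 %*% b_contb)
  }

  if (any(!is.finite(out)))
    stop("integration produced non-finite concentrations (check volumes and ",
         "flows)", call. = FALSE)
  if (min(out) < -1e-6)
    stop("integration produced negative concentrations beyond roundoff",
         call. = FALSE)
  out[out < 0] <- 0
  out[, "NO2_stove", ] <- mgm3_to_ppbv(
    out[, "NO2_stove", , drop = FALSE],
    gas_conditions(config$indoor_temperature))
  structure(out, class = "concentration_series", volumes = vols,
            conta_outdoor = config$conta_outdoor,
            decay_rate = config$decay_rate,
            floorplan_id = fp$floorplan_id)
}

#' Tidy a concentration series
#'
#' @param x A `concentration_series` from [simulate_day()].
#' @param ... Unused.
#' @return A data frame with columns `zone`, `species`, `interval_index`,
#'   `ppbv`.
#' @export
as.data.frame.concentration_series <- function(x, ...) {
  d <- dim(x)
  dn <- dimnames(x)
  data.frame(
    zone = rep(dn$zone, times = d[2] * d[3]),
    species = rep(rep(dn$species, each = d[1]), times = d[3]),
    interval_index = rep(seq_len(d[3]), each = d[1] * d[2]),
    ppbv = as.vector(unclass(x))
  )
}

#' Recover the whole-dwelling air-exchange constant from the inert tracer
#'
#' Computes `k = 1/tau`, where `tau` is the time at which the volume-weighted
#' indoor concentration of the inert tracer CONTB (which starts at 0 indoors)
#' first reaches `1 - 1/e` (~63.2%) of its outdoor level. The crossing is
#' located by log-linear interpolation of `1 - C/C_out` at interval midpoints,
#' then corrected for interval averaging (10-min outputs are means, which lag
#' the instantaneous curve by `log(sinh(kh/2)/(kh/2))/k`; the correction is
#' exact for a single-exponential approach).
#'
#' @param series A `concentration_series` containing CONTB.
#' @param config The [sim_config()] used to produce it.
#' @return An `aer_estimate`: list with `k` (per hour, `NA` if censored),
#'   `tau` (hours), `censored` (threshold never reached within 24 h) and
#'   `k_lower_bound` (only meaningful when censored: the threshold not being
#'   reached implies `k` below this value).
#' @export
air_exchange_constant <- function(series, config = sim_config()) {
  stopifnot(inherits(series, "concentration_series"))
  vols <- attr(series, "volumes")
  outdoor <- attr(series, "conta_outdoor")
  h <- config$output_interval / 3600
  cb <- apply(series[, "CONTB", , drop = FALSE], 3, function(v)
    sum(v * vols) / sum(vols))
  y <- pmax(1 - cb / outdoor, 1e-12)  # remaining fraction, decays like e^-kt
  t_mid <- (seq_len(N_INTERVALS) - 0.5) * h
  target <- exp(-1)
  j <- which(y <= target)
  if (!length(j)) {
    # threshold not reached: tau > 24 h, so k < 1/24; also bound from endpoint
    kl <- max(1 / 24, -log(y[N_INTERVALS]) / t_mid[N_INTERVALS])
    return(structure(list(k = NA_real_, tau = NA_real_, censored = TRUE,
                          k_lower_bound = kl),
                     class = "aer_estimate"))
  }
  j <- j[1L]
  i1 <- if (j == 1L) 1L else j - 1L
  i2 <- if (j == 1L) 2L else j
  ly <- log(y)
  tau0 <- t_mid[i1] + (ly[i1] - (-1)) / (ly[i1] - ly[i2]) *
    (t_mid[i2] - t_mid[i1])
  tau <- tau0
  for (it in 1:4) {
    k <- 1 / tau
    x <- k * h / 2
    tau <- tau0 - log(sinh(x) / x) / k
  }
  structure(list(k = 1 / tau, tau = tau, censored = FALSE,
                 k_lower_bound = NA_real_),
            class = "aer_estimate")
}

#' @exportS3Method base::print
print.aer_estimate <- function(x, ...) {
  if (x$censored)
    cat(sprintf("<aer_estimate> censored: k < %.3f /h (63.2%% not reached in 24 h)\n",
                x$k_lower_bound))
  else
    cat(sprintf("<aer_estimate> k = %.3f /h (tau = %.2f h)\n", x$k, x$tau))
  invisible(x)
}
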