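# Fed-batch feeding laws and a minimal growth-with-inhibitor simulator.
#
# Two feeding regimes are modelled: EFC (exponential feeding culture), where
# the feed rate follows F(t) = F0 * exp(SFR * t) for the whole run, and LFC
# (limited feeding culture), where the specific feed rate SFR starts at the
# same value and is then progressively decreased to track the declining
# specific growth rate of the culture.

#' Fed-batch simulation parameters
#'
#' Bundles the feeding-law and growth-model parameters with field-typical
#' defaults. The inhibitor terms implement a minimal growth-linked secretion
#' model: an inhibitory compound accumulates in proportion to biomass growth
#' and shuts growth down as it approaches a capacity.
#'
#' @param F0 Initial feed rate (L h^-1). Default matches the initial
#'   substrate demand of `X0` growing at `sfr`.
#' @param sfr Specific feed rate (h^-1), default 0.16.
#' @param feed_duration Length of the feeding phase (h), default 30.
#' @param switch_time Time (h) at which the LFC regime starts tracking the
#'   growth-rate decline, default 10.
#' @param mu_max Maximum specific growth rate (h^-1), default 0.45.
#' @param Ks Substrate half-saturation constant (g L^-1), default 0.2.
#' @param yield Biomass yield on substrate (g g^-1), default 0.5.
#' @param k_inhibitor Inhibitor secreted per unit biomass formed
#'   (arbitrary units per g L^-1), default 0.1; 0 disables inhibition.
#' @param inhibitor_capacity Inhibitor level at which growth stops
#'   (same units), default 3.
#' @param X0 Biomass at feed onset (g L^-1), default 1.
#' @param S0 Substrate at feed onset (g L^-1), default 0.5.
#' @param s_in Substrate concentration of the feed (g L^-1), default 300.
#' @param volume Culture volume (L, constant-volume approximation),
#'   default 1.
#' @param od_factor OD590 units per g L^-1 biomass, default 2.30.
#' @param coupling `"growth"` couples inhibitor secretion to mu*X;
#'   `"biomass"` couples it to X alone.
#' @return A list of class `fedbatch_params`.
#' @export
fedbatch_params <- function(F0 = NULL, sfr = 0.16, feed_duration = 30,
                            switch_time = 10, mu_max = 0.45, Ks = 0.2,
                            yield = 0.5, k_inhibitor = 0.1,
                            inhibitor_capacity = 3, X0 = 1, S0 = 0.5,
                            s_in = 300, volume = 1, od_factor = 2.30,
                            coupling = c("growth", "biomass")) {
  coupling <- match.arg(coupling)
  if (is.null(F0)) F0 <- sfr * X0 * volume / (yield * s_in)
  p <- list(F0 = F0, sfr = sfr, feed_duration = feed_duration,
            switch_time = switch_time, mu_max = mu_max, Ks = Ks,
            yield = yield, k_inhibitor = k_inhibitor,
            inhibitor_capacity = inhibitor_capacity, X0 = X0, S0 = S0,
            s_in = s_in, volume = volume, od_factor = od_factor,
            coupling = coupling)
  rates <- c("F0", "sfr", "mu_max", "Ks", "yield", "k_inhibitor", "X0", "S0")
  if (any(unlist(p[rates]) < 0)) stop("rates and concentrations must be >= 0")
  if (od_factor <= 0) stop("OD conversion factor must be positive")
  class(p) <- "fedbatch_params"
  p
}

#' Exponential feeding law
#'
#' `F(t) = F0 * exp(SFR * t)`.
#'
#' @param F0 Initial feed rate.
#' @param sfr Specific feed rate (h^-1).
#' @param t Time since feed onset (h), vectorized; must be >= 0.
#' @return Feed rate at `t`, same units as `F0`.
#' @export
exponential_feed <- function(F0, sfr, t) {
  if (any(t < 0)) stop("time must be non-negative")
  F0 * exp(sfr * t)
}

#' Limited (growth-tracking) feed profile from a realized growth series
#'
#' Holds the specific feed rate at `sfr` until `switch_time`, then scales it
#' by the ratio of the current specific growth rate to its value at the
#' switch, clipped to `[0, sfr]`. The feed rate integrates this SFR:
#' `F(t) = F0 * exp(integral of SFR)` (trapezoidal on the growth grid).
#'
#' @param params A `fedbatch_params` list (uses `F0`, `sfr`, `switch_time`).
#' @param growth Growth tibble with `time_h` and `biomass_g_per_L`
#'   (strictly increasing times).
#' @return Tibble with columns `time_h`, `sfr`, `feed_rate`.
#' @export
limited_feed_profile <- function(params, growth) {
  t <- growth$time_h; x <- growth$biomass_g_per_L
  if (is.unsorted(t, strictly = TRUE)) stop("non-monotone time grid")
  # specific growth rate per backward interval, carried to t_i; first point
  # inherits the first interval's value
  mu <- c(NA_real_, diff(log(pmax(x, .Machine$double.eps))) / diff(t))
  mu[1] <- mu[2]
  mu_switch <- stats::approx(t, mu, xout = params$switch_time, rule = 2)$y
  sfr_t <- ifelse(t < params$switch_time, params$sfr,
                  pmin(params$sfr, pmax(0, params$sfr * mu / mu_switch)))
  cum <- cumsum(c(0, diff(t) * (utils::head(sfr_t, -1) + sfr_t[-1]) / 2))
  tibble::tibble(time_h = t, sfr = sfr_t,
                 feed_rate = params$F0 * exp(cum))
}

#' Simulate a fed-batch culture with growth-linked inhibition
#'
#' Integrates, with fixed-step fourth-order Runge-Kutta,
#' `dX/dt = mu X`, `dS/dt = F s_in / V - mu X / Y`, `dI/dt = k mu X`
#' (or `k X` under biomass coupling), with
#' `mu = mu_max * S/(Ks+S) * max(0, 1 - I/Icap)`. Under the EFC regime the
#' feed is exponential throughout; under LFC the specific feed rate tracks
#' the realized specific growth rate after `switch_time`.
#'
#' @param params A `fedbatch_params` list.
#' @param mode `"efc"` or `"lfc"`.
#' @param dt Integration step (h), default 0.01.
#' @return A tibble of class `fedbatch_sim` with columns `time_h`,
#'   `biomass_g_per_L`, `od590`, `substrate`, `inhibitor`, `feed_rate`, `mu`.
#' @export
simulate_fedbatch <- function(params, mode = c("efc", "lfc"), dt = 0.01) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("dt must be positive")
  p <- params
  n <- ceiling(p$feed_duration / dt)
  times <- seq(0, by = dt, length.out = n + 1L)
  mu_of <- function(S, I) {
    inhib <- if (is.finite(p$inhibitor_capacity))
      max(0, 1 - I / p$inhibitor_capacity) else 1
    p$mu_max * S / (p$Ks + S) * inhib
  }
  deriv <- function(state, feed) {
    X <- state[1]; S <- max(state[2], 0); I <- state[3]
    mu <- mu_of(S, I)
    dI <- if (p$coupling == "growth") p$k_inhibitor * mu * X
          else p$k_inhibitor * X
    c(mu * X, feed * p$s_in / p$volume - mu * X / p$yield, dI)
  }
  X <- numeric(n + 1L); S <- numeric(n + 1L); I <- numeric(n + 1L)
  Fv <- numeric(n + 1L); muv <- numeric(n + 1L)
  state <- c(p$X0, p$S0, 0)
  Fcur <- p$F0
  mu_ref <- NA_real_  # specific growth rate at the LFC switch
  for (i in seq_len(n + 1L)) {
    X[i] <- state[1]; S[i] <- state[2]; I[i] <- state[3]
    muv[i] <- mu_of(max(state[2], 0), state[3])
    if (mode == "lfc" && times[i] >= p$switch_time && is.na(mu_ref))
      mu_ref <- max(muv[i], 1e-12)
    sfr_i <- if (mode == "efc" || times[i] < p$switch_time) p$sfr
             else min(p$sfr, max(0, p$sfr * muv[i] / mu_ref))
    Fv[i] <- Fcur
    if (i > n) break
    # RK4 step with feed held at its step-start value; F advances by the
    # step's SFR afterwards
    k1 <- deriv(state, Fcur)
    k2 <- deriv(state + dt / 2 * k1, Fcur)
    k3 <- deriv(state + dt / 2 * k2, Fcur)
    k4 <- deriv(state + dt * k3, Fcur)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    state[2] <- max(state[2], 0)
    if (any(!is.finite(state)))
      stop(sprintf("non-finite state at t = %.3f h", times[i + 1L]))
    Fcur <- Fcur * exp(sfr_i * dt)
  }
  out <- tibble::tibble(
    time_h = times, biomass_g_per_L = X,
    od590 = biomass_to_od(X, p$od_factor),
    substrate = S, inhibitor = I, feed_rate = Fv, mu = muv
  )
  attr(out, "params") <- p
  attr(out, "mode") <- mode
  class(out) <- c("fedbatch_sim", class(out))
  out
}

#' Convert optical density to biomass and back
#'
#' The calibration is `OD590 = factor * biomass`, with a default factor of
#' 2.30 OD590 units per g L^-1.
#'
#' @param od OD590 readings (>= 0).
#' @param factor OD590 units per g L^-1 (> 0).
#' @return Biomass in g L^-1.
#' @export
od_to_biomass <- function(od, factor = 2.30) {
  if (factor <= 0) stop("OD conversion factor must be positive")
  if (any(od < 0)) stop("OD must be non-negative")
  od / factor
}

#' @rdname od_to_biomass
#' @param biomass Biomass in g L^-1.
#' @export
biomass_to_od <- function(biomass, factor = 2.30) {
  if (factor <= 0) stop("OD conversion factor must be positive")
  biomass * factor
}

#' Growth rate by backward differences
#'
#' The growth rate at observation time `t_i` (i >= 2) is
#' `(X_i - X_{i-1}) / (t_i - t_{i-1})`; the first observation has no rate.
#'
#' @param growth Growth tibble with `time_h`, `biomass_g_per_L`.
#' @return Tibble with columns `time_h`, `rate` (g L^-1 h^-1), one row per
#'   observation from the second onward.
#' @export
growth_rate_series <- function(growth) {
  t <- growth$time_h; x <- growth$biomass_g_per_L
  if (length(t) < 2L) stop("need at least two time points")
  if (anyDuplicated(t)) stop("duplicate time points")
  if (is.unsorted(t)) stop("time points must be increasing")
  tibble::tibble(time_h = t[-1], rate = diff(x) / diff(t))
}
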