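#' Porous-screen pressure-jump coefficients for a braided device
#'
#' The deployed braid is represented in the flow solver as a porous screen
#' across the aneurysm neck (and any jailed ostium): the through-flow
#' pressure jump is
#' \deqn{\Delta p = \tfrac{\rho}{2} K u_n |u_n| + \tfrac{\mu}{\alpha} u_n.}
#' The two terms carry the low- and high-wire-Reynolds-number limits of
#' screen drag. The braid of local porosity \eqn{\beta} is treated as two
#' crossed wire rows in series, each of per-row coverage
#' \eqn{c = 1 - \sqrt{\beta}} (so that the union coverage matches the
#' braid's metal fraction) and wire spacing \eqn{s = d_w / c}. The viscous
#' permeability length comes from the classical transverse creeping-flow
#' drag of a row of cylinders (Tamada-Fujikawa):
#' \eqn{\alpha = s\,\Lambda / (16\pi)} with
#' \eqn{\Lambda = 1 - 2\ln\tau + \tau^2/6}, \eqn{\tau = \pi d_w / s};
#' the inertial coefficient is the standard screen loss
#' \eqn{K = k_0 (1-\beta^2)/\beta^2}. Both vanish as porosity approaches
#' one (transparent screen); constants are overridable for custom
#' correlations.
#'
#' @param local_porosity Local screen porosity in (0, 1): one minus the
#'   local metal coverage of the neck.
#' @param wire_diameter Wire diameter, micrometres.
#' @param props [fluid_properties()] (carried for Reynolds reporting).
#' @param k0 Inertial screen-loss constant (default 1).
#' @return List with `K` (dimensionless), `alpha` (m), `porosity`,
#'   `row_spacing` (m).
#' @export
screen_coefficients <- function(local_porosity, wire_diameter = 30,
                                props = fluid_properties(), k0 = 1.0) {
  if (local_porosity <= 0 || local_porosity >= 1)
    stop("porosity must lie strictly inside (0, 1)")
  beta <- local_porosity
  d_w <- wire_diameter * 1e-6
  cvr <- 1 - sqrt(beta)                      # per-row wire coverage
  s <- d_w / cvr
  tau <- pi * d_w / s
  Lam <- 1 - 2 * log(tau) + tau^2 / 6
  alpha <- s * Lam / (16 * pi)               # two rows in series
  K <- k0 * (1 - beta^2) / beta^2
  list(K = K, alpha = alpha, porosity = beta, wire_diameter = wire_diameter,
       row_spacing = s)
}

#' Aneurysm inflow reduction
#'
#' Percentage reduction in aneurysm inflow due to device deployment:
#' 100 x (inflow without device - inflow with device) / inflow without
#' device, using cycle-averaged (or steady) inflows from matching
#' geometry and waveform.
#'
#' @param Q_no_device,Q_with_device Cycle-averaged aneurysm inflows.
#' @return Reduction in percent.
#' @export
inflow_reduction <- function(Q_no_device, Q_with_device) {
  if (Q_no_device <= 0) stop("inflow without device must be positive")
  100 * (Q_no_device - Q_with_device) / Q_no_device
}

#' Lumped junction network for outlet-pressure sweeps
#'
#' Single-junction resistor network: a prescribed inlet flow divides among
#' branches with linear resistances to fixed outlet pressures. Used to
#' parameterize the effect of raising jailed daughter-vessel outlet
#' pressure: the jailed outlet pressures are increased in steps (default
#' 0/100/200/300 Pa) and the flow split re-solved exactly.
#'
#' @param resistances Branch resistances, Pa per (mL/min).
#' @param outlet_pressures Branch outlet pressures, Pa.
#' @param jailed Logical per branch.
#' @param inlet_flow Total inlet flow, mL/min.
#' @param bias_sweep Jailed-outlet pressure increments, Pa.
#' @return A `lumped_network` object.
#' @export
lumped_network <- function(resistances, outlet_pressures = NULL,
                           jailed = NULL, inlet_flow = 120,
                           bias_sweep = c(0, 100, 200, 300)) {
  nb <- length(resistances)
  stopifnot(nb >= 2, all(resistances > 0), inlet_flow > 0)
  outlet_pressures <- outlet_pressures %||% rep(0, nb)
  jailed <- jailed %||% c(TRUE, rep(FALSE, nb - 1L))
  stopifnot(length(outlet_pressures) == nb, length(jailed) == nb)
  structure(list(resistances = resistances,
                 outlet_pressures = outlet_pressures, jailed = jailed,
                 inlet_flow = inlet_flow, bias_sweep = bias_sweep),
            class = "lumped_network")
}

#' @rdname lumped_network
#' @param network A `lumped_network`.
#' @return For `solve_lumped`: a data.frame with one row per bias level:
#'   junction pressure, per-branch flows (mL/min), and the stented
#'   (non-jailed) outflow fraction.
#' @export
solve_lumped <- function(network) {
  stopifnot(inherits(network, "lumped_network"))
  R <- network$resistances
  G <- sum(1 / R)
  if (!is.finite(G) || G <= 0) stop("singular lumped network")
  res <- lapply(network$bias_sweep, function(b) {
    p_out <- network$outlet_pressures + b * network$jailed
    P <- (network$inlet_flow + sum(p_out / R)) / G
    Q <- (P - p_out) / R
    data.frame(bias = b, junction_pressure = P,
               t(stats::setNames(Q, paste0("Q", seq_along(Q)))),
               stented_fraction = sum(Q[!network$jailed]) / network$inlet_flow)
  })
  do.call(rbind, res)
}

#' Mesh / time-step independence check
#'
#' Given a metric series over successively refined meshes (or time steps),
#' returns the first index at which the relative change to the next
#' refinement falls below the threshold (default 1%).
#'
#' @param metric_series Numeric vector in refinement order.
#' @param threshold Relative-change criterion (default 0.01).
#' @return List with `index` (first converged index, or `NA` if the series
#'   never converges) and `rel_change` (successive relative changes).
#' @export
independence_check <- function(metric_series, threshold = 0.01) {
  stopifnot(length(metric_series) >= 2)
  rel <- abs(diff(metric_series)) / abs(metric_series[-length(metric_series)])
  idx <- which(rel < threshold)
  list(index = if (length(idx)) idx[1] else NA_integer_, rel_change = rel)
}
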