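#' Blood properties
#'
#' Newtonian blood surrogate: density 1000 kg/m^3, dynamic viscosity
#' 0.004 Pa s.
#'
#' @param density kg/m^3.
#' @param dynamic_viscosity Pa s.
#' @return A `fluid_properties` object.
#' @export
fluid_properties <- function(density = 1000, dynamic_viscosity = 0.004) {
  stopifnot(density > 0, dynamic_viscosity > 0)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

# site envelopes: cycle mean and instantaneous range, mL/min
waveform_sites <- list(
  ICA = list(mean = 230, range = c(130, 570)),
  BA  = list(mean = 120, range = c(105, 180)))

#' Pulsatile parent-vessel flow waveform
#'
#' Parametric surrogate of a cerebral inflow waveform: a systolic peak and
#' dicrotic bump shaped by two raised exponential lobes, rescaled so the
#' cycle minimum/maximum match the site envelope and the cycle mean matches
#' `mean_flow` (the shape exponent is solved by bisection). Site envelopes:
#' ICA mean 230 mL/min, range 130-570; BA mean 120 mL/min, range 105-180.
#'
#' @param site "ICA", "BA" or "custom".
#' @param heart_rate_bpm Heart rate; default 75 BPM (0.8 s period).
#' @param mean_flow Cycle-mean flow, mL/min; defaults to the site mean.
#' @param flow_range Instantaneous range `c(min, max)`; required for
#'   `site = "custom"`.
#' @param n_samples Samples per cycle.
#' @return A `waveform` object with fields `period` (s), `samples`
#'   (data.frame `t` s, `Q` mL/min), `mean_flow`, `site`.
#' @export
make_waveform <- function(site = c("ICA", "BA", "custom"),
                          heart_rate_bpm = 75, mean_flow = NULL,
                          flow_range = NULL, n_samples = 512L) {
  site <- match.arg(site)
  if (site == "custom") {
    if (is.null(flow_range) || is.null(mean_flow))
      stop("custom site requires mean_flow and flow_range")
    env <- list(mean = mean_flow, range = flow_range)
  } else {
    env <- waveform_sites[[site]]
    if (!is.null(mean_flow)) env$mean <- mean_flow
    if (!is.null(flow_range)) env$range <- flow_range
  }
  stopifnot(env$mean > 0, env$range[1] < env$mean, env$mean < env$range[2])
  period <- 60 / heart_rate_bpm
  tt <- seq(0, 1, length.out = n_samples + 1L)[-(n_samples + 1L)]
  g <- exp(-((tt - 0.15) / 0.09)^2) + 0.35 * exp(-((tt - 0.42) / 0.07)^2)
  g <- (g - min(g)) / (max(g) - min(g))
  target <- (env$mean - env$range[1]) / (env$range[2] - env$range[1])
  fmean <- function(p) mean(g^p) - target
  p_exp <- stats::uniroot(fmean, c(0.05, 40), tol = 1e-10)$root
  Q <- env$range[1] + (env$range[2] - env$range[1]) * g^p_exp
  structure(list(period = period,
                 samples = data.frame(t = tt * period, Q = Q),
                 mean_flow = mean(Q), site = site, range = env$range),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s: period %.3f s, mean %.1f mL/min, range [%.0f, %.0f]\n",
              x$site, x$period, x$mean_flow, min(x$samples$Q), max(x$samples$Q)))
  invisible(x)
}

# Interpolated flow at arbitrary times (periodic), mL/min.
waveform_flow_at <- function(wf, t) {
  tm <- t %% wf$period
  stats::approx(c(wf$samples$t, wf$period),
                c(wf$samples$Q, wf$samples$Q[1]), xout = tm)$y
}

#' Reynolds and Womersley numbers of a waveform in a vessel
#'
#' Re = rho U D / mu with U the cross-section mean velocity 4Q/(pi D^2),
#' evaluated at the waveform extremes; Womersley alpha = (D/2)
#' sqrt(2 pi f rho / mu).
#'
#' @param waveform A [make_waveform()] object (or a single flow in mL/min).
#' @param diameter Vessel diameter, mm.
#' @param props [fluid_properties()].
#' @return List with `Re_min`, `Re_max`, `alpha`.
#' @export
reynolds_womersley <- function(waveform, diameter, props = fluid_properties()) {
  stopifnot(diameter > 0)
  Q <- if (inherits(waveform, "waveform")) range(waveform$samples$Q) else
    range(waveform)
  f <- if (inherits(waveform, "waveform")) 1 / waveform$period else 75 / 60
  D <- diameter / 1000
  U <- 4 * (Q / 6e7) / (pi * D^2)            # mL/min -> m^3/s
  Re <- props$density * U * D / props$dynamic_viscosity
  alpha <- (D / 2) * sqrt(2 * pi * f * props$density / props$dynamic_viscosity)
  list(Re_min = min(Re), Re_max = max(Re), alpha = alpha)
}
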