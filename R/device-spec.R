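#' Braided flow-diverter device specification
#'
#' Describes a braided ("rhomboid" cell) flow-diverter as manufactured:
#' nominal diameter and length of the cylindrical envelope, strand count,
#' wire diameter and target surface porosity. Porosity is the fraction of
#' the cylindrical envelope not occupied by metal; commercial devices of
#' this class (SILK, Pipeline) braid 48 strands of ~30 micron wire to a
#' nominal porosity around 70%.
#'
#' @param nominal_diameter Nominal (fully expanded) outer diameter, mm.
#' @param length Device length at nominal diameter, mm.
#' @param n_strands Number of braided strands (must be even); half are wound
#'   clockwise, half counter-clockwise.
#' @param wire_diameter Wire diameter, micrometres.
#' @param target_porosity Target surface porosity in (0, 1).
#' @param strand_turns Full helical turns per strand over the device length.
#'   If `NULL` (default) it is solved by [generate_device()] so that the
#'   braid porosity matches `target_porosity`.
#' @return An object of class `device_spec`.
#' @examples
#' spec <- device_spec(3.5, 20)
#' spec
#' @export
device_spec <- function(nominal_diameter, length, n_strands = 48L,
                        wire_diameter = 30, target_porosity = 0.70,
                        strand_turns = NULL) {
  stopifnot(nominal_diameter > 0, length > 0, wire_diameter >= 0)
  if (n_strands %% 2L != 0L || n_strands < 4L)
    stop("n_strands must be an even count >= 4")
  if (target_porosity <= 0 || target_porosity >= 1)
    stop("target_porosity must lie strictly inside (0, 1)")
  if (nominal_diameter < 2.0 || nominal_diameter > 5.0)
    warning("nominal_diameter outside the 2.0-5.0 mm range of commercial devices")
  if (length < 15 || length > 40)
    warning("length outside the 15-40 mm range of commercial devices")
  structure(list(nominal_diameter = nominal_diameter, length = length,
                 n_strands = as.integer(n_strands),
                 wire_diameter = wire_diameter,
                 target_porosity = target_porosity,
                 strand_turns = strand_turns),
            class = "device_spec")
}

#' @export
print.device_spec <- function(x, ...) {
  cat(sprintf("<device_spec> %.2f mm x %.1f mm, %d strands, %.0f um wire, target porosity %.2f\n",
              x$nominal_diameter, x$length, x$n_strands, x$wire_diameter,
              x$target_porosity))
  if (!is.null(x$strand_turns))
    cat(sprintf("  strand_turns: %.3f\n", x$strand_turns))
  invisible(x)
}

#' Metal coverage of a uniform diamond lattice
#'
#' Closed-form union coverage of two crossed families of parallel struts,
#' each with wire-width to perpendicular-spacing ratio `w_over_d`:
#' coverage = 2(w/d) - (w/d)^2. Porosity of the lattice is one minus this.
#'
#' @param w_over_d Ratio of wire width to perpendicular strut spacing.
#' @return Covered area fraction.
#' @export
diamond_lattice_coverage <- function(w_over_d) {
  stopifnot(all(w_over_d >= 0), all(w_over_d <= 1))
  2 * w_over_d - w_over_d^2
}

# Closed-form braid porosity for a given turn count.
# Helix angle psi from the device axis: tan(psi) = turns * pi * D / L.
# Perpendicular spacing of one strand family: s = pi * D * cos(psi) / (n/2).
braid_porosity_closed_form <- function(n_strands, wire_um, diameter_mm,
                                       length_mm, turns) {
  m <- n_strands / 2
  w <- wire_um / 1000
  cospsi <- length_mm / sqrt(length_mm^2 + (turns * pi * diameter_mm)^2)
  s_perp <- pi * diameter_mm * cospsi / m
  cov <- w / s_perp
  if (cov >= 1) return(0)
  1 - diamond_lattice_coverage(cov)
}

# Solve strand turn count so closed-form porosity matches the target.
# Bisection (via uniroot) on turns; porosity is monotone decreasing in turns.
solve_strand_turns <- function(spec) {
  t_lo <- 0.25
  # upper bound: coverage per family of 0.5 (porosity 0.25) or helix angle 85deg
  t_hi <- 0.99 * spec$length * tan(85 * pi / 180) / (pi * spec$nominal_diameter)
  p_hi <- braid_porosity_closed_form(spec$n_strands, spec$wire_diameter,
                                     spec$nominal_diameter, spec$length, t_lo)
  p_lo <- braid_porosity_closed_form(spec$n_strands, spec$wire_diameter,
                                     spec$nominal_diameter, spec$length, t_hi)
  if (spec$target_porosity > p_hi || spec$target_porosity < p_lo)
    stop(sprintf(paste0("target porosity %.3f infeasible for %d strands of ",
                        "%.0f um wire at %.2f mm diameter: achievable range ",
                        "[%.3f, %.3f]"),
                 spec$target_porosity, spec$n_strands, spec$wire_diameter,
                 spec$nominal_diameter, max(p_lo, 0), p_hi))
  f <- function(t) braid_porosity_closed_form(spec$n_strands, spec$wire_diameter,
                                              spec$nominal_diameter, spec$length,
                                              t) - spec$target_porosity
  stats::uniroot(f, c(t_lo, t_hi), tol = 1e-6)$root
}
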