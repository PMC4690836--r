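#' Canonical wide-necked bifurcation aneurysm fixture
#'
#' The idealized symmetric study geometry: 4 mm parent, two 3 mm daughters
#' at +/-60 degrees, 8 mm dome over a 5 mm neck, branch lengths five local
#' diameters. Used throughout the examples, tests and the reduced-scale
#' reproduction studies.
#'
#' @param build_surface Extract the 3D surface (not needed for 2D flow).
#' @return A `vessel_geometry`.
#' @export
aneurysm_fixture <- function(build_surface = FALSE) {
  make_bifurcation_aneurysm(bifurcation_spec(), build_surface = build_surface)
}

#' Ostium screen segment for a daughter branch
#'
#' Cross-branch segment (2D slice coordinates, mm) perpendicular to the
#' daughter centerline close to its take-off, where a device deployed from
#' the parent into the other daughter jails this branch.
#'
#' @param geom An aneurysm `vessel_geometry`.
#' @param branch Branch name (e.g. `"daughter_1"`).
#' @param s_along Arc-length position of the screen along the branch, in
#'   local diameters (default 1.2).
#' @return `c(x1, y1, x2, y2)` in mm.
#' @export
ostium_segment <- function(geom, branch, s_along = 1.2) {
  cl <- NULL
  for (b in geom$centerlines) if (b$name == branch) cl <- b
  if (is.null(cl)) stop(sprintf("no branch named '%s'", branch))
  pa <- polyline_point_at(cl$points, s_along * cl$diameter)
  n2 <- c(-pa$tangent[1, 2], pa$tangent[1, 1])
  half <- cl$diameter / 2 + 0.6
  p <- pa$point[1, 1:2]
  c(p - half * n2, p + half * n2)
}

#' Attach device screens to a fixture flow problem
#'
#' Adds the porous pressure-jump representation of a deployed device to a
#' 2D flow problem: one screen across the aneurysm neck and one across each
#' jailed daughter ostium, all with coefficients from the local metal
#' coverage.
#'
#' @param problem 2D `flow_problem` of an aneurysm geometry.
#' @param coverage Local metal coverage fraction (default 0.30, the nominal
#'   70%-porosity device).
#' @param wire_diameter Wire diameter, um.
#' @param jailed_branches Branch names to jail (default `"daughter_1"`).
#' @param props [fluid_properties()].
#' @return The augmented `flow_problem`.
#' @export
add_device_screens <- function(problem, coverage = 0.30, wire_diameter = 30,
                               jailed_branches = "daughter_1",
                               props = fluid_properties()) {
  geom <- problem$geom
  if (is.null(geom$neck_segment2)) stop("geometry carries no neck segment")
  sc <- screen_coefficients(1 - coverage, wire_diameter, props)
  problem <- add_screen(problem, geom$neck_segment2, sc, label = "neck")
  for (b in jailed_branches)
    problem <- add_screen(problem, ostium_segment(geom, b), sc,
                          label = paste0("ostium_", b))
  problem
}
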