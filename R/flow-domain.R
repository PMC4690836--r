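# Cartesian immersed-boundary flow domain.
#
# The lumen is rasterized onto a uniform staggered (MAC) grid from the
# geometry's signed-distance function: cell centers with sdf < 0 are fluid.
# Caps of synthetic geometries lie on the bounding-box edges, so inlet and
# outlet faces are grid-aligned boundary faces. All solver-facing
# quantities are SI (metres, seconds, Pa); geometry files are mm.

#' Rasterize a vessel geometry into a flow problem
#'
#' @param geom A `vessel_geometry` (synthetic, with implicit SDF).
#' @param resolution Cells across the smallest branch diameter (>= 8).
#' @param mode "2D" (symmetry-plane slice) or "3D".
#' @param dt Solver time step, s (default 0.01).
#' @param n_cycles Cardiac cycles to simulate (default 3).
#' @param outlet_pressures Named or positional vector of outlet pressures,
#'   Pa (default all 0).
#' @param outlet_resistances Optional distal resistances per outlet,
#'   Pa/(m^2/s) in 2D (Pa/(m^3/s) in 3D); models trimmed distal
#'   vasculature via p_out = p_set + R Q. Default 0 (fixed pressure).
#' @return A `flow_problem`.
#' @export
rasterize_domain <- function(geom, resolution = 16, mode = c("2D", "3D"),
                             dt = 0.01, n_cycles = 3,
                             outlet_pressures = NULL,
                             outlet_resistances = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(geom, "vessel_geometry"))
  if (resolution < 8)
    stop("resolution must be at least 8 cells across the smallest diameter")
  if (mode == "3D") return(rasterize_domain_3d(geom, resolution, dt, n_cycles,
                                               outlet_pressures,
                                               outlet_resistances))
  if (is.null(geom$sdf2))
    stop("geometry has no 2D slice SDF; import/synthesize with one or use 3D")
  if (is.null(geom$cap_edges2))
    stop("geometry caps are not grid-aligned; 2D mode needs cap_edges2")
  dmin <- min(geom$branch_diameters)
  h_mm <- dmin / resolution
  bb <- geom$bbox2
  nx <- floor((bb[2, 1] - bb[1, 1]) / h_mm)
  ny <- ceiling((bb[2, 2] - bb[1, 2]) / h_mm)
  xs <- bb[1, 1] + (seq_len(nx) - 0.5) * h_mm
  ys <- bb[1, 2] + (seq_len(ny) - 0.5) * h_mm
  gx <- rep(xs, times = ny); gy <- rep(ys, each = nx)
  fluid <- matrix(geom$sdf2(gx, gy) < 0, nx, ny)

  caps <- lapply(geom$cap_edges2, function(cp) {
    if (cp$edge == "ymin") {
      idx <- which(fluid[, 1] & xs > cp$range[1] & xs < cp$range[2])
      pos <- xs[idx]
    } else if (cp$edge == "xmin") {
      idx <- which(fluid[1, ] & ys > cp$range[1] & ys < cp$range[2])
      pos <- ys[idx]
    } else if (cp$edge == "xmax") {
      idx <- which(fluid[nx, ] & ys > cp$range[1] & ys < cp$range[2])
      pos <- ys[idx]
    } else {
      idx <- which(fluid[, ny] & xs > cp$range[1] & xs < cp$range[2])
      pos <- xs[idx]
    }
    c(cp, list(idx = idx, pos = pos))
  })
  types <- vapply(caps, `[[`, "", "type")
  if (sum(types == "inlet") != 1) stop("geometry must expose exactly one inlet")
  if (!any(types == "outlet")) stop("geometry must expose at least one outlet")
  inlet <- caps[[which(types == "inlet")]]
  outlets <- caps[types == "outlet"]
  if (length(inlet$idx) < 4) stop("inlet cap not resolved on the grid")

  # connectivity: flood fill from the inlet; pockets unreachable from the
  # inlet indicate a disconnected fluid region
  reach <- matrix(FALSE, nx, ny)
  switch(inlet$edge,
         ymin = { reach[inlet$idx, 1] <- TRUE },
         ymax = { reach[inlet$idx, ny] <- TRUE },
         xmin = { reach[1, inlet$idx] <- TRUE },
         xmax = { reach[nx, inlet$idx] <- TRUE })
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nx, ]
    grown[-nx, ] <- grown[-nx, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ny]
    grown[, -ny] <- grown[, -ny] | reach[, -1]
    grown <- grown & fluid
    if (identical(grown, reach)) break
    reach <- grown
  }
  if (any(fluid & !reach)) {
    n_orphan <- sum(fluid & !reach)
    if (n_orphan > 0.002 * sum(fluid))
      stop(sprintf("disconnected fluid region: %d cells unreachable from inlet",
                   n_orphan))
    fluid <- reach                              # drop sub-voxel slivers
  }

  op <- rep(0, length(outlets))
  if (!is.null(outlet_pressures)) op[seq_along(outlet_pressures)] <- outlet_pressures
  or <- rep(0, length(outlets))
  if (!is.null(outlet_resistances)) or[seq_along(outlet_resistances)] <- outlet_resistances
  for (i in seq_along(outlets)) {
    outlets[[i]]$pressure <- op[i]
    outlets[[i]]$resistance <- or[i]
  }

  structure(list(mode = "2D", h = h_mm * 1e-3, h_mm = h_mm, nx = nx, ny = ny,
                 x0 = bb[1, 1], y0 = bb[1, 2], xs = xs, ys = ys,
                 fluid = fluid, n_fluid = sum(fluid),
                 inlet = inlet, outlets = outlets, screens = list(),
                 dt = dt, n_cycles = n_cycles, geom = geom),
            class = "flow_problem")
}

#' @export
print.flow_problem <- function(x, ...) {
  cat(sprintf("<flow_problem> %s grid %s, h = %.3f mm, %d fluid cells, %d outlet(s), %d screen(s)\n",
              x$mode, if (x$mode == "2D") sprintf("%dx%d", x$nx, x$ny)
              else sprintf("%dx%dx%d", x$nx, x$ny, x$nz),
              x$h_mm, x$n_fluid, length(x$outlets), length(x$screens)))
  invisible(x)
}

#' Add a porous-screen segment to a flow problem
#'
#' Marks the staggered faces crossed by the segment (mm coordinates, in the
#' 2D slice plane) as pressure-jump faces with the given coefficients.
#'
#' @param problem A 2D `flow_problem`.
#' @param segment `c(x1, y1, x2, y2)` in mm.
#' @param coeffs Output of [screen_coefficients()].
#' @param label Optional screen name.
#' @return The augmented `flow_problem`.
#' @export
add_screen <- function(problem, segment, coeffs, label = "screen") {
  stopifnot(inherits(problem, "flow_problem"), problem$mode == "2D")
  seg <- as.numeric(segment)
  h <- problem$h_mm; nx <- problem$nx; ny <- problem$ny
  xs <- problem$xs; ys <- problem$ys
  cross_test <- function(px1, py1, px2, py2) {
    d1 <- (seg[3] - seg[1]) * (py1 - seg[2]) - (seg[4] - seg[2]) * (px1 - seg[1])
    d2 <- (seg[3] - seg[1]) * (py2 - seg[2]) - (seg[4] - seg[2]) * (px2 - seg[1])
    e1 <- (px2 - px1) * (seg[2] - py1) - (py2 - py1) * (seg[1] - px1)
    e2 <- (px2 - px1) * (seg[4] - py1) - (py2 - py1) * (seg[3] - px1)
    (d1 * d2 <= 0) & (e1 * e2 <= 0)
  }
  # u-faces (i = 2..nx, j): dual edge joins centers of cells (i-1, j), (i, j)
  iu <- rep(2:nx, times = ny); ju <- rep(seq_len(ny), each = nx - 1L)
  hit_u <- cross_test(xs[iu - 1L], ys[ju], xs[iu], ys[ju])
  act_u <- problem$fluid[cbind(iu - 1L, ju)] & problem$fluid[cbind(iu, ju)]
  ufaces <- cbind(i = iu, j = ju)[hit_u & act_u, , drop = FALSE]
  # v-faces (i, j = 2..ny): dual edge joins centers of cells (i, j-1), (i, j)
  iv <- rep(seq_len(nx), times = ny - 1L); jv <- rep(2:ny, each = nx)
  hit_v <- cross_test(xs[iv], ys[jv - 1L], xs[iv], ys[jv])
  act_v <- problem$fluid[cbind(iv, jv - 1L)] & problem$fluid[cbind(iv, jv)]
  vfaces <- cbind(i = iv, j = jv)[hit_v & act_v, , drop = FALSE]
  if (nrow(ufaces) + nrow(vfaces) == 0)
    stop("screen segment does not cross any fluid faces")
  problem$screens <- c(problem$screens,
                       list(list(label = label, segment = seg, K = coeffs$K,
                                 alpha = coeffs$alpha,
                                 porosity = coeffs$porosity,
                                 ufaces = ufaces, vfaces = vfaces)))
  problem
}
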