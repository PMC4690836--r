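#' Wall shear stress from a flow field
#'
#' One-sided estimate at every wall-adjacent fluid cell: the tangential
#' velocity at the cell center divided by the true wall distance from the
#' signed-distance function (not the staircase distance), times the dynamic
#' viscosity. Reports the per-snapshot fields plus the spatio-temporal mean
#' and peak, and whether the peak lies below the 4 Pa physiological
#' threshold.
#'
#' @param field A `flow_field` (2D).
#' @param region Optional logical matrix (nx x ny) restricting the wall
#'   cells considered (e.g. the aneurysm dome).
#' @return A `wss_field`: `tau` (wall cells x snapshots, Pa), `cells`,
#'   `peak`, `mean`, `below_4Pa`.
#' @export
compute_wss <- function(field, region = NULL) {
  problem <- field$problem
  stopifnot(problem$mode == "2D")
  props <- field$props
  nx <- problem$nx; ny <- problem$ny; h <- problem$h
  fluid <- problem$fluid
  solid <- !fluid
  nb_solid <- matrix(FALSE, nx, ny)
  nb_solid[-1, ] <- nb_solid[-1, ] | solid[-nx, ]
  nb_solid[-nx, ] <- nb_solid[-nx, ] | solid[-1, ]
  nb_solid[, -1] <- nb_solid[, -1] | solid[, -ny]
  nb_solid[, -ny] <- nb_solid[, -ny] | solid[, -1]
  # grid-boundary cells count as wall-adjacent unless they sit on a cap
  edge_wall <- matrix(FALSE, nx, ny)
  edge_wall[1, ] <- edge_wall[nx, ] <- TRUE
  edge_wall[, 1] <- edge_wall[, ny] <- TRUE
  caps <- c(list(problem$inlet), problem$outlets)
  for (cp in caps) {
    switch(cp$edge,
           ymin = { edge_wall[cp$idx, 1] <- FALSE },
           ymax = { edge_wall[cp$idx, ny] <- FALSE },
           xmin = { edge_wall[1, cp$idx] <- FALSE },
           xmax = { edge_wall[nx, cp$idx] <- FALSE })
  }
  wall <- fluid & (nb_solid | edge_wall)
  if (!is.null(region)) wall <- wall & region
  wc <- which(wall, arr.ind = TRUE)
  if (nrow(wc) == 0) stop("no wall cells in the requested region")
  xs <- problem$xs[wc[, 1]]; ys <- problem$ys[wc[, 2]]
  d_mm <- -problem$geom$sdf2(xs, ys)
  d <- pmax(d_mm, 0.25 * problem$h_mm) * 1e-3
  # wall normal from the SDF gradient
  eps <- 0.25 * problem$h_mm
  gx <- (problem$geom$sdf2(xs + eps, ys) - problem$geom$sdf2(xs - eps, ys))
  gy <- (problem$geom$sdf2(xs, ys + eps) - problem$geom$sdf2(xs, ys - eps))
  gn <- sqrt(gx^2 + gy^2); gx <- gx / pmax(gn, 1e-12); gy <- gy / pmax(gn, 1e-12)

  snap_tau <- function(u, v) {
    uc <- 0.5 * (u[wc] + u[cbind(wc[, 1] + 1L, wc[, 2])])
    vc <- 0.5 * (v[wc] + v[cbind(wc[, 1], wc[, 2] + 1L)])
    un <- uc * gx + vc * gy
    ut <- sqrt(pmax(uc^2 + vc^2 - un^2, 0))
    props$dynamic_viscosity * ut / d
  }
  tau <- vapply(seq_along(field$u),
                function(k) snap_tau(field$u[[k]], field$v[[k]]),
                numeric(nrow(wc)))
  tau <- matrix(tau, nrow = nrow(wc))
  structure(list(tau = tau, cells = wc, x = xs, y = ys,
                 peak = max(tau), mean = mean(tau),
                 below_4Pa = max(tau) < 4), class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("<wss_field> %d wall cells x %d snapshots; peak %.3f Pa, mean %.3f Pa (%s 4 Pa)\n",
              nrow(x$tau), ncol(x$tau), x$peak, x$mean,
              if (x$below_4Pa) "peak <" else "peak >="))
  invisible(x)
}

#' Aneurysm inflow through the neck plane
#'
#' Integrates the into-dome-directed (positive along the dome axis) part of
#' the normal velocity across the neck plane, per stored snapshot. In 2D
#' the flux is per unit slab depth (m^2/s).
#'
#' @param field A `flow_field`.
#' @param neck A [define_neck_plane()] object.
#' @param wire_diameter Wire diameter (um) used for the device-proximity
#'   warning (a plane within 2 wire diameters of a screen gives spurious
#'   local-vorticity flux).
#' @return List with `series` (per-snapshot inflow), `times`, `mean`
#'   (cycle mean over the stored window, or the steady value).
#' @export
aneurysm_inflow <- function(field, neck, wire_diameter = 30) {
  problem <- field$problem
  stopifnot(problem$mode == "2D")
  h <- problem$h
  y_p <- neck$point[2]
  jf <- round((y_p - problem$y0) / problem$h_mm) + 1L
  if (jf < 2L || jf > problem$ny) stop("neck plane lies outside the fluid grid")
  xok <- which(abs(problem$xs) <= neck$radius + problem$h_mm / 2)
  act <- problem$fluid[cbind(xok, jf - 1L)] & problem$fluid[cbind(xok, jf)]
  xok <- xok[act]
  if (length(xok) == 0) stop("neck plane does not intersect fluid cells")
  for (sc in problem$screens) {
    if (min(abs(sc$segment[c(2, 4)] - y_p)) < 2 * wire_diameter / 1000)
      warning("neck plane lies within 2 wire diameters of a screen; expect spurious flux")
  }
  series <- vapply(field$v, function(v) sum(pmax(v[cbind(xok, jf)], 0)) * h, 0)
  tm <- field$times
  structure(list(series = series, times = tm, mean = mean(series),
                 j_face = jf, cells = xok), class = "inflow_series")
}
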