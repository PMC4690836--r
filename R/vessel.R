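#' Parametric bifurcation-aneurysm specification
#'
#' Parameters of the synthetic wide-necked bifurcation aneurysm: a parent
#' vessel splitting into 2 or 4 daughter branches with a spherical dome
#' blended over the bifurcation apex through a circular neck. Defaults give
#' an idealized ICA-terminus-like fixture (4 mm parent, two 3 mm daughters,
#' 8 mm dome, 5 mm neck); `n_daughters = 4` gives a basilar-tip-like layout
#' with two PCA-like and two SCA-like branches.
#'
#' @param parent_diameter Parent vessel diameter, mm.
#' @param daughter_diameters Daughter diameters, mm (length `n_daughters`).
#' @param daughter_angles Initial branch angles from the parent axis,
#'   degrees (signed; negative = left).
#' @param n_daughters 2 or 4.
#' @param dome_diameter Aneurysm dome diameter, mm.
#' @param neck_diameter Neck diameter, mm (must not exceed the dome).
#' @param vessel_length_factor Branch centerline length in local diameters.
#' @return An object of class `bifurcation_spec`.
#' @export
bifurcation_spec <- function(parent_diameter = 4, daughter_diameters = NULL,
                             daughter_angles = NULL, n_daughters = 2L,
                             dome_diameter = 8, neck_diameter = 5,
                             vessel_length_factor = 5) {
  if (!n_daughters %in% c(2L, 4L)) stop("n_daughters must be 2 or 4")
  if (is.null(daughter_diameters))
    daughter_diameters <- if (n_daughters == 2L) c(3, 3) else c(2.2, 2.2, 1.6, 1.6)
  if (is.null(daughter_angles))
    daughter_angles <- if (n_daughters == 2L) c(-60, 60) else c(-60, 60, -35, 35)
  stopifnot(length(daughter_diameters) == n_daughters,
            length(daughter_angles) == n_daughters,
            all(daughter_diameters > 0), parent_diameter > 0,
            dome_diameter > 0, neck_diameter > 0)
  if (neck_diameter > dome_diameter)
    stop("neck_diameter must not exceed dome_diameter")
  structure(list(parent_diameter = parent_diameter,
                 daughter_diameters = daughter_diameters,
                 daughter_angles = daughter_angles,
                 n_daughters = as.integer(n_daughters),
                 dome_diameter = dome_diameter,
                 neck_diameter = neck_diameter,
                 vessel_length_factor = vessel_length_factor),
            class = "bifurcation_spec")
}

# finite-cylinder style SDF for a capsule polyline clipped flat at the far end
branch_sdf3 <- function(p, poly, r) {
  point_polyline_dist3(p, poly) - r
}

#' Generate a straight or toroidally curved vessel
#'
#' @param diameter Lumen diameter, mm.
#' @param length Centerline length, mm.
#' @param curvature_radius Optional centerline curvature radius, mm;
#'   `NULL` gives a straight tube along +x.
#' @param cell Surface extraction cell size, mm (default `diameter / 12`).
#' @param build_surface Extract the triangulated surface (default `TRUE`).
#' @return A `vessel_geometry` with analytic centerline, signed-distance
#'   functions (3D and in-plane 2D slice), labeled caps, and (optionally)
#'   a watertight surface.
#' @export
make_straight_vessel <- function(diameter, length, curvature_radius = NULL,
                                 cell = diameter / 12, build_surface = TRUE) {
  stopifnot(diameter > 0, length > 0)
  r <- diameter / 2
  if (is.null(curvature_radius)) {
    centerline <- cbind(c(0, length), c(0, 0), c(0, 0))
    sdf3 <- function(p) {
      rad <- sqrt(p[, 2]^2 + p[, 3]^2) - r
      pmax(rad, -p[, 1], p[, 1] - length)
    }
    sdf2 <- function(x, y) pmax(abs(y) - r, -x, x - length)
    caps <- list(
      list(name = "inlet", type = "inlet", point = c(0, 0, 0),
           normal = c(-1, 0, 0), diameter = diameter),
      list(name = "outlet", type = "outlet", point = c(length, 0, 0),
           normal = c(1, 0, 0), diameter = diameter))
    cap_edges2 <- list(list(name = "inlet", type = "inlet", edge = "xmin",
                            range = c(-r, r)),
                       list(name = "outlet", type = "outlet", edge = "xmax",
                            range = c(-r, r)))
    bbox2 <- rbind(c(0, -r), c(length, r))
    bbox3 <- rbind(c(0, -r, -r), c(length, r, r))
  } else {
    if (curvature_radius < diameter)
      stop("curvature_radius must be at least the vessel diameter")
    Rc <- curvature_radius
    phi <- length / Rc
    tt <- seq(0, phi, length.out = 200)
    centerline <- cbind(Rc * sin(tt), Rc * (1 - cos(tt)), 0 * tt)
    e0 <- centerline[1, ]; t0 <- c(1, 0, 0)
    e1 <- centerline[nrow(centerline), ]
    t1 <- c(cos(phi), sin(phi), 0)
    cl <- centerline
    sdf3 <- function(p) {
      d <- point_polyline_dist3(p, cl) - r
      pmax(d, -(p %*% t0 - sum(e0 * t0)), (p %*% t1 - sum(e1 * t1)))
    }
    sdf2 <- function(x, y) {
      d <- sqrt((x - 0)^2 + (y - Rc)^2)      # distance from arc center
      band <- abs(d - Rc) - r
      a0 <- atan2(x, Rc - y)                  # angle along the arc
      pmax(band, -a0 * Rc, (a0 - phi) * Rc)
    }
    caps <- list(
      list(name = "inlet", type = "inlet", point = e0, normal = -t0,
           diameter = diameter),
      list(name = "outlet", type = "outlet", point = e1, normal = t1,
           diameter = diameter))
    cap_edges2 <- NULL
    pad <- r + cell
    bbox3 <- rbind(apply(centerline, 2, min) - pad,
                   apply(centerline, 2, max) + pad)
    bbox2 <- bbox3[, 1:2]
  }
  geom <- structure(list(
    surface = NULL, caps = caps, dome = NULL, dome_label = integer(0),
    centerlines = list(list(name = "vessel", points = centerline,
                            diameter = diameter)),
    branch_diameters = c(vessel = diameter),
    sdf3 = sdf3, sdf2 = sdf2, bbox2 = bbox2, bbox3 = bbox3,
    cap_edges2 = cap_edges2, neck_segment2 = NULL,
    source = "synthetic"), class = "vessel_geometry")
  if (build_surface) geom$surface <- extract_surface(geom, cell)
  geom
}

# Daughter branch centerline: straight take-off at `angle` degrees from the
# parent (+y) axis, a circular bend to the horizontal, then straight until
# it reaches |x| = x_end (common outflow plane).
daughter_centerline <- function(angle_deg, diameter, length_factor) {
  th <- angle_deg * pi / 180
  dirv <- c(sin(th), cos(th))                  # direction, angle from +y axis
  sgn <- sign(sin(th)); if (sgn == 0) sgn <- 1
  total <- length_factor * diameter
  straight1 <- min(2 * diameter, 0.4 * total)
  Rb <- 2 * diameter
  p0 <- straight1 * dirv
  cen <- p0 + Rb * sgn * c(cos(th), -sin(th))  # bend center on the turn side
  aa <- seq(0, pi / 2 - abs(th), length.out = 24)
  a <- th + sgn * aa
  pts <- cbind(cen[1] - Rb * sgn * cos(a), cen[2] + Rb * sgn * sin(a))
  arc_len <- Rb * (pi / 2 - abs(th))
  tail_len <- max(total - straight1 - arc_len, 0.5 * diameter)
  pend <- pts[nrow(pts), ] + tail_len * c(sgn, 0)
  poly2 <- rbind(c(0, 0), p0, pts[-1, , drop = FALSE], pend)
  cbind(poly2, 0)
}

#' Generate a synthetic wide-necked bifurcation aneurysm
#'
#' Builds the idealized geometry as a smooth implicit union of the parent
#' vessel (along +y, inlet at the bottom), the daughter branches (which bend
#' to exit horizontally at a common outflow plane on each side), a spherical
#' dome over the bifurcation apex, and a cylindrical neck channel of the
#' requested neck diameter connecting apex and dome. The smooth-union radius
#' is 0.25 x neck diameter. Analytic centerlines, cap labels, the neck plane
#' position and the dome region are all carried on the returned object; the
#' in-plane (z = 0) signed-distance slice drives the 2D flow solver.
#'
#' @param spec A [bifurcation_spec()].
#' @param cell Surface extraction cell size, mm (default: smallest
#'   diameter / 10).
#' @param build_surface Extract the 3D triangulated surface (default TRUE;
#'   set FALSE for 2D-only studies).
#' @return A `vessel_geometry`.
#' @export
make_bifurcation_aneurysm <- function(spec,
                                      cell = min(spec$daughter_diameters) / 10,
                                      build_surface = TRUE) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  if (spec$neck_diameter > 1.5 * spec$parent_diameter)
    stop("neck wider than the bifurcation footprint")
  rp <- spec$parent_diameter / 2
  Lp <- spec$vessel_length_factor * spec$parent_diameter
  r_dome <- spec$dome_diameter / 2
  r_neck <- spec$neck_diameter / 2
  k_blend <- 0.25 * spec$neck_diameter

  branches <- lapply(seq_len(spec$n_daughters), function(i) {
    cl <- daughter_centerline(spec$daughter_angles[i],
                              spec$daughter_diameters[i],
                              spec$vessel_length_factor)
    list(name = sprintf("daughter_%d", i), points = cl,
         diameter = spec$daughter_diameters[i],
         side = if (sin(spec$daughter_angles[i] * pi / 180) < 0) "left" else "right")
  })
  x_end <- max(abs(vapply(branches, function(b) b$points[nrow(b$points), 1], 0)))
  # extend every daughter to the common outflow plane |x| = x_end
  branches <- lapply(branches, function(b) {
    pts <- b$points
    sgn <- if (b$side == "left") -1 else 1
    pts[nrow(pts), 1] <- sgn * x_end
    b$points <- pts
    b
  })

  # The dome center is lifted along the parent axis until the dome clears
  # every daughter lumen by a wall margin (blend radius + 0.5 mm), so that
  # the only fluid connection into the sac is the neck channel. The neck
  # plane also stays above the daughter lumen envelope on the axis.
  y_env <- max(vapply(seq_len(spec$n_daughters), function(i) {
    s <- abs(sin(spec$daughter_angles[i] * pi / 180))
    (spec$daughter_diameters[i] / 2) / max(s, 0.2)
  }, 0))
  half_h <- sqrt(max(r_dome^2 - r_neck^2, 0))
  y_c <- 1.15 * y_env + half_h
  repeat {
    clear <- vapply(branches, function(b) {
      min(point_polyline_dist2(0, y_c, b$points[, 1:2])) -
        (r_dome + b$diameter / 2 + k_blend + 0.5)
    }, 0)
    if (all(clear >= 0) || y_c > 10 * r_dome) break
    y_c <- y_c + 0.1
  }
  y_neck <- y_c - half_h
  y_top <- y_c + r_dome

  parent_cl <- cbind(c(0, 0), c(-Lp, 0), c(0, 0))

  # the cylindrical neck channel is redundant (and would inflate the dome
  # through the smooth union) when the dome sits directly on the neck plane
  use_neck_channel <- half_h > 0.1 * r_neck
  sdf3 <- function(p) {
    d <- branch_sdf3(p, parent_cl, rp)
    for (b in branches)
      d <- smooth_min(d, branch_sdf3(p, b$points, b$diameter / 2), k_blend)
    dome_d <- sqrt(p[, 1]^2 + (p[, 2] - y_c)^2 + p[, 3]^2) - r_dome
    if (use_neck_channel) {
      neck_d <- pmax(sqrt(p[, 1]^2 + p[, 3]^2) - r_neck, -p[, 2], p[, 2] - y_c)
      dome_d <- smooth_min(dome_d, neck_d, k_blend)
    }
    d <- smooth_min(d, dome_d, k_blend)
    # flat clips at inlet / outflow planes
    pmax(d, -(p[, 2] + Lp), abs(p[, 1]) - x_end)
  }
  sdf2 <- function(x, y) {
    d <- point_polyline_dist2(x, y, parent_cl[, 1:2]) - rp
    for (b in branches)
      d <- smooth_min(d, point_polyline_dist2(x, y, b$points[, 1:2]) -
                        b$diameter / 2, k_blend)
    dome_d <- sqrt(x^2 + (y - y_c)^2) - r_dome
    if (use_neck_channel) {
      neck_d <- pmax(abs(x) - r_neck, -y, y - y_c)
      dome_d <- smooth_min(dome_d, neck_d, k_blend)
    }
    d <- smooth_min(d, dome_d, k_blend)
    pmax(d, -(y + Lp), abs(x) - x_end)
  }

  caps <- c(list(list(name = "inlet", type = "inlet", point = c(0, -Lp, 0),
                      normal = c(0, -1, 0), diameter = spec$parent_diameter)),
            lapply(branches, function(b) {
              pe <- b$points[nrow(b$points), ]
              sgn <- if (b$side == "left") -1 else 1
              list(name = b$name, type = "outlet", point = pe,
                   normal = c(sgn, 0, 0), diameter = b$diameter)
            }))
  cap_edges2 <- c(list(list(name = "inlet", type = "inlet", edge = "ymin",
                            range = c(-rp, rp))),
                  lapply(branches, function(b) {
                    pe <- b$points[nrow(b$points), 1:2]
                    list(name = b$name, type = "outlet",
                         edge = if (b$side == "left") "xmin" else "xmax",
                         range = pe[2] + c(-1, 1) * b$diameter / 2)
                  }))

  bbox2 <- rbind(c(-x_end, -Lp), c(x_end, y_top + cell))
  bbox3 <- rbind(c(-x_end, -Lp, -max(rp, r_dome) - cell),
                 c(x_end, y_top + cell, max(rp, r_dome) + cell))

  geom <- structure(list(
    surface = NULL, caps = caps,
    dome = list(center = c(0, y_c, 0), radius = r_dome, axis = c(0, 1, 0),
                y_neck = y_neck, neck_diameter = spec$neck_diameter,
                y_top = y_top),
    dome_label = integer(0),
    centerlines = c(list(list(name = "parent", points = parent_cl,
                              diameter = spec$parent_diameter)),
                    lapply(branches, function(b) b[c("name", "points", "diameter")])),
    branch_diameters = stats::setNames(
      c(spec$parent_diameter, vapply(branches, `[[`, 0, "diameter")),
      c("parent", vapply(branches, `[[`, "", "name"))),
    sdf3 = sdf3, sdf2 = sdf2, bbox2 = bbox2, bbox3 = bbox3,
    cap_edges2 = cap_edges2,
    neck_segment2 = c(-r_neck, y_neck, r_neck, y_neck),
    spec = spec, source = "synthetic"), class = "vessel_geometry")
  if (build_surface) {
    geom$surface <- extract_surface(geom, cell)
    cen <- face_centroids(geom$surface)
    geom$dome_label <- which(in_dome_region(geom, cen))
  }
  geom
}

# Membership test for the aneurysm sac region (dome sphere plus the neck
# channel above the neck plane). `p` is n x 3 or n x 2 (z = 0 assumed).
in_dome_region <- function(geom, p, tol = 0.3) {
  dm <- geom$dome
  if (ncol(p) == 2) p <- cbind(p, 0)
  r2 <- p[, 1]^2 + p[, 3]^2
  above <- p[, 2] > dm$y_neck
  in_sphere <- r2 + (p[, 2] - dm$center[2])^2 < (dm$radius + tol)^2
  in_neck <- sqrt(r2) < dm$neck_diameter / 2 + tol
  above & (in_sphere | in_neck)
}

extract_surface <- function(geom, cell) {
  pad <- 2 * cell
  bb <- geom$bbox3
  bb[1, ] <- bb[1, ] - pad; bb[2, ] <- bb[2, ] + pad
  marching_tetrahedra(geom$sdf3, bb, cell)
}

face_centroids <- function(surface) {
  (surface$vertices[surface$faces[, 1], , drop = FALSE] +
     surface$vertices[surface$faces[, 2], , drop = FALSE] +
     surface$vertices[surface$faces[, 3], , drop = FALSE]) / 3
}

#' @export
print.vessel_geometry <- function(x, ...) {
  n_out <- sum(vapply(x$caps, function(cp) cp$type == "outlet", TRUE))
  cat(sprintf("<vessel_geometry> (%s) 1 inlet, %d outlet(s)%s\n", x$source,
              n_out, if (!is.null(x$dome)) ", aneurysm dome" else ""))
  if (!is.null(x$surface))
    cat(sprintf("  surface: %d triangles, volume %.1f mm^3\n",
                nrow(x$surface$faces), mesh_volume(x$surface)))
  invisible(x)
}

#' Define the aneurysm neck measurement plane
#'
#' Places the inflow-measurement plane at the dome/parent junction, offset
#' toward the dome. The plane should sit as close to the natural neck as
#' possible while staying clear of the device: if device node positions are
#' supplied and any strut lies within two wire diameters of the plane a
#' warning is emitted, since local vorticity at the struts contaminates the
#' flux there.
#'
#' @param geom An aneurysm `vessel_geometry`.
#' @param offset Offset toward the dome along the dome axis, mm.
#' @param device Optional `device_mesh` or node-position matrix to check
#'   for strut proximity.
#' @return An object of class `neck_plane` (point, unit normal, boundary
#'   polyline on the lumen surface).
#' @export
define_neck_plane <- function(geom, offset = 0, device = NULL) {
  if (is.null(geom$dome)) stop("geometry has no aneurysm dome label")
  dm <- geom$dome
  y <- dm$y_neck + offset
  if (offset < 0 || y >= dm$y_top)
    stop("offset places the plane outside the dome (degenerate)")
  rho <- if (y <= dm$center[2]) dm$neck_diameter / 2 else
    sqrt(max(dm$radius^2 - (y - dm$center[2])^2, 0))
  ang <- seq(0, 2 * pi, length.out = 65)
  boundary <- cbind(rho * cos(ang), y, rho * sin(ang))
  if (!is.null(device)) {
    nodes <- if (inherits(device, "device_mesh")) device$nodes else device
    w_mm <- if (inherits(device, "device_mesh")) device$wire_diameter / 1000 else 0.03
    if (any(abs(nodes[, 2] - y) < 2 * w_mm))
      warning("device struts lie within 2 wire diameters of the neck plane")
  }
  structure(list(point = c(0, y, 0), normal = dm$axis,
                 boundary = boundary, radius = rho), class = "neck_plane")
}

#' @export
print.neck_plane <- function(x, ...) {
  cat(sprintf("<neck_plane> at (%.2f, %.2f, %.2f), normal (%g, %g, %g), radius %.2f mm\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3], x$radius))
  invisible(x)
}

# Volume of the aneurysm dome region (above the neck plane), by voxel
# integration of the implicit lumen.
dome_volume <- function(geom, cell = 0.15) {
  stopifnot(!is.null(geom$dome))
  dm <- geom$dome
  xs <- seq(-dm$radius, dm$radius, by = cell)
  ys <- seq(dm$y_neck, dm$y_top + cell, by = cell)
  zs <- xs
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  inside <- geom$sdf3(pts) < 0
  sum(inside) * cell^3
}
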