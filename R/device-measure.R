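# Unrolled strut segments of a device on its current cylinder.
# Returns a matrix with columns s1, z1, s2, z2 in mm; the circumferential
# coordinate s = R * theta lives on [0, W) with W = pi * current_diameter,
# and each strut is wrapped to its shortest circumferential representation.
unroll_struts <- function(mesh) {
  R <- mesh$current_diameter / 2
  W <- 2 * pi * R
  th <- mesh$node_theta %% (2 * pi)
  s <- R * th
  s1 <- s[mesh$struts[, 1]]; s2 <- s[mesh$struts[, 2]]
  z1 <- mesh$node_z[mesh$struts[, 1]]; z2 <- mesh$node_z[mesh$struts[, 2]]
  ds <- s2 - s1
  ds <- ds - W * round(ds / W)
  cbind(s1 = s1, z1 = z1, s2 = s1 + ds, z2 = z2)
}

# Mark pixels covered by struts widened to `width` on a raster of pixel size
# `px` over window [0,W] x [zlim]. Struts are drawn at s-offsets -W, 0, +W so
# that the circumferential seam is handled.
rasterize_struts <- function(segs, W, zlim, px, width) {
  nx <- max(2L, ceiling(W / px))
  ny <- max(2L, ceiling(diff(zlim) / px))
  covered <- matrix(FALSE, nx, ny)
  if (width <= 0) return(covered)
  r <- width / 2
  xs0 <- (seq_len(nx) - 0.5) * px
  ys0 <- zlim[1] + (seq_len(ny) - 0.5) * px
  for (shift in c(-W, 0, W)) {
    a1 <- segs[, "s1"] + shift; a2 <- segs[, "s2"] + shift
    b1 <- segs[, "z1"]; b2 <- segs[, "z2"]
    xmin <- pmin(a1, a2) - r; xmax <- pmax(a1, a2) + r
    ymin <- pmin(b1, b2) - r; ymax <- pmax(b1, b2) + r
    keep <- which(xmax > 0 & xmin < W & ymax > zlim[1] & ymin < zlim[2])
    for (si in keep) {
      i0 <- max(1L, floor(xmin[si] / px)); i1 <- min(nx, ceiling(xmax[si] / px))
      j0 <- max(1L, floor((ymin[si] - zlim[1]) / px))
      j1 <- min(ny, ceiling((ymax[si] - zlim[1]) / px))
      if (i0 > i1 || j0 > j1) next
      ii <- i0:i1; jj <- j0:j1
      pxs <- rep(xs0[ii], times = length(jj))
      pys <- rep(ys0[jj], each = length(ii))
      d <- point_seg_dist2(pxs, pys, a1[si], b1[si], a2[si], b2[si])
      hit <- d <= r
      if (any(hit)) {
        im <- rep(ii, times = length(jj))[hit]
        jm <- rep(jj, each = length(ii))[hit]
        covered[cbind(im, jm)] <- TRUE
      }
    }
  }
  covered
}

#' Measure device surface porosity by strut rasterization
#'
#' Unrolls the braid onto its cylindrical envelope, widens every strut
#' centerline to the wire diameter, rasterizes the result on a deterministic
#' pixel grid and reports the uncovered area fraction. This is the
#' definition of device porosity used throughout: one minus the projected
#' metal coverage of the envelope surface.
#'
#' @param mesh A `device_mesh`.
#' @param px_per_wire Raster resolution, pixels across the wire width
#'   (minimum 8; the default).
#' @param axial_window Optional `c(z0, z1)` (mm) restricting the measurement
#'   to an axial band; `NULL` (default) measures the full device length.
#' @return Porosity as a fraction in [0, 1].
#' @export
measure_porosity <- function(mesh, px_per_wire = 8, axial_window = NULL) {
  stopifnot(inherits(mesh, "device_mesh"))
  if (px_per_wire < 8) stop("px_per_wire must be >= 8")
  if (mesh$current_diameter <= 0 || mesh$current_length <= 0)
    stop("degenerate cylinder: zero diameter or length")
  w <- mesh$wire_diameter / 1000
  if (w == 0) return(1.0)
  W <- pi * mesh$current_diameter
  zlim <- axial_window %||% c(0, mesh$current_length)
  px <- w / px_per_wire
  segs <- unroll_struts(mesh)
  covered <- rasterize_struts(segs, W, zlim, px, w)
  1 - mean(covered)
}

#' Measure the braid pore diameter
#'
#' Rasterizes a window of the unrolled braid with struts widened to the wire
#' diameter, labels the open (non-metal) cells, and computes for each closed
#' cell the diameter of the largest inscribed disk via a distance transform.
#' Reports the median over the cells fully contained in the window.
#'
#' @param mesh A `device_mesh`.
#' @param px_per_wire Raster resolution in pixels per wire width (>= 8).
#' @return Median inscribed pore diameter in micrometres.
#' @export
measure_pore_diameter <- function(mesh, px_per_wire = 8) {
  stopifnot(inherits(mesh, "device_mesh"))
  w <- mesh$wire_diameter / 1000
  W <- pi * mesh$current_diameter
  m <- mesh$n_strands / 2
  cospsi <- mesh$current_length /
    sqrt(mesh$current_length^2 + (mesh$strand_turns * pi * mesh$current_diameter)^2)
  s_perp <- W * cospsi / m           # perpendicular strand spacing, mm
  cell <- s_perp / max(cospsi, 0.2)  # rough cell extent
  half <- 3.5 * cell
  zc <- mesh$current_length / 2
  zlim <- c(max(0, zc - half), min(mesh$current_length, zc + half))
  width <- max(w, 1e-4)
  px <- width / max(px_per_wire, 8)
  segs <- unroll_struts(mesh)
  covered <- rasterize_struts(segs, min(W, 2 * half), zlim, px, width)
  open <- !covered
  labels <- EBImage::bwlabel(open * 1)
  if (max(labels) == 0) stop("no closed cells in braid window")
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  interior <- setdiff(seq_len(max(labels)), c(0, border))
  if (length(interior) == 0)
    stop("no closed cells: too few strands or turns to form pores")
  dist <- EBImage::distmap(open * 1)
  pores <- vapply(interior, function(lb) 2 * max(dist[labels == lb]) * px, 0)
  stats::median(pores) * 1000
}

#' Sweep struts into a triangulated tube surface
#'
#' Restores the physical wire thickness by sweeping a circular cross-section
#' of the wire diameter along every strut centerline. Each strut becomes a
#' capped prism with `n_sides` facets; the union is returned as a triangle
#' soup suitable for STL export and visualization.
#'
#' @param mesh A `device_mesh` (reference, crimped or deployed positions).
#' @param n_sides Facets around each strut tube.
#' @param nodes Optional replacement node positions (e.g. deployed).
#' @return A `surface_mesh` (list of `vertices` n x 3 mm and `faces` m x 3).
#' @export
sweep_struts <- function(mesh, n_sides = 8L, nodes = NULL) {
  stopifnot(inherits(mesh, "device_mesh"))
  P <- nodes %||% mesh$nodes
  r <- mesh$wire_diameter / 2000          # wire radius in mm
  a <- P[mesh$struts[, 1], , drop = FALSE]
  b <- P[mesh$struts[, 2], , drop = FALSE]
  ax <- normalize_rows(b - a)
  ref <- matrix(rep(c(0, 0, 1), each = nrow(ax)), ncol = 3)
  flip <- abs(ax[, 3]) > 0.9
  ref[flip, ] <- matrix(rep(c(1, 0, 0), each = sum(flip)), ncol = 3)
  n1 <- normalize_rows(cross3(ax, ref))
  n2 <- cross3(ax, n1)
  ns <- nrow(a)
  ang <- 2 * pi * (0:(n_sides - 1L)) / n_sides
  verts <- vector("list", 2L * n_sides + 2L)
  for (s in seq_len(n_sides)) {
    off <- r * (cos(ang[s]) * n1 + sin(ang[s]) * n2)
    verts[[s]] <- a + off
    verts[[n_sides + s]] <- b + off
  }
  verts[[2L * n_sides + 1L]] <- a
  verts[[2L * n_sides + 2L]] <- b
  V <- do.call(rbind, verts)   # blocks of ns rows per logical vertex
  idx <- function(block, strut) (block - 1L) * ns + strut
  strut_i <- seq_len(ns)
  faces <- vector("list", n_sides)
  for (s in seq_len(n_sides)) {
    sn <- if (s == n_sides) 1L else s + 1L
    a1 <- idx(s, strut_i); a2 <- idx(sn, strut_i)
    b1 <- idx(n_sides + s, strut_i); b2 <- idx(n_sides + sn, strut_i)
    ca <- idx(2L * n_sides + 1L, strut_i); cb <- idx(2L * n_sides + 2L, strut_i)
    faces[[s]] <- rbind(cbind(a1, b1, a2), cbind(a2, b1, b2),
                        cbind(ca, a2, a1), cbind(cb, b1, b2))
  }
  F <- do.call(rbind, faces)
  structure(list(vertices = V, faces = F), class = "surface_mesh")
}
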