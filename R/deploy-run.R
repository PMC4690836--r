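#' Plan the distal-to-proximal release schedule
#'
#' Bins device nodes by axial coordinate into ordered bands, the first band
#' being the distal tip (largest axial coordinate; distal = downstream
#' along the stented branch by convention). Releasing the bands in order
#' mimics gradual unsheathing of the device from its delivery catheter.
#'
#' @param mesh A `device_mesh`.
#' @param n_bands Number of release bands (>= 1).
#' @param iteration_quantum Relaxation iterations granted to each band
#'   before the next is released regardless of residual.
#' @return A `release_schedule` (list of node-index bands).
#' @export
plan_release_schedule <- function(mesh, n_bands = 10L,
                                  iteration_quantum = 20L) {
  n <- nrow(mesh$nodes)
  if (n_bands < 1L) stop("n_bands must be >= 1")
  if (n_bands > n) stop("more release bands than device nodes")
  ord <- order(mesh$node_z, decreasing = TRUE)    # distal tip first
  band_of <- ceiling(seq_along(ord) * n_bands / n)
  bands <- split(ord, band_of)
  structure(list(bands = unname(bands), n_bands = as.integer(n_bands),
                 iteration_quantum = as.integer(iteration_quantum)),
            class = "release_schedule")
}

# Map device-local coordinates (x, y, z axial) onto a centerline with
# parallel-transport frames. `advance` positions the device midpoint at
# that arc length along the centerline.
align_to_centerline <- function(local, device_length, centerline, advance) {
  seg <- centerline[-1, , drop = FALSE] - centerline[-nrow(centerline), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  cs <- c(0, cumsum(len))
  total <- cs[length(cs)]
  if (device_length > total)
    stop("device longer than the available branch centerline")
  advance <- advance %||% (total / 2)
  s0 <- min(max(advance - device_length / 2, 0), total - device_length)
  # parallel-transport frames at the polyline vertices
  Tm <- normalize_rows(rbind(seg, seg[nrow(seg), , drop = FALSE]))
  N1 <- matrix(0, nrow(Tm), 3L)
  ref <- if (abs(Tm[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  N1[1, ] <- normalize_rows(cross3(matrix(Tm[1, ], 1), matrix(ref, 1)))
  for (k in 2:nrow(Tm)) {
    v <- N1[k - 1L, ] - sum(N1[k - 1L, ] * Tm[k, ]) * Tm[k, ]
    nv <- sqrt(sum(v * v))
    N1[k, ] <- if (nv > 1e-9) v / nv else N1[k - 1L, ]
  }
  N2 <- cross3(Tm, N1)
  s <- s0 + local[, 3]
  idx <- pmin(pmax(findInterval(s, cs, rightmost.closed = TRUE), 1L),
              nrow(centerline) - 1L)
  f <- (s - cs[idx]) / pmax(len[idx], 1e-12)
  base <- centerline[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * f
  base + N1[idx, , drop = FALSE] * local[, 1] + N2[idx, , drop = FALSE] * local[, 2]
}

#' Deploy a crimped device inside a vessel lumen
#'
#' The crimped spring network is aligned to the target centerline (bent
#' along it with parallel-transport frames and advanced so the device
#' midpoint sits at `advance`, e.g. under the aneurysm neck), then relaxed
#' by damped pseudo-dynamic iteration: nodes move along the net spring
#' force, scaled per node by its incident stiffness; the step factor is
#' halved whenever total spring energy increases. Release proceeds
#' distal-to-proximal per the schedule. A node that comes within a wire
#' radius of the lumen wall is projected onto the wall offset and
#' permanently fixed (no-slip wall contact).
#'
#' @param network A [build_spring_network()] of the crimped device.
#' @param geom A `vessel_geometry` with an implicit `sdf3`.
#' @param schedule A [plan_release_schedule()]; default 10 bands.
#' @param centerline Target centerline (n x 3 mm); default: the geometry's
#'   first branch.
#' @param advance Arc length of the device midpoint along the centerline.
#' @param tol_mm Convergence tolerance on the per-iteration maximum node
#'   displacement (default 0.1 x wire diameter).
#' @param max_iters Iteration cap; non-convergence returns
#'   `converged = FALSE` rather than an error.
#' @param eta Initial step factor.
#' @param momentum Heavy-ball momentum on the relaxation steps (0 recovers
#'   plain damped gradient iteration).
#' @param pre_expand Initialize at the inextensional-helix family member
#'   that just fits the local lumen (radius clamped to the centerline
#'   clearance), instead of the crimped diameter. This removes the slow
#'   collective pitch/untwist mode from the iteration; the relaxation then
#'   resolves local adaptation (bends, tapers, wall contact).
#' @return A `deployed_device`: final node positions, contact flags,
#'   residual history, energy history, convergence flag, and the network.
#' @export
deploy <- function(network, geom, schedule = NULL, centerline = NULL,
                   advance = NULL, tol_mm = NULL, max_iters = 2000L,
                   eta = 0.5, momentum = 0.9, pre_expand = TRUE) {
  stopifnot(inherits(network, "spring_network"))
  if (is.null(geom$sdf3)) stop("geometry has no implicit surface for contact")
  mesh <- network$mesh
  schedule <- schedule %||% plan_release_schedule(mesh)
  centerline <- centerline %||% geom$centerlines[[1]]$points
  tol_mm <- tol_mm %||% (0.1 * mesh$wire_diameter / 1000)
  r_w <- network$wire_radius_mm

  local <- cbind(mesh$nodes[, 1], mesh$nodes[, 2], mesh$node_z)
  dev_len <- mesh$current_length
  if (pre_expand) {
    # clearance of the lumen along the device span of the centerline
    cs <- c(0, cumsum(sqrt(rowSums((centerline[-1, , drop = FALSE] -
              centerline[-nrow(centerline), , drop = FALSE])^2))))
    total <- cs[length(cs)]
    adv0 <- advance %||% (total / 2)
    # clearance over the span the expanded device will occupy
    span <- seq(max(adv0 - mesh$reference_length / 2, 0),
                min(adv0 + mesh$reference_length / 2, total), length.out = 25)
    cl_pts <- do.call(rbind, lapply(span, function(s)
      polyline_point_at(centerline, s)$point))
    clear <- -geom$sdf3(cl_pts)
    D_fit <- 2 * (min(clear) - r_w) * 0.995
    D0 <- mesh$reference_diameter
    D_init <- max(min(D0, D_fit), mesh$current_diameter)
    Nt <- mesh$strand_turns
    S <- sqrt(mesh$reference_length^2 + (pi * D0 * Nt)^2)
    L_init <- sqrt(max(S^2 - (pi * D_init * Nt)^2, (0.3 * mesh$reference_length)^2))
    scale_r <- D_init / mesh$current_diameter
    scale_z <- L_init / mesh$current_length
    local <- cbind(local[, 1] * scale_r, local[, 2] * scale_r,
                   local[, 3] * scale_z)
    dev_len <- L_init
  }
  X <- align_to_centerline(local, dev_len, centerline, advance)
  # rest configuration mapped the same way (for the free-expansion target
  # the springs already encode it; alignment only sets the start state)
  n <- nrow(X)
  released <- logical(n); fixed <- logical(n)
  sdf_grad <- function(P) {
    e <- 0.05
    gx <- geom$sdf3(cbind(P[, 1] + e, P[, 2], P[, 3])) -
      geom$sdf3(cbind(P[, 1] - e, P[, 2], P[, 3]))
    gy <- geom$sdf3(cbind(P[, 1], P[, 2] + e, P[, 3])) -
      geom$sdf3(cbind(P[, 1], P[, 2] - e, P[, 3]))
    gz <- geom$sdf3(cbind(P[, 1], P[, 2], P[, 3] + e)) -
      geom$sdf3(cbind(P[, 1], P[, 2], P[, 3] - e))
    normalize_rows(cbind(gx, gy, gz))
  }

  # Jacobi projection of strand-length (inextensibility) constraints.
  li <- network$lin$i; lj <- network$lin$j; L0 <- network$lin$L0
  project_lengths <- function(X, movable, sweeps = 4L, omega = 0.9) {
    for (s in seq_len(sweeps)) {
      d <- X[lj, , drop = FALSE] - X[li, , drop = FALSE]
      L <- pmax(row_norm(d), 1e-12)
      err <- (L - L0) / L
      mi <- movable[li]; mj <- movable[lj]
      wsum <- mi + mj
      ok <- wsum > 0
      corr <- d * err
      ci <- corr * (mi / pmax(wsum, 1)) * ok
      cj <- -corr * (mj / pmax(wsum, 1)) * ok
      acc <- accumulate_rows(matrix(0, n, 3L), li, ci)
      acc <- accumulate_rows(acc, lj, cj)
      cnt <- tabulate(li, nbins = n) + tabulate(lj, nbins = n)
      X <- X + omega * acc / pmax(cnt, 1L)
    }
    X
  }

  band <- 1L
  released[schedule$bands[[1L]]] <- TRUE
  band_iters <- 0L
  eta0 <- eta
  V <- matrix(0, n, 3L)
  energies <- spring_energy(network, X)
  residuals <- numeric(0)
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L; band_iters <- band_iters + 1L
    F <- spring_forces(network, X)
    move <- released & !fixed
    V <- momentum * V
    V[move, ] <- V[move, , drop = FALSE] +
      eta * F[move, , drop = FALSE] / network$knorm[move]
    V[!move, ] <- 0
    X_new <- project_lengths(X + V, move)
    res <- max(abs(X_new - X))
    # wall contact: project offending nodes to the wire-radius offset
    mv <- which(move)
    if (length(mv)) {
      sd <- geom$sdf3(X_new[mv, , drop = FALSE])
      hit <- sd > -r_w
      if (any(hit)) {
        hv <- mv[hit]
        g <- sdf_grad(X_new[hv, , drop = FALSE])
        X_new[hv, ] <- X_new[hv, , drop = FALSE] -
          (sd[hit] + r_w) * g
        fixed[hv] <- TRUE
        V[hv, ] <- 0
      }
    }
    X <- X_new
    e_new <- spring_energy(network, X)
    energies <- c(energies, e_new)
    # damp harder when the energy trend turns upward
    lag <- min(20L, length(energies) - 1L)
    if (lag >= 5L && e_new > energies[length(energies) - lag]) {
      eta <- max(eta * 0.6, 0.02)
      V[] <- 0
    } else {
      eta <- min(eta * 1.02, eta0)
    }
    residuals <- c(residuals, res)
    all_released <- band >= length(schedule$bands)
    if (!all_released &&
        (res < 10 * tol_mm || band_iters >= schedule$iteration_quantum)) {
      band <- band + 1L
      released[schedule$bands[[band]]] <- TRUE
      band_iters <- 0L
    } else if (all_released && res < tol_mm) {
      break
    }
  }
  converged <- band >= length(schedule$bands) &&
    length(residuals) > 0 && utils::tail(residuals, 1) < tol_mm
  structure(list(nodes = X, contact_flags = fixed,
                 iterations_used = it, residual = residuals,
                 energy = energies, converged = converged,
                 network = network, geom = geom,
                 tol_mm = tol_mm), class = "deployed_device")
}

#' @export
print.deployed_device <- function(x, ...) {
  cat(sprintf("<deployed_device> %d nodes, %d in wall contact, %d iterations, converged: %s\n",
              nrow(x$nodes), sum(x$contact_flags), x$iterations_used,
              x$converged))
  invisible(x)
}

#' Wall apposition statistics of a deployed device
#'
#' Per-node gap between the strut surface (node position plus wire radius)
#' and the lumen wall, summarized as max, mean and the malapposed fraction
#' (gap > 0.1 mm).
#'
#' @param deployed A `deployed_device`.
#' @param geom Vessel geometry (default: the one deployed into).
#' @return List with `gap` (per node, mm), `max`, `mean`, `fraction_over_0.1mm`.
#' @export
apposition <- function(deployed, geom = deployed$geom) {
  gap <- -geom$sdf3(deployed$nodes) - deployed$network$wire_radius_mm
  gap <- pmax(gap, 0)
  list(gap = gap, max = max(gap), mean = mean(gap),
       fraction_over_0.1mm = mean(gap > 0.1))
}

#' Local metal coverage over the neck plane
#'
#' Projects the struts near the neck plane onto it (widened to the wire
#' diameter) and reports the covered fraction of the neck disk by
#' rasterization; one minus this is the local porosity that parameterizes
#' the flow screen.
#'
#' @param deployed A `deployed_device` (or `device_mesh` with positions).
#' @param neck A [define_neck_plane()] object.
#' @param slab Half-thickness of the strut selection slab, mm (default 3x
#'   wire diameter + 0.2).
#' @param side `"near"` keeps only struts on the dome-facing side of the
#'   device axis; `"slab"` keeps all struts within the slab.
#' @param px_per_wire Raster resolution.
#' @return Covered fraction of the neck disk.
#' @export
local_metal_coverage <- function(deployed, neck, slab = NULL,
                                 side = c("slab", "near"), px_per_wire = 8) {
  side <- match.arg(side)
  if (inherits(deployed, "deployed_device")) {
    P <- deployed$nodes; mesh <- deployed$network$mesh
  } else {
    P <- deployed$nodes; mesh <- deployed
  }
  w_mm <- mesh$wire_diameter / 1000
  slab <- slab %||% (3 * w_mm + 0.2)
  nrm <- neck$normal / sqrt(sum(neck$normal^2))
  dist <- as.vector(sweep(P, 2, neck$point) %*% nrm)
  keep_node <- abs(dist) <= slab
  if (side == "near") keep_node <- keep_node | (dist > 0 & abs(dist) <= 2 * slab)
  ks <- keep_node[mesh$struts[, 1]] & keep_node[mesh$struts[, 2]]
  if (!any(ks)) stop("no device struts intersect the neck region")
  st <- mesh$struts[ks, , drop = FALSE]
  # in-plane basis
  ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- cross3(matrix(nrm, 1), matrix(ref, 1)); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(matrix(nrm, 1), e1)
  proj <- function(idx) {
    q <- sweep(P[idx, , drop = FALSE], 2, neck$point)
    cbind(as.vector(q %*% t(e1)), as.vector(q %*% t(e2)))
  }
  a <- proj(st[, 1]); b <- proj(st[, 2])
  R <- neck$radius
  px <- max(w_mm, 1e-3) / px_per_wire
  ng <- ceiling(2 * R / px)
  xs <- seq(-R, R, length.out = ng)
  covered <- matrix(FALSE, ng, ng)
  rad <- w_mm / 2
  for (s in seq_len(nrow(a))) {
    x0 <- min(a[s, 1], b[s, 1]) - rad; x1 <- max(a[s, 1], b[s, 1]) + rad
    y0 <- min(a[s, 2], b[s, 2]) - rad; y1 <- max(a[s, 2], b[s, 2]) + rad
    i0 <- max(1L, findInterval(x0, xs)); i1 <- min(ng, findInterval(x1, xs) + 1L)
    j0 <- max(1L, findInterval(y0, xs)); j1 <- min(ng, findInterval(y1, xs) + 1L)
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    pxv <- rep(xs[ii], times = length(jj)); pyv <- rep(xs[jj], each = length(ii))
    dseg <- point_seg_dist2(pxv, pyv, a[s, 1], a[s, 2], b[s, 1], b[s, 2])
    hit <- dseg <= rad
    if (any(hit))
      covered[cbind(rep(ii, times = length(jj))[hit],
                    rep(jj, each = length(ii))[hit])] <- TRUE
  }
  in_disk <- outer(xs, xs, function(px_, py_) px_^2 + py_^2 <= R^2)
  sum(covered & in_disk) / sum(in_disk)
}
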