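# Coarse-3D companion solver.
#
# Same incremental projection scheme as the 2D slice solver on a staggered
# (MAC) grid, kept deliberately compact for the coarse grids (<= ~200k
# cells) used at desk scale: first-order upwind advection, explicit
# diffusion under CFL substepping, exact sparse-Cholesky projection.
# Patient-scale body-fitted meshes are out of scope.

rasterize_domain_3d <- function(geom, resolution, dt, n_cycles,
                                outlet_pressures, outlet_resistances) {
  if (is.null(geom$sdf3)) stop("geometry has no 3D SDF")
  dmin <- min(geom$branch_diameters)
  h_mm <- dmin / resolution
  bb <- geom$bbox3
  nd <- pmax(4L, floor((bb[2, ] - bb[1, ]) / h_mm))
  nx <- nd[1]; ny <- nd[2]; nz <- nd[3]
  if (nx * ny * nz > 5e6) stop("3D grid too large; lower the resolution")
  xs <- bb[1, 1] + (seq_len(nx) - 0.5) * h_mm
  ys <- bb[1, 2] + (seq_len(ny) - 0.5) * h_mm
  zs <- bb[1, 3] + (seq_len(nz) - 0.5) * h_mm
  pts <- cbind(rep(xs, times = ny * nz),
               rep(rep(ys, each = nx), times = nz),
               rep(zs, each = nx * ny))
  fluid <- array(geom$sdf3(pts) < 0, dim = c(nx, ny, nz))

  # caps from the 3D cap metadata: each cap lies on a bbox face
  caps <- lapply(geom$caps, function(cp) {
    n <- cp$normal
    ax <- which.max(abs(n))
    lohi <- if (n[ax] < 0) 1L else c(nx, ny, nz)[ax]
    sl <- switch(ax, fluid[lohi, , ], fluid[, lohi, ], fluid[, , lohi])
    cen <- cp$point[-ax]
    cc <- switch(ax, expand.grid(a = ys, b = zs), expand.grid(a = xs, b = zs),
                 expand.grid(a = xs, b = ys))
    ok <- matrix((cc$a - cen[1])^2 + (cc$b - cen[2])^2 <=
                   (cp$diameter / 2 + h_mm)^2, nrow(sl), ncol(sl)) & sl
    list(name = cp$name, type = cp$type, axis = ax,
         side = if (n[ax] < 0) "lo" else "hi", mask = ok,
         center = cen, diameter = cp$diameter)
  })
  types <- vapply(caps, `[[`, "", "type")
  inlet <- caps[[which(types == "inlet")[1]]]
  outlets <- caps[types == "outlet"]
  op <- rep(0, length(outlets))
  if (!is.null(outlet_pressures)) op[seq_along(outlet_pressures)] <- outlet_pressures
  for (i in seq_along(outlets)) {
    outlets[[i]]$pressure <- op[i]
    outlets[[i]]$resistance <- 0
  }
  structure(list(mode = "3D", h = h_mm * 1e-3, h_mm = h_mm,
                 nx = nx, ny = ny, nz = nz, xs = xs, ys = ys, zs = zs,
                 fluid = fluid, n_fluid = sum(fluid),
                 inlet = inlet, outlets = outlets, screens = list(),
                 dt = dt, n_cycles = n_cycles, geom = geom),
            class = "flow_problem")
}

# shift an array by one cell along an axis, zero-filling
shift3 <- function(a, ax, by) {
  d <- dim(a); out <- array(0, d)
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  if (by > 0) { src[[ax]] <- 1:(d[ax] - 1); dst[[ax]] <- 2:d[ax] }
  else { src[[ax]] <- 2:d[ax]; dst[[ax]] <- 1:(d[ax] - 1) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

solve_flow3d <- function(problem, waveform, props, steady = TRUE,
                         n_cycles = NULL, dt = NULL, max_time = 3,
                         steady_tol = 5e-4, verbose = FALSE) {
  if (!steady) stop("the coarse 3D solver supports steady (mean-flow) mode")
  h <- problem$h; rho <- props$density
  nu_visc <- props$dynamic_viscosity / rho
  nx <- problem$nx; ny <- problem$ny; nz <- problem$nz
  fluid <- problem$fluid
  D_in <- problem$inlet$diameter
  U <- (waveform$mean_flow / 6e7) / (pi * (D_in / 1000)^2 / 4)
  dt_sub <- 0.7 * h / (1.5 * 1.3 * U)
  dt_sub <- min(dt_sub, 0.2 * h^2 / nu_visc)

  # velocity faces: active if both flanking cells are fluid; cap faces extra
  facemask <- function(ax) {
    dpad <- c(nx, ny, nz); dpad[ax] <- dpad[ax] + 1L
    act <- array(FALSE, dpad)
    idx <- lapply(c(nx, ny, nz), seq_len)
    lo <- idx; lo[[ax]] <- 1:(dpad[ax] - 2L)
    hi <- idx; hi[[ax]] <- 2:(dpad[ax] - 1L)
    inner <- fluid[lo[[1]], lo[[2]], lo[[3]]] & fluid[hi[[1]], hi[[2]], hi[[3]]]
    ii <- idx; ii[[ax]] <- 2:(dpad[ax] - 1L)
    act[ii[[1]], ii[[2]], ii[[3]]] <- inner
    act
  }
  UA <- facemask(1L); VA <- facemask(2L); WA <- facemask(3L)
  set_cap_faces <- function(cap, arr, value_mask_only = FALSE) {
    ax <- cap$axis
    pos <- if (cap$side == "lo") 1L else dim(arr)[ax]
    sl <- switch(ax, arr[pos, , ], arr[, pos, ], arr[, , pos])
    sl[cap$mask] <- TRUE
    switch(ax, arr[pos, , ] <- sl, arr[, pos, ] <- sl, arr[, , pos] <- sl)
    arr
  }
  for (o in problem$outlets) {
    if (o$axis == 1L) UA <- set_cap_faces(o, UA)
    if (o$axis == 2L) VA <- set_cap_faces(o, VA)
    if (o$axis == 3L) WA <- set_cap_faces(o, WA)
  }
  inlet <- problem$inlet
  if (inlet$axis == 1L) UA <- set_cap_faces(inlet, UA)
  if (inlet$axis == 2L) VA <- set_cap_faces(inlet, VA)
  if (inlet$axis == 3L) WA <- set_cap_faces(inlet, WA)

  # Poisson over fluid cells
  cid <- array(0L, c(nx, ny, nz)); cid[fluid] <- seq_len(sum(fluid))
  nf <- sum(fluid)
  w3 <- which(fluid, arr.ind = TRUE)
  ti <- integer(0); tj <- integer(0)
  dg <- numeric(nf)
  for (ax in 1:3) for (sgn in c(-1L, 1L)) {
    nb <- w3; nb[, ax] <- nb[, ax] + sgn
    ok <- nb[, ax] >= 1L & nb[, ax] <= c(nx, ny, nz)[ax]
    ok[ok] <- fluid[nb[ok, , drop = FALSE]]
    ids <- cid[w3[ok, , drop = FALSE]]; nbs <- cid[nb[ok, , drop = FALSE]]
    ti <- c(ti, ids); tj <- c(tj, nbs)
    dg[ids] <- dg[ids] + 1
  }
  out_cells <- list()
  for (k in seq_along(problem$outlets)) {
    o <- problem$outlets[[k]]
    pos <- if (o$side == "lo") 1L else c(nx, ny, nz)[o$axis]
    sl <- switch(o$axis, cid[pos, , ], cid[, pos, ], cid[, , pos])
    ids <- sl[o$mask & sl > 0]
    dg[ids] <- dg[ids] + 1
    out_cells[[k]] <- ids
  }
  A <- Matrix::sparseMatrix(i = c(ti, seq_len(nf)), j = c(tj, seq_len(nf)),
                            x = c(rep(-1, length(ti)), dg), dims = c(nf, nf))
  chol_p <- Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE)

  u <- array(0, c(nx + 1L, ny, nz)); v <- array(0, c(nx, ny + 1L, nz))
  w <- array(0, c(nx, ny, nz + 1L)); p <- array(0, c(nx, ny, nz))

  # parabolic inlet profile on the inlet cap
  icap <- inlet
  prof_r2 <- {
    cc <- switch(icap$axis,
                 expand.grid(a = problem$ys, b = problem$zs),
                 expand.grid(a = problem$xs, b = problem$zs),
                 expand.grid(a = problem$xs, b = problem$ys))
    r2 <- matrix(((cc$a - icap$center[1])^2 + (cc$b - icap$center[2])^2) /
                   (icap$diameter / 2)^2, dim(icap$mask)[1], dim(icap$mask)[2])
    pmax(1 - r2, 0)
  }
  prof <- 2 * U * prof_r2                    # tube parabola, mean U
  sgn_in <- if (icap$side == "lo") 1 else -1
  set_inlet <- function() {
    pos <- if (icap$side == "lo") 1L else dim(switch(icap$axis, u, v, w))[icap$axis]
    val <- sgn_in * prof * icap$mask
    if (icap$axis == 1L) u[pos, , ] <<- val
    if (icap$axis == 2L) v[, pos, ] <<- val
    if (icap$axis == 3L) w[, , pos] <<- val
  }

  cvec <- function(a, ax) {                  # cell-centered component
    d <- dim(a)
    idx <- lapply(c(nx, ny, nz), seq_len)
    lo <- idx; hi <- idx; hi[[ax]] <- 2:d[ax]; lo[[ax]] <- 1:(d[ax] - 1L)
    0.5 * (a[lo[[1]], lo[[2]], lo[[3]]] + a[hi[[1]], hi[[2]], hi[[3]]])
  }

  upwind_adv <- function(comp, uc, vc, wc) {
    # first-order upwind gradient of a cell-centered field
    gpx <- (comp - shift3(comp, 1L, 1L)) / h
    gmx <- (shift3(comp, 1L, -1L) - comp) / h
    gpy <- (comp - shift3(comp, 2L, 1L)) / h
    gmy <- (shift3(comp, 2L, -1L) - comp) / h
    gpz <- (comp - shift3(comp, 3L, 1L)) / h
    gmz <- (shift3(comp, 3L, -1L) - comp) / h
    uc * ifelse(uc > 0, gpx, gmx) + vc * ifelse(vc > 0, gpy, gmy) +
      wc * ifelse(wc > 0, gpz, gmz)
  }

  lap_cell <- function(a, mask) {
    tot <- array(0, dim(a))
    for (ax in 1:3) for (sgn in c(-1L, 1L)) {
      nbv <- shift3(a, ax, sgn)
      nbm <- shift3(mask * 1, ax, sgn) > 0
      d <- ifelse(nbm, nbv - a, -2 * a)     # no-slip ghost at walls
      tot <- tot + d
    }
    tot / h^2
  }

  p_out <- vapply(problem$outlets, `[[`, 0, "pressure")
  fl_idx <- w3
  t_now <- 0; last_u <- u; divres <- NA
  repeat {
    for (s in seq_len(40L)) {
      set_inlet()
      u[!UA] <- 0; v[!VA] <- 0; w[!WA] <- 0
      uc <- cvec(u, 1L); vc <- cvec(v, 2L); wc <- cvec(w, 3L)
      au <- upwind_adv(uc, uc, vc, wc); av <- upwind_adv(vc, uc, vc, wc)
      aw <- upwind_adv(wc, uc, vc, wc)
      du <- -au + nu_visc * lap_cell(uc, fluid)
      dv <- -av + nu_visc * lap_cell(vc, fluid)
      dw <- -aw + nu_visc * lap_cell(wc, fluid)
      # distribute cell-centered updates back to faces (average of flanks)
      addface <- function(a, dcell, ax) {
        d <- dim(a)
        pad <- array(0, d)
        idx <- lapply(c(nx, ny, nz), seq_len)
        lo <- idx; hi <- idx
        ii <- idx; ii[[ax]] <- 2:(d[ax] - 1L)
        loD <- idx; loD[[ax]] <- 1:(d[ax] - 2L) + 0
        # mean of the two flanking cells
        dcl <- dcell; dim(dcl) <- c(nx, ny, nz)
        sl_lo <- switch(ax, dcl[1:(nx - 1L), , ], dcl[, 1:(ny - 1L), ],
                        dcl[, , 1:(nz - 1L)])
        sl_hi <- switch(ax, dcl[2:nx, , ], dcl[, 2:ny, ], dcl[, , 2:nz])
        val <- 0.5 * (sl_lo + sl_hi)
        if (ax == 1L) pad[2:nx, , ] <- val
        if (ax == 2L) pad[, 2:ny, ] <- val
        if (ax == 3L) pad[, , 2:nz] <- val
        a + dt_sub * pad
      }
      u <- addface(u, du, 1L); v <- addface(v, dv, 2L); w <- addface(w, dw, 3L)
      # pressure gradient (full field, outlet ghosts)
      gpx <- array(0, dim(u)); gpy <- array(0, dim(v)); gpz <- array(0, dim(w))
      gpx[2:nx, , ] <- (p[2:nx, , ] - p[1:(nx - 1L), , ]) / h
      gpy[, 2:ny, ] <- (p[, 2:ny, ] - p[, 1:(ny - 1L), ]) / h
      gpz[, , 2:nz] <- (p[, , 2:nz] - p[, , 1:(nz - 1L)]) / h
      for (k in seq_along(problem$outlets)) {
        o <- problem$outlets[[k]]
        pos <- if (o$side == "lo") 1L else c(nx, ny, nz)[o$axis] + 1L
        if (o$axis == 1L) {
          pc <- if (o$side == "lo") p[1, , ] else p[nx, , ]
          sgn <- if (o$side == "lo") 1 else -1
          sl <- sgn * (pc - p_out[k]) / h
          gpx[pos, , ][o$mask] <- sl[o$mask]
        }
      }
      u <- u - dt_sub * gpx / rho; v <- v - dt_sub * gpy / rho
      w <- w - dt_sub * gpz / rho
      set_inlet()
      u[!UA] <- 0; v[!VA] <- 0; w[!WA] <- 0
      div <- (u[2:(nx + 1L), , ] - u[1:nx, , ] + v[, 2:(ny + 1L), ] -
                v[, 1:ny, ] + w[, , 2:(nz + 1L)] - w[, , 1:nz]) / h
      rhs <- -(rho * h^2 / dt_sub) * div[fl_idx]
      dp <- as.vector(Matrix::solve(chol_p, rhs))
      dpa <- array(0, c(nx, ny, nz)); dpa[fl_idx] <- dp
      p <- p + dpa
      cx <- array(0, dim(u)); cy <- array(0, dim(v)); cz <- array(0, dim(w))
      cx[2:nx, , ] <- (dpa[2:nx, , ] - dpa[1:(nx - 1L), , ]) / h
      cy[, 2:ny, ] <- (dpa[, 2:ny, ] - dpa[, 1:(ny - 1L), ]) / h
      cz[, , 2:nz] <- (dpa[, , 2:nz] - dpa[, , 1:(nz - 1L)]) / h
      for (k in seq_along(problem$outlets)) {
        o <- problem$outlets[[k]]
        if (o$axis == 1L) {
          pos <- if (o$side == "lo") 1L else nx + 1L
          pc <- if (o$side == "lo") dpa[1, , ] else dpa[nx, , ]
          sgn <- if (o$side == "lo") 1 else -1
          sl <- sgn * pc / h
          cx[pos, , ][o$mask] <- sl[o$mask]
        }
      }
      free_u <- UA; free_v <- VA; free_w <- WA
      if (icap$axis == 1L) {
        pos <- if (icap$side == "lo") 1L else nx + 1L
        free_u[pos, , ][icap$mask] <- FALSE
      }
      u[free_u] <- u[free_u] - dt_sub * cx[free_u] / rho
      v[free_v] <- v[free_v] - dt_sub * cy[free_v] / rho
      w[free_w] <- w[free_w] - dt_sub * cz[free_w] / rho
      div2 <- (u[2:(nx + 1L), , ] - u[1:nx, , ] + v[, 2:(ny + 1L), ] -
                 v[, 1:ny, ] + w[, , 2:(nz + 1L)] - w[, , 1:nz]) / h
      divres <- max(abs(div2[fl_idx]))
      t_now <- t_now + dt_sub
    }
    chg <- max(abs(u - last_u)) / max(abs(u), 1e-12)
    if (verbose) message(sprintf("3D t=%.3f chg=%.2e", t_now, chg))
    last_u <- u
    if (chg < steady_tol || t_now > max_time) break
  }
  structure(list(mode = "3D", steady = TRUE, u = u, v = v, w = w, p = p,
                 times = t_now, problem = problem, props = props,
                 div_residual = divres, converged = chg < steady_tol,
                 waveform = waveform), class = "flow_field")
}

# Tube-oriented WSS for the coarse 3D solver: tangential speed at
# wall-adjacent fluid cells over the SDF wall distance.
compute_wss3d <- function(field) {
  problem <- field$problem
  props <- field$props
  fluid <- problem$fluid
  nx <- problem$nx; ny <- problem$ny; nz <- problem$nz
  nbw <- array(FALSE, dim(fluid))
  for (ax in 1:3) for (sgn in c(-1L, 1L))
    nbw <- nbw | (shift3((!fluid) * 1, ax, sgn) > 0)
  wallc <- which(fluid & nbw, arr.ind = TRUE)
  pts <- cbind(problem$xs[wallc[, 1]], problem$ys[wallc[, 2]],
               problem$zs[wallc[, 3]])
  d_mm <- -problem$geom$sdf3(pts)
  d <- pmax(d_mm, 0.25 * problem$h_mm) * 1e-3
  uc <- 0.5 * (field$u[wallc] + field$u[cbind(wallc[, 1] + 1L, wallc[, 2, drop = FALSE], wallc[, 3, drop = FALSE])])
  vc <- 0.5 * (field$v[wallc] + field$v[cbind(wallc[, 1, drop = FALSE], wallc[, 2] + 1L, wallc[, 3, drop = FALSE])])
  wc <- 0.5 * (field$w[wallc] + field$w[cbind(wallc[, 1, drop = FALSE], wallc[, 2, drop = FALSE], wallc[, 3] + 1L)])
  sp <- sqrt(uc^2 + vc^2 + wc^2)
  tau <- props$dynamic_viscosity * sp / d
  structure(list(tau = matrix(tau, ncol = 1), cells = wallc,
                 peak = max(tau), mean = mean(tau),
                 below_4Pa = max(tau) < 4), class = "wss_field")
}
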