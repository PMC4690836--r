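#' Solve incompressible flow on a rasterized domain
#'
#' Time-marches the incompressible Navier-Stokes equations on the staggered
#' Cartesian grid with an incremental pressure-correction (projection)
#' scheme: explicit central-difference advection, Crank-Nicolson diffusion,
#' and an exact sparse-Cholesky pressure solve every substep. The solver
#' substeps the requested output time step automatically to an advective
#' CFL of 0.45 (a warning reports the substepping). Outlets hold fixed
#' pressures (optionally augmented by distal resistances); the inlet
#' carries a parabolic profile scaled to the waveform; walls are no-slip;
#' screen faces apply the porous pressure jump semi-implicitly.
#'
#' In `steady = TRUE` mode the inlet is held at the waveform's cycle mean
#' and marching continues until the inlet pressure and outlet fluxes
#' stabilize (relative change below `steady_tol` between checks), which is
#' the configuration used for the jailed-outlet pressure sweeps.
#'
#' @param problem A `flow_problem` from [rasterize_domain()] (+ screens).
#' @param waveform A [make_waveform()] object.
#' @param props [fluid_properties()].
#' @param steady Steady (mean-flow) marching instead of pulsatile cycles.
#' @param n_cycles Override the problem's cycle count.
#' @param dt Override the problem's output time step, s.
#' @param steady_tol Relative-change convergence criterion for steady mode.
#' @param max_time Cap on simulated seconds in steady mode.
#' @param store_every Store every k-th output step (pulsatile mode).
#' @param verbose Print progress.
#' @return A `flow_field`: velocity/pressure snapshots, times, per-step
#'   inlet/outlet fluxes, divergence residuals, and grid metadata.
#' @export
solve_flow <- function(problem, waveform, props = fluid_properties(),
                       steady = FALSE, n_cycles = NULL, dt = NULL,
                       steady_tol = 2e-4, max_time = 6, store_every = 1L,
                       verbose = FALSE) {
  stopifnot(inherits(problem, "flow_problem"))
  if (problem$mode == "3D")
    return(solve_flow3d(problem, waveform, props, steady = steady,
                        n_cycles = n_cycles, dt = dt, max_time = max_time,
                        steady_tol = steady_tol, verbose = verbose))
  dt <- dt %||% problem$dt
  n_cycles <- n_cycles %||% problem$n_cycles
  h <- problem$h
  rho <- props$density

  D_in <- problem$inlet$diameter %||% problem$geom$caps[[1]]$diameter
  U_of_t <- function(t) {
    Q <- if (steady) waveform$mean_flow else waveform_flow_at(waveform, t)
    (Q / 6e7) / (pi * (D_in / 1000)^2 / 4)   # 3D mean velocity, m/s
  }
  U_peak <- max(waveform$samples$Q) / 6e7 / (pi * (D_in / 1000)^2 / 4)
  re <- reynolds_womersley(waveform, D_in, props)
  if (re$Re_max > 2000)
    warning(sprintf("inlet Reynolds number %.0f exceeds laminar range", re$Re_max))

  u_ref <- if (steady) U_of_t(0) else U_peak
  n_sub <- max(1L, ceiling(1.5 * 1.3 * u_ref * dt / (0.7 * h)))
  if (n_sub > 1L && verbose)
    message(sprintf("CFL substepping: %d substeps per %.3g s step", n_sub, dt))
  dt_sub <- dt / n_sub

  # Crank-Nicolson diffusion solves are bypassed in favour of the explicit
  # update when CFL substepping makes the diffusion number negligible
  # (identical results at solver tolerance, at a fraction of the cost).
  diff_num <- (props$dynamic_viscosity / rho) * dt_sub / h^2
  implicit_diff <- diff_num > 0.12
  sv <- build_solver2d(problem, props, dt_sub, factorize = implicit_diff)
  nx <- problem$nx; ny <- problem$ny
  u <- matrix(0, nx + 1L, ny); v <- matrix(0, nx, ny + 1L)
  p <- matrix(0, nx, ny)
  p_out <- vapply(problem$outlets, `[[`, 0, "pressure")
  p_out_eff <- p_out

  # inlet parabolic profile (unit mean), on the inlet face positions
  in_pos <- problem$inlet$pos
  in_w <- (max(in_pos) - min(in_pos)) + problem$h_mm
  in_c <- mean(range(in_pos))
  xi <- (in_pos - in_c) / (in_w / 2)
  prof <- 1.5 * (1 - xi^2)
  set_inlet <- function(t) {
    U <- U_of_t(t)
    if (problem$inlet$edge == "ymin") v[cbind(problem$inlet$idx, 1L)] <<- U * prof
    else if (problem$inlet$edge == "xmin") u[cbind(1L, problem$inlet$idx)] <<- U * prof
  }

  apply_masks <- function() {
    u[!sv$u_act] <<- 0; v[!sv$v_act] <<- 0
  }

  outlet_flux <- function() {
    vapply(seq_along(problem$outlets), function(k) {
      fu <- sv$u_out_list[[k]]; fv <- sv$v_out_list[[k]]
      s <- 0
      if (nrow(fu)) {
        sgn <- if (problem$outlets[[k]]$edge == "xmin") -1 else 1
        s <- s + sgn * sum(u[fu]) * h
      }
      if (nrow(fv)) {
        sgn <- if (problem$outlets[[k]]$edge == "ymin") -1 else 1
        s <- s + sgn * sum(v[fv]) * h
      }
      s
    }, 0)
  }
  inlet_flux <- function() {
    if (problem$inlet$edge == "ymin") sum(v[cbind(problem$inlet$idx, 1L)]) * h
    else sum(u[cbind(1L, problem$inlet$idx)]) * h
  }

  fl_cells <- cbind(sv$ci, sv$cj)

  substep <- function(t_now) {
    set_inlet(t_now); apply_masks()
    adv <- advection2d(u, v, h, props$dynamic_viscosity / rho)
    # pressure gradient at faces (ghost = effective outlet pressure)
    pg <- pressure_gradients2d(p, p_out_eff, sv, problem)
    uvec <- u[sv$u_act]; vvec <- v[sv$v_act]
    if (implicit_diff) {
      rhs_u <- uvec + dt_sub * (-adv$Nu[sv$u_act] - pg$gu[sv$u_act] / rho) +
        sv$mu$cfac * as.vector(sv$mu$L %*% uvec)
      rhs_v <- vvec + dt_sub * (-adv$Nv[sv$v_act] - pg$gv[sv$v_act] / rho) +
        sv$mv$cfac * as.vector(sv$mv$L %*% vvec)
      # prescribed inflow rows carry the boundary value
      if (any(sv$mu$pres)) rhs_u[sv$mu$ids[sv$mu$pres]] <- uvec[sv$mu$ids[sv$mu$pres]]
      if (any(sv$mv$pres)) rhs_v[sv$mv$ids[sv$mv$pres]] <- vvec[sv$mv$ids[sv$mv$pres]]
      us <- as.vector(Matrix::solve(sv$mu$lu, rhs_u))
      vs <- as.vector(Matrix::solve(sv$mv$lu, rhs_v))
    } else {
      us <- uvec + dt_sub * (-adv$Nu[sv$u_act] - pg$gu[sv$u_act] / rho) +
        2 * sv$mu$cfac * as.vector(sv$mu$L %*% uvec)
      vs <- vvec + dt_sub * (-adv$Nv[sv$v_act] - pg$gv[sv$v_act] / rho) +
        2 * sv$mv$cfac * as.vector(sv$mv$L %*% vvec)
      if (any(sv$mu$pres)) us[sv$mu$ids[sv$mu$pres]] <- uvec[sv$mu$ids[sv$mu$pres]]
      if (any(sv$mv$pres)) vs[sv$mv$ids[sv$mv$pres]] <- vvec[sv$mv$ids[sv$mv$pres]]
    }
    # screen drag (semi-implicit)
    for (sc in sv$screens) {
      if (length(sc$u_ids)) {
        ui <- sc$u_ids[sc$u_ids > 0]
        g <- (0.5 * sc$K * abs(us[ui]) + props$dynamic_viscosity /
                (rho * sc$alpha)) / h
        us[ui] <- us[ui] / (1 + dt_sub * g)
      }
      if (length(sc$v_ids)) {
        vi <- sc$v_ids[sc$v_ids > 0]
        g <- (0.5 * sc$K * abs(vs[vi]) + props$dynamic_viscosity /
                (rho * sc$alpha)) / h
        vs[vi] <- vs[vi] / (1 + dt_sub * g)
      }
    }
    u[sv$u_act] <<- us; v[sv$v_act] <<- vs
    set_inlet(t_now)
    # projection
    div <- (u[2:(nx + 1L), , drop = FALSE] - u[1:nx, , drop = FALSE] +
              v[, 2:(ny + 1L), drop = FALSE] - v[, 1:ny, drop = FALSE]) / h
    rhs_p <- -(rho * h^2 / dt_sub) * div[fl_cells]
    dp <- as.vector(Matrix::solve(sv$chol_p, rhs_p))
    dpm <- matrix(0, nx, ny); dpm[fl_cells] <- dp
    p <<- p + dpm
    corr <- pressure_gradients2d(dpm, rep(0, length(p_out_eff)), sv, problem)
    free_u <- sv$u_act & !sv$u_in
    free_v <- sv$v_act & !sv$v_in
    u[free_u] <<- u[free_u] - (dt_sub / rho) * corr$gu[free_u]
    v[free_v] <<- v[free_v] - (dt_sub / rho) * corr$gv[free_v]
    div2 <- (u[2:(nx + 1L), , drop = FALSE] - u[1:nx, , drop = FALSE] +
               v[, 2:(ny + 1L), drop = FALSE] - v[, 1:ny, drop = FALSE]) / h
    max(abs(div2[fl_cells]))
  }

  update_outlet_pressure <- function() {
    Qk <- outlet_flux()
    tgt <- p_out + vapply(problem$outlets, `[[`, 0, "resistance") * Qk
    p_out_eff <<- 0.5 * p_out_eff + 0.5 * tgt
  }

  inlet_pressure <- function() {
    ids <- if (problem$inlet$edge == "ymin") cbind(problem$inlet$idx, 1L)
    else cbind(1L, problem$inlet$idx)
    mean(p[ids])
  }

  if (!is.null(problem$init)) {
    u <- problem$init$u; v <- problem$init$v; p <- problem$init$p
    if (!is.null(problem$init$p_out_eff)) p_out_eff <- problem$init$p_out_eff
  }

  if (steady) {
    t_now <- 0; it <- 0L; divres <- NA
    pin_last <- Inf
    repeat {
      u_prev <- u; v_prev <- v
      for (s in seq_len(50L)) {
        divres <- substep(t_now)
        t_now <- t_now + dt_sub; it <- it + 1L
      }
      if (any(vapply(problem$outlets, `[[`, 0, "resistance") != 0))
        update_outlet_pressure()
      pin <- inlet_pressure()
      uscale <- max(abs(u), abs(v), 1e-12)
      chg <- c(max(abs(u - u_prev), abs(v - v_prev)) / uscale,
               abs(pin - pin_last) / max(abs(pin), 1e-9))
      if (verbose)
        message(sprintf("t=%.3f s  Pin=%.2f Pa  chg=%.2e/%.2e",
                        t_now, pin, chg[1], chg[2]))
      pin_last <- pin
      if (all(chg < steady_tol) || t_now >= max_time) break
    }
    converged <- all(chg < steady_tol)
    if (!converged) warning("steady solve hit max_time before convergence")
    return(structure(list(
      mode = "2D", steady = TRUE, u = list(u), v = list(v), p = p,
      times = t_now, problem = problem, props = props,
      inlet_flux = inlet_flux(), outlet_flux = outlet_flux(),
      inlet_pressure = inlet_pressure(), outlet_pressure_eff = p_out_eff,
      div_residual = divres, converged = converged, n_sub = n_sub,
      waveform = waveform), class = "flow_field"))
  }

  n_steps <- round(n_cycles * waveform$period / dt)
  keep <- seq(1L, n_steps, by = store_every)
  u_hist <- vector("list", length(keep)); v_hist <- vector("list", length(keep))
  t_hist <- numeric(length(keep))
  flux_in <- numeric(n_steps); flux_out <- matrix(0, n_steps,
                                                  length(problem$outlets))
  divres <- numeric(n_steps)
  t_now <- 0; ik <- 1L
  for (st in seq_len(n_steps)) {
    dmax <- 0
    for (s in seq_len(n_sub)) {
      dmax <- max(dmax, substep(t_now))
      t_now <- t_now + dt_sub
    }
    if (any(vapply(problem$outlets, `[[`, 0, "resistance") != 0))
      update_outlet_pressure()
    divres[st] <- dmax
    flux_in[st] <- inlet_flux(); flux_out[st, ] <- outlet_flux()
    if (st %in% keep) {
      u_hist[[ik]] <- u; v_hist[[ik]] <- v; t_hist[ik] <- t_now
      ik <- ik + 1L
    }
    if (verbose && st %% 20L == 0L)
      message(sprintf("step %d/%d t=%.2f s", st, n_steps, t_now))
  }
  structure(list(mode = "2D", steady = FALSE, u = u_hist, v = v_hist, p = p,
                 times = t_hist, dt = dt * store_every, problem = problem,
                 props = props, flux_in = flux_in, flux_out = flux_out,
                 div_residual = divres,
                 final_cycle = which(t_hist > (n_cycles - 1) * waveform$period - 1e-9),
                 n_sub = n_sub, waveform = waveform),
            class = "flow_field")
}

# Pressure gradients at staggered faces with outlet ghost values.
pressure_gradients2d <- function(p, p_out_vals, sv, problem) {
  nx <- problem$nx; ny <- problem$ny; h <- problem$h
  gu <- matrix(0, nx + 1L, ny); gv <- matrix(0, nx, ny + 1L)
  gu[2:nx, ] <- (p[2:nx, , drop = FALSE] - p[1:(nx - 1L), , drop = FALSE]) / h
  gv[, 2:ny] <- (p[, 2:ny, drop = FALSE] - p[, 1:(ny - 1L), drop = FALSE]) / h
  for (k in seq_along(problem$outlets)) {
    o <- problem$outlets[[k]]; pv <- p_out_vals[k]
    if (o$edge == "xmin") gu[cbind(1L, o$idx)] <- (p[cbind(1L, o$idx)] - pv) / h
    else if (o$edge == "xmax")
      gu[cbind(nx + 1L, o$idx)] <- (pv - p[cbind(nx, o$idx)]) / h
    else if (o$edge == "ymin") gv[cbind(o$idx, 1L)] <- (p[cbind(o$idx, 1L)] - pv) / h
    else gv[cbind(o$idx, ny + 1L)] <- (pv - p[cbind(o$idx, ny)]) / h
  }
  list(gu = gu, gv = gv)
}

#' @export
print.flow_field <- function(x, ...) {
  if (isTRUE(x$steady))
    cat(sprintf("<flow_field> steady %s, t=%.2f s, inlet %.4g, Pin %.1f Pa, max|div| %.2e\n",
                x$mode, x$times, x$inlet_flux, x$inlet_pressure, x$div_residual))
  else
    cat(sprintf("<flow_field> %s, %d stored steps over %.2f s, max|div| %.2e\n",
                x$mode, length(x$times), max(x$times), max(x$div_residual)))
  invisible(x)
}
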