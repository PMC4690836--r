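#' Contrast transport parameters
#'
#' Scalar contrast is transported as an independent passive quantity (it
#' does not alter blood density or viscosity): advection by the computed
#' flow plus isotropic diffusion with a blood diffusivity of 1.0e-7 m^2/s,
#' with zero diffusive flux through walls. The inlet bolus is a uniform
#' unit concentration held for one cardiac cycle, introduced after two full
#' cycles (1.60 s at 75 BPM) to let pulsatile transients decay, with the
#' run extending two further cycles (4.00 s total).
#'
#' @param diffusivity m^2/s.
#' @param bolus_start,bolus_duration Bolus schedule, s.
#' @return A `transport_params` object.
#' @export
transport_params <- function(diffusivity = 1.0e-7, bolus_start = 1.60,
                             bolus_duration = 0.80) {
  stopifnot(diffusivity >= 0, bolus_start >= 0, bolus_duration > 0)
  structure(list(diffusivity = diffusivity, bolus_start = bolus_start,
                 bolus_duration = bolus_duration, source = 0),
            class = "transport_params")
}

# Superbee-limited upwind face interpolation along one axis of a cell
# field. phi: cell matrix; vel: face-normal velocity on interior faces
# (n+1 faces per line, boundary faces handled by caller). Returns interior
# face values (MUSCL kappa-free TVD reconstruction).
limited_face_values <- function(phi_up2, phi_up, phi_dn) {
  r <- (phi_up - phi_up2) / ifelse(abs(phi_dn - phi_up) > 1e-30,
                                   phi_dn - phi_up, 1e-30)
  psi <- pmax(0, pmin(2 * r, 1), pmin(r, 2))     # superbee
  phi_up + 0.5 * psi * (phi_dn - phi_up)
}

#' Transport contrast through a computed flow field
#'
#' Advances the scalar transport equation over the stored velocity
#' snapshots of a pulsatile `flow_field` (2D), using conservative
#' flux-limited (superbee) upwind advection - which keeps the
#' concentration bounded in [0, 1] and creates no new extrema - plus
#' explicit diffusion, with CFL substepping per snapshot interval. The
#' inlet concentration follows the bolus schedule; outlets are advective
#' outflow; walls are zero-flux.
#'
#' @param field A pulsatile `flow_field` covering the schedule window.
#' @param params [transport_params()].
#' @return A `contrast_field`: concentration snapshots (cell matrices),
#'   times, and global mass-balance diagnostics.
#' @export
transport_contrast <- function(field, params = transport_params()) {
  problem <- field$problem
  stopifnot(problem$mode == "2D", !isTRUE(field$steady))
  if (max(field$times) + 1e-9 < params$bolus_start)
    stop("bolus schedule lies outside the computed flow window")
  nx <- problem$nx; ny <- problem$ny; h <- problem$h
  fluid <- problem$fluid
  Gam <- params$diffusivity
  phi <- matrix(0, nx, ny)
  inlet <- problem$inlet
  nsnap <- length(field$times)
  out <- vector("list", nsnap)
  mass <- numeric(nsnap)
  net_influx <- numeric(nsnap)
  infl_acc <- 0
  dt_out <- c(field$times[1], diff(field$times))

  # neighbor-presence masks for diffusion (zero-flux at walls)
  fl <- fluid
  # open_xm[i, j]: the face between cells (i-1, j) and (i, j) is open
  open_xm <- rbind(rep(FALSE, ny), fl[-nx, , drop = FALSE] & fl[-1, , drop = FALSE])
  open_ym <- cbind(rep(FALSE, nx), fl[, -ny, drop = FALSE] & fl[, -1, drop = FALSE])

  for (s in seq_len(nsnap)) {
    u <- field$u[[s]]; v <- field$v[[s]]
    t0 <- field$times[s] - dt_out[s]
    umax <- max(abs(u), abs(v), 1e-9)
    nsub <- max(1L, ceiling(umax * dt_out[s] / (0.45 * h)))
    dts <- dt_out[s] / nsub
    for (ss in seq_len(nsub)) {
      t_now <- t0 + ss * dts
      bol <- as.numeric(t_now >= params$bolus_start &
                          t_now < params$bolus_start + params$bolus_duration)
      # --- advective fluxes (superbee upwind) ---
      # x-faces: interior faces i = 2..nx between cells i-1, i
      phiW <- phi[c(1L, 1L:(nx - 1L)), , drop = FALSE]   # i-1 with clamp
      phiWW <- phi[c(1L, 1L, 1L:(nx - 2L)), , drop = FALSE]
      phiE <- phi[c(2L:nx, nx), , drop = FALSE]
      phiEE <- phi[c(3L:nx, nx, nx), , drop = FALSE]
      uf <- u[2:(nx + 1L), , drop = FALSE]               # faces i+1 of cell i
      # face between cell i and i+1 (i = 1..nx-1): use u[i+1, ]
      ufi <- u[2:nx, , drop = FALSE]
      fpos <- limited_face_values(phiWW[2:nx, , drop = FALSE],
                                  phi[1:(nx - 1L), , drop = FALSE],
                                  phi[2:nx, , drop = FALSE])
      fneg <- limited_face_values(phiEE[1:(nx - 1L), , drop = FALSE],
                                  phi[2:nx, , drop = FALSE],
                                  phi[1:(nx - 1L), , drop = FALSE])
      fx_int <- ifelse(ufi >= 0, fpos, fneg) * ufi       # (nx-1) x ny
      Fx <- matrix(0, nx + 1L, ny)
      Fx[2:nx, ] <- fx_int
      # y-faces
      vfi <- v[, 2:ny, drop = FALSE]
      gpos <- limited_face_values(phi[, c(1L, 1L:(ny - 2L)), drop = FALSE],
                                  phi[, 1:(ny - 1L), drop = FALSE],
                                  phi[, 2:ny, drop = FALSE])
      gneg <- limited_face_values(phi[, c(3L:ny, ny), drop = FALSE],
                                  phi[, 2:ny, drop = FALSE],
                                  phi[, 1:(ny - 1L), drop = FALSE])
      Fy <- matrix(0, nx, ny + 1L)
      Fy[, 2:ny] <- ifelse(vfi >= 0, gpos, gneg) * vfi
      # boundary faces: inlet carries the bolus, outlets advect out
      if (inlet$edge == "ymin")
        Fy[cbind(inlet$idx, 1L)] <- v[cbind(inlet$idx, 1L)] * bol
      else if (inlet$edge == "xmin")
        Fx[cbind(1L, inlet$idx)] <- u[cbind(1L, inlet$idx)] * bol
      bnd_out <- 0
      for (o in problem$outlets) {
        if (o$edge == "xmin") {
          Fx[cbind(1L, o$idx)] <- u[cbind(1L, o$idx)] * phi[cbind(1L, o$idx)]
          bnd_out <- bnd_out - sum(Fx[cbind(1L, o$idx)])
        } else if (o$edge == "xmax") {
          Fx[cbind(nx + 1L, o$idx)] <- u[cbind(nx + 1L, o$idx)] *
            phi[cbind(nx, o$idx)]
          bnd_out <- bnd_out + sum(Fx[cbind(nx + 1L, o$idx)])
        } else if (o$edge == "ymin") {
          Fy[cbind(o$idx, 1L)] <- v[cbind(o$idx, 1L)] * phi[cbind(o$idx, 1L)]
          bnd_out <- bnd_out - sum(Fy[cbind(o$idx, 1L)])
        } else {
          Fy[cbind(o$idx, ny + 1L)] <- v[cbind(o$idx, ny + 1L)] *
            phi[cbind(o$idx, ny)]
          bnd_out <- bnd_out + sum(Fy[cbind(o$idx, ny + 1L)])
        }
      }
      adv <- (Fx[2:(nx + 1L), , drop = FALSE] - Fx[1:nx, , drop = FALSE] +
                Fy[, 2:(ny + 1L), drop = FALSE] - Fy[, 1:ny, drop = FALSE]) / h
      # --- diffusion (zero-flux walls) ---
      dW <- (phiW - phi); dW[!open_xm] <- 0
      dE <- (phiE - phi); dE[!rbind(open_xm[-1, , drop = FALSE],
                                    rep(FALSE, ny))] <- 0
      phiS <- phi[, c(1L, 1L:(ny - 1L)), drop = FALSE]
      phiN <- phi[, c(2L:ny, ny), drop = FALSE]
      dS <- (phiS - phi); dS[!open_ym] <- 0
      dN <- (phiN - phi); dN[!cbind(open_ym[, -1, drop = FALSE],
                                    rep(FALSE, nx))] <- 0
      lap <- (dW + dE + dS + dN) / h^2
      phi_new <- phi + dts * (-adv + Gam * lap)
      phi_new[!fluid] <- 0
      phi <- phi_new
      bnd_in <- if (inlet$edge == "ymin") sum(v[cbind(inlet$idx, 1L)]) * bol
      else sum(u[cbind(1L, inlet$idx)]) * bol
      infl_acc <- infl_acc + (bnd_in - bnd_out) * h * dts
    }
    out[[s]] <- phi
    mass[s] <- sum(phi[fluid]) * h^2
    net_influx[s] <- infl_acc
  }
  structure(list(concentration = out, times = field$times,
                 problem = problem, params = params,
                 mass = mass, net_influx = net_influx),
            class = "contrast_field")
}

#' @export
print.contrast_field <- function(x, ...) {
  cat(sprintf("<contrast_field> %d snapshots over %.2f s, final max phi %.3f\n",
              length(x$times), max(x$times),
              max(x$concentration[[length(x$times)]])))
  invisible(x)
}

#' Dome contrast residence curve
#'
#' Volume-weighted mean concentration over the aneurysm dome per snapshot.
#'
#' @param cf A `contrast_field`.
#' @param dome_mask Logical cell matrix; default: the geometry's dome
#'   region above the neck plane.
#' @return A `residence_curve` (data.frame `time`, `concentration`).
#' @export
residence_curve <- function(cf, dome_mask = NULL) {
  problem <- cf$problem
  if (is.null(dome_mask)) {
    geom <- problem$geom
    if (is.null(geom$dome)) stop("geometry has no dome; supply dome_mask")
    gx <- rep(problem$xs, times = problem$ny)
    gy <- rep(problem$ys, each = problem$nx)
    dome_mask <- matrix(in_dome_region(geom, cbind(gx, gy)),
                        problem$nx, problem$ny) & problem$fluid
  }
  if (!any(dome_mask)) stop("empty dome mask")
  conc <- vapply(cf$concentration, function(p) mean(p[dome_mask]), 0)
  structure(data.frame(time = cf$times, concentration = conc),
            class = c("residence_curve", "data.frame"))
}

#' Fit an exponential decay to a residence curve
#'
#' Ordinary least squares on the log concentration from the curve's peak
#' down to its first crossing of 10% of peak; the decay rate is minus the
#' slope. If the curve never falls to 10% of peak the fit uses the
#' available decay and sets `truncated = TRUE` with a warning.
#'
#' @param curve A [residence_curve()] (or data.frame time/concentration).
#' @return A `decay_fit`: `rate` (1/s), `r_squared`, `window`, `truncated`.
#' @export
fit_exponential_decay <- function(curve) {
  tt <- curve$time; cc <- curve$concentration
  ipk <- which.max(cc)
  if (ipk == length(cc)) stop("curve has no decay after its peak")
  peak <- cc[ipk]
  below <- which(cc[(ipk + 1L):length(cc)] <= 0.1 * peak)
  truncated <- length(below) == 0
  iend <- if (truncated) length(cc) else ipk + below[1]
  if (truncated)
    warning("decay never reaches 10% of peak; fitting available decay window")
  sel <- ipk:iend
  ok <- sel[cc[sel] > 0]
  if (length(ok) < 3) stop("too few samples in the decay window")
  fit <- stats::lm(log(cc[ok]) ~ tt[ok])
  y <- log(cc[ok])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(rate = -unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 window = c(tt[ipk], tt[iend]), truncated = truncated,
                 n = length(ok)), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> rate %.3f 1/s, R^2 %.4f, window [%.2f, %.2f] s%s\n",
              x$rate, x$r_squared, x$window[1], x$window[2],
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Percent reduction in contrast decay rate after treatment
#'
#' 100 x (rate_untreated - rate_treated) / rate_untreated.
#'
#' @param fit_nd,fit_d `decay_fit` objects (or bare rates, 1/s) for the
#'   untreated and treated runs.
#' @return Percent reduction.
#' @export
decay_rate_reduction <- function(fit_nd, fit_d) {
  r0 <- if (inherits(fit_nd, "decay_fit")) fit_nd$rate else fit_nd
  r1 <- if (inherits(fit_d, "decay_fit")) fit_d$rate else fit_d
  if (r0 <= 0) stop("untreated decay rate must be positive")
  100 * (r0 - r1) / r0
}

#' Render virtual angiogram frames
#'
#' Beer-Lambert parallel projection of the concentration field:
#' \eqn{I = 1 - \exp(-\kappa \int \phi \, dl)}, grayscale-inverted so
#' opacified lumen appears dark, mimicking digital subtraction
#' angiography. 2D fields project with one cell depth per cell.
#'
#' @param cf A `contrast_field`.
#' @param kappa Attenuation, 1/m; default calibrated so a fully opacified
#'   path of one parent-vessel diameter maps to 90% intensity.
#' @param path_mm Reference path length for the default kappa (mm).
#' @param out_dir If non-NULL, write 8-bit grayscale PNG frames there.
#' @return An `angiogram`: list of frames (matrices in [0,1]) and times.
#' @export
render_angiogram <- function(cf, kappa = NULL, path_mm = 4, out_dir = NULL) {
  h <- cf$problem$h
  kappa <- kappa %||% (-log(1 - 0.9) / (path_mm * 1e-3))
  frames <- lapply(cf$concentration, function(p) {
    path <- if (length(dim(p)) == 3L) apply(p, c(1, 2), sum) * h else p * h
    1 - exp(-kappa * path)               # intensity I
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(frames)) {
      img <- 1 - frames[[k]]             # DSA convention: contrast dark
      img <- t(img[, ncol(img):1, drop = FALSE])
      png::writePNG(img, file.path(out_dir, sprintf("frame_%04d.png", k)))
    }
  }
  structure(list(frames = frames, times = cf$times, kappa = kappa),
            class = "angiogram")
}
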