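# Staggered-grid incompressible projection solver (2D slice).
#
# Incremental pressure-correction time stepping: central-difference
# advection (explicit), Crank-Nicolson diffusion (implicit sparse solves),
# screen drag applied semi-implicitly on flagged faces, and an exact sparse
# Cholesky pressure projection each substep. Advection stability is kept by
# automatic substepping of the solver time step to a CFL of 0.45.

# Precompute masks, sparse operators and factorizations for a problem.
build_solver2d <- function(problem, props, dt_sub, factorize = TRUE) {
  nx <- problem$nx; ny <- problem$ny; h <- problem$h
  fluid <- problem$fluid
  nu_visc <- props$dynamic_viscosity / props$density

  FL <- function(i, j) {                      # fluid lookup with bounds
    ok <- i >= 1L & i <= nx & j >= 1L & j <= ny
    out <- logical(length(i)); out[ok] <- fluid[cbind(i[ok], j[ok])]
    out
  }

  # --- classify u-faces ((nx+1) x ny) ---
  iu <- rep(seq_len(nx + 1L), times = ny); ju <- rep(seq_len(ny), each = nx + 1L)
  u_int <- FL(iu - 1L, ju) & FL(iu, ju)
  u_bnd <- matrix(FALSE, nx + 1L, ny)        # boundary (inlet/outlet) faces
  u_in <- matrix(FALSE, nx + 1L, ny)
  u_out_list <- list()
  for (k in seq_along(problem$outlets)) {
    o <- problem$outlets[[k]]
    if (o$edge == "xmin") u_out_list[[k]] <- cbind(1L, o$idx)
    else if (o$edge == "xmax") u_out_list[[k]] <- cbind(nx + 1L, o$idx)
    else u_out_list[[k]] <- cbind(integer(0), integer(0))
  }
  if (problem$inlet$edge == "xmin") u_in[cbind(1L, problem$inlet$idx)] <- TRUE
  u_act <- matrix(u_int, nx + 1L, ny)
  for (f in u_out_list) if (nrow(f)) u_act[f] <- TRUE
  u_act <- u_act | u_in

  # --- classify v-faces (nx x (ny+1)) ---
  iv <- rep(seq_len(nx), times = ny + 1L); jv <- rep(seq_len(ny + 1L), each = nx)
  v_int <- FL(iv, jv - 1L) & FL(iv, jv)
  v_in <- matrix(FALSE, nx, ny + 1L)
  v_out_list <- list()
  for (k in seq_along(problem$outlets)) {
    o <- problem$outlets[[k]]
    if (o$edge == "ymin") v_out_list[[k]] <- cbind(o$idx, 1L)
    else if (o$edge == "ymax") v_out_list[[k]] <- cbind(o$idx, ny + 1L)
    else v_out_list[[k]] <- cbind(integer(0), integer(0))
  }
  if (problem$inlet$edge == "ymin") v_in[cbind(problem$inlet$idx, 1L)] <- TRUE
  v_act <- matrix(v_int, nx, ny + 1L)
  for (f in v_out_list) if (nrow(f)) v_act[f] <- TRUE
  v_act <- v_act | v_in

  # --- Poisson operator over fluid cells ---
  cid <- matrix(0L, nx, ny); cid[fluid] <- seq_len(sum(fluid))
  nf <- sum(fluid)
  ci <- rep(seq_len(nx), times = ny); cj <- rep(seq_len(ny), each = nx)
  fc <- fluid[cbind(ci, cj)]
  ci <- ci[fc]; cj <- cj[fc]                 # fluid cell coordinates, id order?
  ord <- order(cid[cbind(ci, cj)]); ci <- ci[ord]; cj <- cj[ord]
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  diag_acc <- numeric(nf)
  add_nb <- function(ni, nj) {
    # neighbor coupling across an interior face
    ok <- FL(ni, nj)
    ids <- cid[cbind(ci[ok], cj[ok])]
    nbs <- cid[cbind(ni[ok], nj[ok])]
    trip_i <<- c(trip_i, ids); trip_j <<- c(trip_j, nbs)
    trip_x <<- c(trip_x, rep(-1, sum(ok)))
    diag_acc[ids] <<- diag_acc[ids] + 1
  }
  add_nb(ci - 1L, cj); add_nb(ci + 1L, cj); add_nb(ci, cj - 1L); add_nb(ci, cj + 1L)
  # outlet ghost Dirichlet couplings
  out_cells <- list()
  for (k in seq_along(problem$outlets)) {
    o <- problem$outlets[[k]]
    cells <- switch(o$edge,
                    xmin = cbind(1L, o$idx), xmax = cbind(nx, o$idx),
                    ymin = cbind(o$idx, 1L), ymax = cbind(o$idx, ny))
    ids <- cid[cells]
    diag_acc[ids] <- diag_acc[ids] + 1
    out_cells[[k]] <- list(cells = cells, ids = ids)
  }
  A <- Matrix::sparseMatrix(i = c(trip_i, seq_len(nf)),
                            j = c(trip_j, seq_len(nf)),
                            x = c(trip_x, diag_acc), dims = c(nf, nf))
  chol_p <- Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE)

  # outlet-cap masks per grid edge: tangential gradients are zero across
  # outlet planes, while walls and the inlet plane are no-slip ghosts
  cap_mask <- list(ymin = logical(nx), ymax = logical(nx),
                   xmin = logical(ny), xmax = logical(ny))
  for (o in problem$outlets) cap_mask[[o$edge]][o$idx] <- TRUE

  # --- momentum Laplacian + CN factorization for one face family ---
  build_mom <- function(act, inflow, family) {
    dims <- dim(act)
    idm <- matrix(0L, dims[1], dims[2]); idm[act] <- seq_len(sum(act))
    nU <- sum(act)
    w <- which(act, arr.ind = TRUE)
    fi <- w[, 1]; fj <- w[, 2]
    ids <- idm[w]
    is_pres <- inflow[w]
    ti <- integer(0); tj <- integer(0); tx <- numeric(0)
    dg <- numeric(nU)
    get_face <- function(i, j) {
      ok <- i >= 1L & i <= dims[1] & j >= 1L & j <= dims[2]
      out <- integer(length(i)); out[ok] <- idm[cbind(i[ok], j[ok])]
      out
    }
    add_dir <- function(di, dj, tangential) {
      ni <- fi + di; nj <- fj + dj
      nid <- get_face(ni, nj)
      inb <- i_inb <- nid > 0L
      free <- !is_pres
      use <- inb & free
      ti <<- c(ti, ids[use]); tj <<- c(tj, nid[use]); tx <<- c(tx, rep(1, sum(use)))
      dg[ids[use]] <<- dg[ids[use]] - 1
      # missing neighbor handling for free faces
      miss <- !inb & free
      if (any(miss)) {
        mi <- ni[miss]; mj <- nj[miss]
        inside_grid <- mi >= 1L & mi <= dims[1] & mj >= 1L & mj <= dims[2]
        mids <- ids[miss]
        if (tangential) {
          # wall ghost u_nb = -u when both flanking cells are solid
          if (family == "u") {
            c1 <- !FL(mi - 1L, mj); c2 <- !FL(mi, mj)
          } else {
            c1 <- !FL(mi, mj - 1L); c2 <- !FL(mi, mj)
          }
          ghost <- inside_grid & c1 & c2
          dg[mids[ghost]] <<- dg[mids[ghost]] - 2    # ghost -u
          dg[mids[inside_grid & !ghost]] <<-
            dg[mids[inside_grid & !ghost]] - 1       # Dirichlet 0 at face
          if (any(!inside_grid)) {
            # beyond the grid edge: no-slip ghost unless across an outlet
            og <- which(!inside_grid)
            if (family == "u") {
              edge <- ifelse(mj[og] < 1L, "ymin", "ymax")
              along <- pmin(pmax(mi[og] - 1L, 1L), nx)  # flanking cell column
              along2 <- pmin(pmax(mi[og], 1L), nx)
              is_out <- vapply(seq_along(og), function(q)
                cap_mask[[edge[q]]][along[q]] && cap_mask[[edge[q]]][along2[q]],
                TRUE)
            } else {
              edge <- ifelse(mi[og] < 1L, "xmin", "xmax")
              along <- pmin(pmax(mj[og] - 1L, 1L), ny)
              along2 <- pmin(pmax(mj[og], 1L), ny)
              is_out <- vapply(seq_along(og), function(q)
                cap_mask[[edge[q]]][along[q]] && cap_mask[[edge[q]]][along2[q]],
                TRUE)
            }
            dg[mids[og[!is_out]]] <<- dg[mids[og[!is_out]]] - 2
            # outlet: Neumann (skip)
          }
        } else {
          # normal direction: missing face is a wall face (value 0) if
          # inside the grid, Neumann if beyond the boundary
          dg[mids[inside_grid]] <<- dg[mids[inside_grid]] - 1
        }
      }
    }
    if (family == "u") {
      add_dir(-1L, 0L, FALSE); add_dir(1L, 0L, FALSE)
      add_dir(0L, -1L, TRUE);  add_dir(0L, 1L, TRUE)
    } else {
      add_dir(0L, -1L, FALSE); add_dir(0L, 1L, FALSE)
      add_dir(-1L, 0L, TRUE);  add_dir(1L, 0L, TRUE)
    }
    Lsp <- Matrix::sparseMatrix(i = c(ti, seq_len(nU)), j = c(tj, seq_len(nU)),
                                x = c(tx, dg), dims = c(nU, nU))
    cfac <- nu_visc * dt_sub / (2 * h^2)
    pres_ids <- ids[is_pres]
    if (length(pres_ids)) {
      Lsp <- methods::as(Lsp, "CsparseMatrix")
      Lsp[pres_ids, ] <- 0
    }
    M <- NULL
    if (factorize) {
      # prescribed (inflow) rows become identity; their values enter the
      # neighbors' equations through the retained column entries
      M <- methods::as(Matrix::Diagonal(nU) - cfac * Lsp, "CsparseMatrix")
      if (length(pres_ids)) M[cbind(pres_ids, pres_ids)] <- 1
    }
    list(idm = idm, n = nU, faces = w, ids = ids, pres = is_pres,
         L = Lsp, lu = if (factorize) Matrix::lu(M), cfac = cfac)
  }
  mu <- build_mom(u_act, u_in, "u")
  mv <- build_mom(v_act, v_in, "v")

  # screen face ids
  screens <- lapply(problem$screens, function(sc) {
    list(K = sc$K, alpha = sc$alpha,
         u_ids = mu$idm[sc$ufaces[, , drop = FALSE]],
         v_ids = mv$idm[sc$vfaces[, , drop = FALSE]])
  })

  list(nx = nx, ny = ny, h = h, nf = nf, cid = cid, fluid = fluid,
       ci = ci, cj = cj, chol_p = chol_p,
       u_act = u_act, v_act = v_act, u_in = u_in, v_in = v_in,
       u_out_list = u_out_list, v_out_list = v_out_list,
       out_cells = out_cells, mu = mu, mv = mv, screens = screens,
       dt_sub = dt_sub, props = props)
}

# Advection terms on the staggered grid, in conservative flux form with
# hybrid differencing: central interpolation of the advected velocity below
# a face Peclet number of 2, blending to first-order upwind above it (the
# classic stabilization for explicit time integration of the convective
# terms). Velocities outside the fluid are zero in the arrays, which
# doubles as the no-slip closure for near-wall averages.
advection2d <- function(u, v, h, nu_visc) {
  nx <- nrow(u) - 1L; ny <- ncol(u)
  hyb <- function(adv, ce, up) {
    g <- 1 - 2 * nu_visc / (abs(adv) * h + 1e-30)
    g <- pmin(pmax(g, 0), 1)
    (1 - g) * ce + g * up
  }
  # --- x-fluxes of u at cell centers (i = 0..nx+1 padded) ---
  uc <- 0.5 * (u[1:nx, , drop = FALSE] + u[2:(nx + 1L), , drop = FALSE])
  up_x <- ifelse(uc >= 0, u[1:nx, , drop = FALSE], u[2:(nx + 1L), , drop = FALSE])
  Fx <- uc * hyb(uc, uc, up_x)                          # nx x ny
  Fxp <- rbind(Fx[1, ], Fx, Fx[nx, ])                   # zero-gradient pad
  dUU <- (Fxp[2:(nx + 2L), , drop = FALSE] -
            Fxp[1:(nx + 1L), , drop = FALSE]) / h
  # --- y-fluxes of v at cell centers ---
  vc <- 0.5 * (v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1L), drop = FALSE])
  up_y <- ifelse(vc >= 0, v[, 1:ny, drop = FALSE], v[, 2:(ny + 1L), drop = FALSE])
  Fy <- vc * hyb(vc, vc, up_y)
  Fyp <- cbind(Fy[, 1], Fy, Fy[, ny])
  dVV <- (Fyp[, 2:(ny + 2L), drop = FALSE] -
            Fyp[, 1:(ny + 1L), drop = FALSE]) / h
  # --- uv fluxes at cell corners (nx+1) x (ny+1) ---
  upad <- cbind(0, u, 0)
  u_lo <- upad[, 1:(ny + 1L), drop = FALSE]
  u_hi <- upad[, 2:(ny + 2L), drop = FALSE]
  u_ce <- 0.5 * (u_lo + u_hi)
  vpad <- rbind(0, v, 0)
  v_lo <- vpad[1:(nx + 1L), , drop = FALSE]
  v_hi <- vpad[2:(nx + 2L), , drop = FALSE]
  v_ce <- 0.5 * (v_lo + v_hi)
  u_at_c <- hyb(v_ce, u_ce, ifelse(v_ce >= 0, u_lo, u_hi))  # advected by v
  v_at_c <- hyb(u_ce, v_ce, ifelse(u_ce >= 0, v_lo, v_hi))  # advected by u
  Cu <- v_ce * u_at_c
  Cv <- u_ce * v_at_c
  dUV <- (Cu[, 2:(ny + 1L), drop = FALSE] - Cu[, 1:ny, drop = FALSE]) / h
  dVU <- (Cv[2:(nx + 1L), , drop = FALSE] - Cv[1:nx, , drop = FALSE]) / h
  list(Nu = dUU + dUV, Nv = dVV + dVU)
}
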