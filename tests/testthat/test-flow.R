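test_that("waveforms honor their site envelopes and cycle means", {
  for (site in c("ICA", "BA")) {
    wf <- make_waveform(site)
    env <- stentflow:::waveform_sites[[site]]
    expect_equal(wf$period, 0.8)
    # numeric cycle integral / period equals the mean within 0.5%
    expect_lt(abs(mean(wf$samples$Q) / env$mean - 1), 0.005)
    expect_gte(min(wf$samples$Q), env$range[1] - 1e-9)
    expect_lte(max(wf$samples$Q), env$range[2] + 1e-9)
  }
  # constant waveform limit
  wfc <- make_waveform("custom", mean_flow = 100, flow_range = c(99.9, 100.1))
  expect_lt(diff(range(wfc$samples$Q)), 0.3)
  expect_error(make_waveform("custom", mean_flow = 100), "flow_range")
})

test_that("Reynolds and Womersley numbers match closed forms", {
  rw <- reynolds_womersley(make_waveform("ICA"), 2.4)
  expect_equal(rw$alpha, 0.0012 * sqrt(2 * pi * 1.25 * 1000 / 0.004),
               tolerance = 1e-9)
  expect_equal(rw$alpha, 1.68, tolerance = 0.005)
  rw2 <- reynolds_womersley(c(230, 230), 4.0)
  expect_equal(rw2$Re_max, 1000 * (4 * (230 / 6e7) / (pi * 0.004^2)) * 0.004 /
                 0.004, tolerance = 1e-9)
  expect_equal(rw2$Re_max, 305, tolerance = 0.002)
  expect_equal(reynolds_womersley(c(0, 0), 4.0)$Re_max, 0)
})

test_that("steady channel flow reproduces plane Poiseuille", {
  cf <- channel_field()
  ff <- cf$field; U <- cf$U
  u <- ff$u[[1]]
  prof <- u[round(nrow(u) * 0.7), ]
  expect_lt(abs(max(prof) / (1.5 * U) - 1), 0.02)
  # wall shear 6 mu U / H within 5%
  w <- compute_wss(ff)
  tau_th <- 6 * 0.004 * U / 0.001
  expect_lt(abs(w$mean / tau_th - 1), 0.05)
  expect_lt(abs(w$peak / tau_th - 1), 0.08)
  # driving gradient ~ 12 mu U L / H^2
  expect_equal(ff$inlet_pressure, 12 * 0.004 * U / 0.001^2 * 0.008,
               tolerance = 0.05)
  # global mass conservation within 0.1%
  expect_lt(abs(ff$inlet_flux - sum(ff$outlet_flux)) /
              abs(ff$inlet_flux), 0.001)
  expect_lt(ff$div_residual, 1e-8)
})

test_that("zero inflow with equal outlet pressures gives a quiescent field", {
  tube <- make_straight_vessel(1, 8, build_surface = FALSE)
  fp <- rasterize_domain(tube, resolution = 8)
  wf <- make_waveform("custom", mean_flow = 1e-9,
                      flow_range = c(0.5e-9, 2e-9))
  ff <- suppressWarnings(solve_flow(fp, wf, steady = TRUE, max_time = 0.05))
  expect_lt(max(abs(ff$u[[1]]), abs(ff$v[[1]])), 1e-6)
})

test_that("screen coefficients follow the wire-row correlation", {
  sc <- screen_coefficients(0.70, 30)
  # hand evaluation of the configured correlation
  cvr <- 1 - sqrt(0.70); s <- 30e-6 / cvr; tau <- pi * 30e-6 / s
  expect_equal(sc$K, (1 - 0.7^2) / 0.7^2, tolerance = 1e-12)
  expect_equal(sc$alpha, s * (1 - 2 * log(tau) + tau^2 / 6) / (16 * pi),
               tolerance = 1e-12)
  # transparent limit
  hi <- screen_coefficients(0.999999, 30)
  expect_lt(hi$K, 1e-5)
  expect_gt(hi$alpha, 1)
  # K monotone decreasing in porosity on (0.3, 1)
  ks <- vapply(seq(0.3, 0.99, by = 0.01),
               function(b) screen_coefficients(b, 30)$K, 0)
  expect_true(all(diff(ks) < 0))
  expect_error(screen_coefficients(1.2), "porosity")
})

test_that("a near-transparent screen leaves the channel solution unchanged", {
  cf <- channel_field()
  fp <- cf$problem
  fp2 <- add_screen(fp, c(4, -0.5, 4, 0.5),
                    screen_coefficients(0.9999, 30))
  ff2 <- solve_flow(fp2, cf$waveform, steady = TRUE, steady_tol = 1e-4)
  expect_equal(max(abs(ff2$u[[1]] - cf$field$u[[1]])), 0,
               tolerance = 1e-4 * max(abs(cf$field$u[[1]])))
})

test_that("the inflow-reduction formula is the stated relative-inflow ratio", {
  expect_equal(inflow_reduction(1, 1), 0)
  expect_equal(inflow_reduction(1.000, 0.313), 68.7)
  expect_equal(inflow_reduction(5, 0), 100)
  expect_error(inflow_reduction(0, 1), "positive")
})

test_that("lumped junction solves match closed forms and stay affine", {
  nw <- lumped_network(c(5, 5), inlet_flow = 120, bias_sweep = c(0, 300))
  out <- solve_lumped(nw)
  expect_equal(out$Q1[1], 60); expect_equal(out$Q2[1], 60)
  expect_equal(out$Q1[2], 30); expect_equal(out$Q2[2], 90)
  expect_equal(out$stented_fraction[2], 0.75)
  # stented fraction affine in bias while jailed flow stays positive
  nw2 <- lumped_network(c(4, 6), inlet_flow = 200,
                        bias_sweep = seq(0, 300, by = 50))
  o2 <- solve_lumped(nw2)
  expect_lt(max(abs(diff(diff(o2$stented_fraction)))), 1e-12)
  expect_true(all(diff(o2$Q1) < 0))  # jailed flow monotone decreasing
})

test_that("independence checks flag the first sub-threshold refinement", {
  expect_identical(independence_check(c(10, 10))$index, 1L)
  expect_identical(independence_check(c(12, 10.5, 10.05, 10.04))$index, 3L)
  expect_true(is.na(independence_check(c(1, 2, 1, 2, 1))$index))
})

test_that("domain rasterization enforces resolution and connectivity", {
  tube <- make_straight_vessel(3, 15, build_surface = FALSE)
  expect_error(rasterize_domain(tube, resolution = 4), "at least 8")
  fp3 <- rasterize_domain(tube, resolution = 10, mode = "3D")
  frac <- mean(fp3$fluid[round(fp3$nx / 2), , ])
  expect_lt(abs(frac / (pi / 4) - 1), 0.05)
  # refining the grid changes the tube volume estimate by < 2%
  v1 <- sum(fp3$fluid) * fp3$h_mm^3
  fp3b <- rasterize_domain(tube, resolution = 20, mode = "3D")
  v2 <- sum(fp3b$fluid) * fp3b$h_mm^3
  expect_lt(abs(v1 / v2 - 1), 0.02)
})

test_that("coarse 3D tube flow recovers Poiseuille wall shear", {
  tube <- make_straight_vessel(3, 15, build_surface = FALSE)
  fp <- rasterize_domain(tube, resolution = 14, mode = "3D")
  U <- 0.08
  Q <- U * pi * 0.0015^2 * 6e7
  wf <- make_waveform("custom", mean_flow = Q, flow_range = c(0.5 * Q, 2 * Q))
  ff <- solve_flow(fp, wf, steady = TRUE)
  mid <- ff$u[round(fp$nx * 0.7), , ]
  expect_lt(abs(max(mid) / (2 * U) - 1), 0.06)
  w <- stentflow:::compute_wss3d(ff)
  expect_lt(abs(w$mean / (4 * 0.004 * U / 0.0015) - 1), 0.10)
})

test_that("screened fixture reduces aneurysm inflow and honors mass balance", {
  fx <- fixture_flows()
  q0 <- aneurysm_inflow(fx$f0, fx$np)
  q1 <- aneurysm_inflow(fx$f1, fx$np)
  red <- inflow_reduction(q0$mean, q1$mean)
  expect_gt(red, 50)
  expect_lt(red, 100)
  for (f in list(fx$f0, fx$f1))
    expect_lt(abs(f$inlet_flux - sum(f$outlet_flux)) / f$inlet_flux, 0.001)
  # symmetric untreated fixture splits flow evenly, matching the lumped
  # junction solve with equal branch resistances
  split_fv <- fx$f0$outlet_flux / sum(fx$f0$outlet_flux)
  lm <- solve_lumped(lumped_network(c(5, 5), inlet_flow = 230,
                                    bias_sweep = 0))
  expect_lt(abs(split_fv[2] - lm$stented_fraction[1]), 0.10)
  # dome WSS is reduced by the screen
  gx <- rep(fx$fp0$xs, times = fx$fp0$ny)
  gy <- rep(fx$fp0$ys, each = fx$fp0$nx)
  # evaluate away from the screen edge (local vorticity at the struts
  # contaminates the first cells above the neck plane)
  dome <- matrix(stentflow:::in_dome_region(fx$geom, cbind(gx, gy)) &
                   gy > fx$geom$dome$y_neck + 1, fx$fp0$nx, fx$fp0$ny)
  w0 <- compute_wss(fx$f0, region = dome)
  w1 <- compute_wss(fx$f1, region = dome)
  expect_lt(w1$peak, w0$peak)
  expect_lt(w1$mean, w0$mean)
})

test_that("jailed-outlet pressure bias obeys the weak-coupling bounds", {
  fx <- fixture_flows()
  geom <- fx$geom
  # tuned fixture: distal resistances put the inlet-outlet gradient at the
  # post-device level; untreated baseline in the same configuration
  R <- c(3e5, 3e5)
  fp0t <- rasterize_domain(geom, resolution = 8, outlet_resistances = R)
  f0t <- solve_flow(fp0t, fx$wf, steady = TRUE)
  q0 <- aneurysm_inflow(f0t, fx$np)$mean
  fluxes <- numeric(0); reds <- numeric(0)
  for (b in c(0, 300)) {
    fp <- rasterize_domain(geom, resolution = 8,
                           outlet_pressures = c(b, 0),
                           outlet_resistances = R)
    fp <- add_device_screens(fp)
    fp$init <- list(u = f0t$u[[1]], v = f0t$v[[1]], p = f0t$p)
    fb <- solve_flow(fp, fx$wf, steady = TRUE)
    fluxes <- c(fluxes, fb$outlet_flux[1])
    reds <- c(reds, inflow_reduction(q0, aneurysm_inflow(fb, fx$np)$mean))
  }
  # jailed-branch flow drops monotonically under the bias
  expect_lt(fluxes[2], fluxes[1])
  # change in device-induced inflow reduction stays below 11 points
  expect_lte(reds[2] - reds[1], 11)
})
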