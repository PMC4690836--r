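# short pulsatile channel flow reused across transport tests
channel_pulse <- function() cached("channel_pulse", function() {
  tube <- make_straight_vessel(1, 20, build_surface = FALSE)
  fp <- rasterize_domain(tube, resolution = 8)
  U <- 0.05
  Q <- U * pi * 0.0005^2 * 6e7
  wf <- make_waveform("custom", mean_flow = Q,
                      flow_range = c(0.98 * Q, 1.02 * Q))
  list(field = solve_flow(fp, wf, n_cycles = 1, dt = 0.02), U = U, fp = fp)
})

test_that("pure advection moves a sharp front at the flow speed", {
  cp <- channel_pulse()
  tpar <- transport_params(diffusivity = 0, bolus_start = 0.1,
                           bolus_duration = 10)
  cf <- transport_contrast(cp$field, tpar)
  # bounded scheme: no over/undershoot
  rng <- range(vapply(cf$concentration, range, numeric(2)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1 + 1e-6)
  # centerline front position ~ 1.5 U t (parabolic peak) within one cell
  k <- which.min(abs(cf$times - 0.3))
  p <- cf$concentration[[k]]
  mid <- p[, round(ncol(p) / 2)]
  xf <- cp$fp$xs[max(which(mid > 0.5))]
  expect_lt(abs(xf - 1.5 * cp$U * 1000 * (0.3 - 0.1)), 2 * cp$fp$h_mm)
  # scalar mass balance: cumulative boundary flux equals stored mass
  expect_lt(max(abs(cf$mass - cf$net_influx)) / max(cf$mass), 0.005)
})

test_that("zero velocity and no bolus keeps the scalar identically zero", {
  cp <- channel_pulse()
  still <- cp$field
  still$u <- lapply(still$u, function(m) m * 0)
  still$v <- lapply(still$v, function(m) m * 0)
  cf <- transport_contrast(still, transport_params(0, bolus_start = 0.5,
                                                   bolus_duration = 1))
  expect_identical(max(vapply(cf$concentration, max, 0)), 0)
})

test_that("residence curves are volume-weighted dome means", {
  cp <- channel_pulse()
  cf <- transport_contrast(cp$field,
                           transport_params(0, bolus_start = 0.1,
                                            bolus_duration = 10))
  mask <- cp$fp$fluid
  rc <- residence_curve(cf, dome_mask = mask)
  # brute-force oracle on the final snapshot
  expect_equal(rc$concentration[length(rc$concentration)],
               mean(cf$concentration[[length(cf$times)]][mask]))
  # uniform and half/half fields
  cf1 <- cf
  cf1$concentration[[1]][] <- 1
  expect_equal(residence_curve(cf1, mask)$concentration[1], 1)
  half <- cf$concentration[[1]]; half[] <- 0
  half[seq_len(nrow(half) / 2), ] <- 1
  hmask <- mask; hmask[] <- TRUE
  cf1$concentration[[1]] <- half
  expect_equal(residence_curve(cf1, hmask)$concentration[1], 0.5,
               tolerance = 0.02)
  expect_error(residence_curve(cf, dome_mask = mask & FALSE), "empty")
})

test_that("exponential decay fits recover known rates", {
  tt <- seq(0, 6, by = 0.01)
  # exact exponential: rate 2, perfect fit
  f1 <- fit_exponential_decay(data.frame(time = tt,
                                         concentration = exp(-2 * tt)))
  expect_equal(f1$rate, 2, tolerance = 0.005)
  expect_equal(f1$r_squared, 1, tolerance = 1e-9)
  # the untreated reference rate used in the angiographic comparison
  f2 <- fit_exponential_decay(data.frame(time = tt,
                                         concentration = exp(-3.86 * tt)))
  expect_equal(f2$rate, 3.86, tolerance = 0.005)
  # noiseless recovery across the physiological range, within 2%
  for (r in c(0.5, 1.5, 3, 5)) {
    fr <- fit_exponential_decay(data.frame(time = tt,
                                           concentration = exp(-r * tt)))
    expect_lt(abs(fr$rate / r - 1), 0.02)
  }
  # multiplicative noise, seeded: within 5%
  set.seed(0)
  cc <- exp(-2 * tt) * exp(stats::rnorm(length(tt), 0, 0.02))
  fn <- fit_exponential_decay(data.frame(time = tt, concentration = cc))
  expect_lt(abs(fn$rate / 2 - 1), 0.05)
  # truncated decay warns and flags
  expect_warning(
    ft <- fit_exponential_decay(data.frame(time = tt[tt < 0.5],
                                           concentration = exp(-2 * tt[tt < 0.5]))),
    "10%")
  expect_true(ft$truncated)
})

test_that("decay-rate reduction follows the stated formula", {
  expect_equal(decay_rate_reduction(2, 2), 0)
  expect_equal(decay_rate_reduction(3.86, 1.46), 62.17617, tolerance = 1e-6)
  expect_equal(decay_rate_reduction(2, 0), 100)
  expect_error(decay_rate_reduction(0, 1), "positive")
})

test_that("angiogram projection follows Beer-Lambert attenuation", {
  cp <- channel_pulse()
  cf <- transport_contrast(cp$field,
                           transport_params(0, bolus_start = 0.1,
                                            bolus_duration = 10))
  # zero concentration -> uniform background frame
  cf0 <- cf; cf0$concentration <- lapply(cf$concentration, function(p) p * 0)
  ag0 <- render_angiogram(cf0)
  expect_identical(max(vapply(ag0$frames, max, 0)), 0)
  # uniform phi = 1 through a known path length
  cfu <- cf; cfu$concentration[[1]][] <- 1
  kap <- 500
  agu <- render_angiogram(cfu, kappa = kap)
  expect_equal(agu$frames[[1]][1, 1], 1 - exp(-kap * cp$fp$h),
               tolerance = 1e-12)
  # kappa -> 0: intensity proportional to the path integral
  ag_small <- render_angiogram(cfu, kappa = 1e-4)
  ratio <- ag_small$frames[[1]][1, 1] / (1e-4 * cp$fp$h)
  expect_equal(ratio, 1, tolerance = 1e-3)
  # frames can be written as PNG files
  dir <- tempfile()
  render_angiogram(cf, out_dir = dir)
  expect_gt(length(list.files(dir, pattern = "\\.png$")), 0)
})
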