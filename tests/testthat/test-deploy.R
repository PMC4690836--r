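test_that("spring network construction follows the stiffness forms", {
  # two-node single strut: one linear spring, no torsional springs
  one <- structure(list(
    nodes = rbind(c(0, 0, 0), c(0, 0, 0.2)),
    struts = matrix(c(1L, 2L), 1), strand_id = 1L,
    wire_diameter = 30, reference_diameter = 1, reference_length = 0.2,
    current_diameter = 1, current_length = 0.2, strand_turns = 1,
    n_strands = 2L, node_z = c(0, 0.2), node_theta = c(0, 0)),
    class = "device_mesh")
  net1 <- build_spring_network(one)
  expect_identical(length(net1$lin$k), 1L)
  expect_identical(length(net1$tor$a), 0L)
  # EA/L arithmetic: w = 30 um, L0 = 200 um, unit modulus
  expect_equal(net1$lin$k, pi * (15e-6)^2 / 200e-6, tolerance = 1e-10)
  degen <- one
  degen$nodes[2, 3] <- 0
  expect_error(build_spring_network(degen), "zero-length")
})

test_that("crimping stores elastic energy relative to the reference braid", {
  net <- small_network()
  expect_gt(stentflow:::spring_energy(net), 0)
  expect_equal(stentflow:::spring_energy(net, net$ref_nodes), 0,
               tolerance = 1e-20)
})

test_that("release schedules partition nodes distal to proximal", {
  dev <- small_device()
  sch <- plan_release_schedule(dev, 10)
  all_nodes <- sort(unlist(sch$bands))
  expect_identical(all_nodes, seq_len(nrow(dev$nodes)))
  sizes <- lengths(sch$bands)
  expect_lte(diff(range(sizes)), 1L)
  # first band is the distal tip (largest axial coordinate)
  expect_gte(min(dev$node_z[sch$bands[[1]]]),
             max(dev$node_z[sch$bands[[10]]]))
  expect_identical(length(plan_release_schedule(dev, 1)$bands), 1L)
  expect_error(plan_release_schedule(dev, nrow(dev$nodes) + 1L), "bands")
})

test_that("an undersized device expands freely to its nominal diameter", {
  net <- small_network(3.0)
  tube <- make_straight_vessel(3.5, 30, build_surface = FALSE)
  dep <- deploy(net, tube)
  expect_true(dep$converged)
  r <- sqrt(dep$nodes[, 2]^2 + dep$nodes[, 3]^2)
  expect_lt(abs(2 * mean(r) / 3.0 - 1), 0.02)
  # apposition gap of the undersized device ~ (tube - device) / 2
  ap <- apposition(dep)
  expect_equal(ap$mean, (3.5 - 3.0) / 2 - net$wire_radius_mm,
               tolerance = 0.1)
})

test_that("an oversized device apposes the wall at the vessel diameter", {
  net <- small_network(3.5)
  tube <- make_straight_vessel(3.0, 30, build_surface = FALSE)
  dep <- deploy(net, tube)
  expect_true(dep$converged)
  r_out <- sqrt(dep$nodes[, 2]^2 + dep$nodes[, 3]^2) + net$wire_radius_mm
  expect_lt(abs(2 * max(r_out) / 3.0 - 1), 0.02)
  ap <- apposition(dep)
  expect_lt(ap$max, 0.1)
  expect_equal(ap$fraction_over_0.1mm, 0)
  # no node penetrates the wall beyond tolerance
  expect_lte(max(tube$sdf3(dep$nodes)), -net$wire_radius_mm + 1e-6)
})

test_that("curved-vessel deployment compresses the inner bend", {
  tube <- make_straight_vessel(3.0, 25, curvature_radius = 10,
                               build_surface = FALSE)
  spec <- suppressWarnings(device_spec(3.5, 12, 16, strand_turns = 3))
  net <- build_spring_network(crimp_device(generate_device(spec), 1.2)$mesh)
  dep <- deploy(net, tube, max_iters = 1500)
  expect_true(dep$converged)
  # arc center at (0, 10): inner-bend gaps <= outer-bend gaps
  dctr <- sqrt(dep$nodes[, 1]^2 + (dep$nodes[, 2] - 10)^2)
  gap <- pmax(-tube$sdf3(dep$nodes) - net$wire_radius_mm, 0)
  expect_lte(mean(gap[dctr < 10]), mean(gap[dctr >= 10]) + 1e-6)
})

test_that("relaxation energy is non-increasing for plain damped iteration", {
  net <- small_network(3.0)
  tube <- make_straight_vessel(3.5, 30, build_surface = FALSE)
  dep <- deploy(net, tube, momentum = 0, eta = 0.05, max_iters = 300,
                pre_expand = FALSE,
                schedule = plan_release_schedule(net$mesh, 1))
  de <- diff(dep$energy)
  expect_lte(max(de), 1e-9 * max(dep$energy))
})

test_that("deployment is deterministic", {
  net <- small_network(3.5)
  tube <- make_straight_vessel(3.0, 30, build_surface = FALSE)
  d1 <- deploy(net, tube, max_iters = 400)
  d2 <- deploy(net, tube, max_iters = 400)
  expect_identical(d1$nodes, d2$nodes)
  expect_identical(d1$residual, d2$residual)
})

test_that("local metal coverage of the expanded braid matches its porosity", {
  # uniformly expanded commercial-class lattice over a flat neck: coverage
  # ~ 1 - porosity = 0.30
  dev <- reference_device()
  cvr_th <- 1 - sqrt(0.70)        # per-family coverage of the 70% braid
  s_perp <- (30e-3) / cvr_th
  mesh <- flat_lattice_mesh(s_mm = s_perp, wire_um = 30, psi_deg = 66)
  neck <- structure(list(point = c(0, 0, 0), normal = c(0, 1, 0),
                         radius = 2.5), class = "neck_plane")
  cov <- local_metal_coverage(mesh, neck)
  expect_lt(abs(cov - 0.30), 0.02)
  # doubling the strut density roughly doubles coverage minus overlap
  dense <- flat_lattice_mesh(s_mm = s_perp / 2, wire_um = 30, psi_deg = 66)
  cov2 <- local_metal_coverage(dense, neck)
  c1 <- 2 * cvr_th
  expect_lt(abs(cov2 - diamond_lattice_coverage(c1)), 0.03)
  # no struts near the plane -> error
  far <- structure(list(point = c(0, 50, 0), normal = c(0, 1, 0),
                        radius = 2.5), class = "neck_plane")
  expect_error(local_metal_coverage(mesh, far), "no device struts")
})
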