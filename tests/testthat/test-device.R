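test_that("diamond-lattice coverage closed form matches the union formula", {
  # one family covers w/d; two crossed families: 2c - c^2
  expect_equal(diamond_lattice_coverage(0.162), 2 * 0.162 - 0.162^2)
  expect_equal(diamond_lattice_coverage(0.162), 0.297756)
  expect_equal(diamond_lattice_coverage(0), 0)
  expect_equal(diamond_lattice_coverage(1), 1)
})

test_that("generated braid hits the target porosity and its invariants", {
  dev <- reference_device()
  # nodes on the reference cylinder
  r <- sqrt(dev$nodes[, 1]^2 + dev$nodes[, 2]^2)
  expect_lt(max(abs(r - dev$reference_diameter / 2)), 1e-6)
  # interior nodes have degree 4 (crossings) or 2; ends may dangle
  deg <- tabulate(c(dev$struts[, 1], dev$struts[, 2]), nbins = nrow(dev$nodes))
  interior <- dev$node_z > 0.5 & dev$node_z < dev$reference_length - 0.5
  expect_true(all(deg[interior] %in% c(2L, 4L)))
  expect_true(all(deg >= 1L))
  # connected strut graph (BFS over the adjacency)
  n <- nrow(dev$nodes)
  adj <- split(c(dev$struts[, 2], dev$struts[, 1]),
               c(dev$struts[, 1], dev$struts[, 2]))
  seen <- logical(n); frontier <- 1L; seen[1] <- TRUE
  while (length(frontier)) {
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    frontier <- nxt[!seen[nxt]]
    seen[frontier] <- TRUE
  }
  expect_true(all(seen))
  # measured porosity within a point of the 70% target
  expect_lt(abs(measure_porosity(dev) - 0.70), 0.01)
})

test_that("rasterized porosity agrees with the closed form on a flat lattice", {
  # w/d = 30/185 -> coverage 2c - c^2
  mesh <- flat_lattice_mesh(s_mm = 0.185, wire_um = 30)
  cvr <- 30e-3 / 0.185
  # use the neck-plane coverage rasterizer over a disk inside the patch
  neck <- structure(list(point = c(0, 0, 0), normal = c(0, 1, 0),
                         radius = 2.5), class = "neck_plane")
  got <- local_metal_coverage(mesh, neck)
  expect_lt(abs(got - diamond_lattice_coverage(cvr)), 0.02)
})

test_that("zero wire diameter gives porosity one; infeasible targets error", {
  dev <- suppressWarnings(generate_device(device_spec(3.5, 20, strand_turns = 4)))
  dev$wire_diameter <- 0
  expect_identical(measure_porosity(dev), 1.0)
  expect_error(generate_device(device_spec(3.5, 20, n_strands = 96,
                                           wire_diameter = 60,
                                           target_porosity = 0.95)),
               "achievable range")
})

test_that("crimping reaches the catheter with strand length conserved", {
  dev <- reference_device()
  cr <- crimp_device(dev, 1.0)
  expect_equal(cr$report$crimped_diameter, 1.0)
  expect_lt(cr$report$strand_length_error, 0.01)
  expect_gte(cr$report$crimped_length, dev$reference_length)
  # a 3.0 mm device into a 1.0 mm catheter: 33% of nominal
  d3 <- suppressWarnings(generate_device(device_spec(3.0, 20)))
  c3 <- crimp_device(d3, 1.0)
  expect_equal(100 * c3$report$crimped_diameter / 3.0, 33.3, tolerance = 0.01)
  # identity crimp leaves the mesh unchanged
  cid <- crimp_device(dev, dev$reference_diameter)
  expect_equal(cid$mesh$nodes, dev$nodes, tolerance = 1e-12)
  expect_equal(cid$report$crimped_length, dev$reference_length)
  # helix arc-length oracle: 2 turns, D = 3, L = 20 -> S = 27.48 mm;
  # crimped to D = 1: L' = sqrt(S^2 - (2 pi 0.5 * 2)^2) = 26.755
  S <- sqrt(20^2 + (pi * 3 * 2)^2)
  Lc <- sqrt(S^2 - (pi * 1 * 2)^2)
  dev2 <- suppressWarnings(generate_device(
    device_spec(3, 20, n_strands = 16, strand_turns = 2)))
  cr2 <- crimp_device(dev2, 1.0)
  expect_equal(cr2$report$crimped_length, Lc, tolerance = 1e-3)
  expect_error(crimp_device(dev, 0.05), "lumen")
  expect_error(crimp_device(dev, 5), "exceeds")
})

test_that("pore diameters of the device family fall in the commercial range", {
  # diamond cell oracle: perpendicular spacing 185 um, wire 30 um ->
  # inscribed disk ~ 155 um (distance transform on the rasterized cell)
  dev <- reference_device()
  pd <- measure_pore_diameter(dev)
  m <- dev$n_strands / 2
  cospsi <- dev$reference_length /
    sqrt(dev$reference_length^2 + (dev$strand_turns * pi * dev$reference_diameter)^2)
  s_perp <- pi * dev$reference_diameter * cospsi / m * 1000
  expect_equal(pd, s_perp - 30, tolerance = 0.08)
  for (D in c(2.0, 5.0)) {
    dk <- generate_device(device_spec(D, 20))
    pk <- measure_pore_diameter(dk)
    expect_gte(pk, 120); expect_lte(pk, 260)
  }
  expect_gte(pd, 120); expect_lte(pd, 260)
})

test_that("swept struts form tubes of the wire radius around the centerlines", {
  dev <- small_device()
  surf <- sweep_struts(dev, n_sides = 6)
  expect_gt(nrow(surf$faces), 0)
  # sampled vertices lie within the wire radius of some strut centerline
  set.seed(1)
  pick <- sample(nrow(surf$vertices), 200)
  r_w <- dev$wire_diameter / 2000
  dmin <- rep(Inf, length(pick))
  P <- surf$vertices[pick, , drop = FALSE]
  for (s in seq_len(nrow(dev$struts))) {
    dmin <- pmin(dmin, stentflow:::point_seg_dist3(P, dev$nodes[dev$struts[s, 1], ],
                                       dev$nodes[dev$struts[s, 2], ]))
  }
  expect_lt(max(dmin), r_w + 1e-9)
  # single straight strut: lateral area ~ pi * w * L
  one <- dev
  one$nodes <- rbind(c(0, 0, 0), c(0, 0, 5))
  one$struts <- matrix(c(1L, 2L), 1)
  one$strand_id <- 1L
  s1 <- sweep_struts(one, n_sides = 64)
  a <- s1$vertices[s1$faces[, 1], ]; b <- s1$vertices[s1$faces[, 2], ]
  c3m <- s1$vertices[s1$faces[, 3], ]
  area <- sum(0.5 * sqrt(rowSums(stentflow:::cross3(b - a, c3m - a)^2)))
  w_mm <- dev$wire_diameter / 1000
  expect_equal(area, pi * w_mm * 5 + 2 * pi * (w_mm / 2)^2 / 2,
               tolerance = 0.02)
  # crimped device sweep stays inside catheter + wire radius
  cr <- crimp_device(dev, 1.0)$mesh
  sc <- sweep_struts(cr)
  rad <- sqrt(sc$vertices[, 1]^2 + sc$vertices[, 2]^2)
  expect_lte(max(rad), 0.5 + r_w + 1e-9)
})
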