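# Shared lazily-built fixtures. Everything is generated in code at test
# time; heavier objects are cached per session in this environment.
.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.cache[[name]])) .cache[[name]] <- builder()
  .cache[[name]]
}

# commercial-class braided device at 3.5 mm nominal
reference_device <- function() cached("reference_device", function() {
  generate_device(device_spec(3.5, 20))
})

# small braid for deployment tests (coarse but same topology)
small_device <- function(diameter = 3.0) cached(
  paste0("small_device_", diameter), function() {
    suppressWarnings(generate_device(
      device_spec(diameter, 12, n_strands = 12, strand_turns = 2.5)))
  })

# crimped small network
small_network <- function(diameter = 3.0) cached(
  paste0("small_net_", diameter), function() {
    build_spring_network(crimp_device(small_device(diameter), 1.0)$mesh)
  })

# narrow channel and its converged steady Poiseuille solution
channel_field <- function() cached("channel_field", function() {
  tube <- make_straight_vessel(1, 8, build_surface = FALSE)
  fp <- rasterize_domain(tube, resolution = 16)
  U <- 0.1
  Q <- U * pi * 0.0005^2 * 6e7
  wf <- make_waveform("custom", mean_flow = Q, flow_range = c(0.4 * Q, 2.2 * Q))
  list(field = solve_flow(fp, wf, steady = TRUE, steady_tol = 1e-4),
       U = U, problem = fp, waveform = wf, tube = tube)
})

# coarse untreated/screened steady solves of the aneurysm fixture
fixture_flows <- function() cached("fixture_flows", function() {
  geom <- aneurysm_fixture()
  wf <- make_waveform("ICA")
  np <- define_neck_plane(geom, offset = 0.5)
  fp0 <- rasterize_domain(geom, resolution = 8)
  f0 <- solve_flow(fp0, wf, steady = TRUE)
  fp1 <- add_device_screens(fp0)
  fp1$init <- list(u = f0$u[[1]], v = f0$v[[1]], p = f0$p)
  f1 <- solve_flow(fp1, wf, steady = TRUE)
  list(geom = geom, wf = wf, np = np, fp0 = fp0, fp1 = fp1, f0 = f0, f1 = f1)
})

# uniform flat diamond lattice as a device_mesh, for coverage oracles:
# two crossed strut families at +-psi from the y axis with perpendicular
# spacing s_mm, spanning a [-ext, ext]^2 patch in the (x, z) plane at y = 0.
flat_lattice_mesh <- function(s_mm, wire_um, psi_deg = 60, ext = 4) {
  psi <- psi_deg * pi / 180
  nodes <- NULL; struts <- NULL; strand <- NULL
  sid <- 0L
  for (sgn in c(-1, 1)) {
    dirv <- c(sin(psi) * sgn, cos(psi))          # in-plane direction (x, z)
    nrm <- c(dirv[2], -dirv[1])
    offs <- seq(-2 * ext, 2 * ext, by = s_mm)
    for (o in offs) {
      sid <- sid + 1L
      a <- o * nrm - 3 * ext * dirv
      b <- o * nrm + 3 * ext * dirv
      i0 <- nrow(nodes %||% matrix(0, 0, 3))
      nodes <- rbind(nodes, c(a[1], 0, a[2]), c(b[1], 0, b[2]))
      struts <- rbind(struts, c(i0 + 1L, i0 + 2L))
      strand <- c(strand, sid)
    }
  }
  structure(list(nodes = nodes, struts = struts, strand_id = strand,
                 wire_diameter = wire_um, reference_diameter = 2 * ext,
                 reference_length = 2 * ext, current_diameter = 2 * ext,
                 current_length = 2 * ext, strand_turns = 1,
                 n_strands = sid, node_z = nodes[, 3],
                 node_theta = rep(0, nrow(nodes))),
            class = "device_mesh")
}
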