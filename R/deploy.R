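#' Build the spring network of a device mesh
#'
#' Every strut becomes a linear spring with stiffness in the axial EA/L
#' form, \eqn{k = \pi (w/2)^2 E / L_0} (SI, per unit modulus
#' `stiffness_scale`); every interior along-strand node triple becomes a
#' torsional (bending) spring in the EI/L form,
#' \eqn{k_\theta = c_\theta \pi (w/2)^4 E / (4 L_0)}. Rest lengths and rest
#' angles are taken from the reference (uncrimped) configuration, so a
#' crimped network stores elastic energy that drives re-expansion. The
#' bending constant is augmented (default `torsion_scale = 400`) to account
#' for crossing-point interlock of the braid, which pure wire bending
#' stiffness does not capture; it scales with the mandated w^4/L form.
#'
#' @param mesh A `device_mesh` (typically crimped).
#' @param stiffness_scale Young's-modulus scale (arbitrary units; the
#'   equilibrium is independent of it).
#' @param torsion_scale Multiplier on the bending stiffness.
#' @return A `spring_network`.
#' @export
build_spring_network <- function(mesh, stiffness_scale = 1,
                                 torsion_scale = 400) {
  stopifnot(inherits(mesh, "device_mesh"))
  ref <- mesh$ref_nodes %||% mesh$nodes
  w_m <- mesh$wire_diameter * 1e-6
  r_m <- w_m / 2
  d <- ref[mesh$struts[, 1], , drop = FALSE] - ref[mesh$struts[, 2], , drop = FALSE]
  L0 <- row_norm(d)                          # mm
  if (any(L0 < 1e-9)) stop("zero-length strut in device mesh")
  k_lin <- stiffness_scale * pi * r_m^2 / (L0 * 1e-3)

  # along-strand triples from the per-strand strut chains
  trip <- vector("list", max(mesh$strand_id))
  for (s in seq_len(max(mesh$strand_id))) {
    st <- mesh$struts[mesh$strand_id == s, , drop = FALSE]
    chain <- c(st[1, 1], st[, 2])            # struts are stored in chain order
    if (length(chain) >= 3L)
      trip[[s]] <- cbind(chain[-c(length(chain) - 1L, length(chain))],
                         chain[-c(1L, length(chain))],
                         chain[-c(1L, 2L)])
  }
  trip <- do.call(rbind, trip)
  if (is.null(trip)) trip <- matrix(integer(0), 0, 3)
  ang0 <- if (nrow(trip)) triple_angles(ref, trip) else numeric(0)
  Lbar <- 1e-3 * (L0[1] + stats::median(L0)) / 2
  k_tor <- torsion_scale * stiffness_scale * pi * r_m^4 / (4 * Lbar)
  k_tor <- rep(k_tor, nrow(trip))

  # Crossing-interlock (diamond-diagonal) springs. Bend angles plus strut
  # lengths alone leave the discrete strands free to writhe (the dihedral
  # degrees of freedom are unconstrained), so a braid could fold up
  # isometrically without energy penalty. The interlocked crossings of a
  # real braid resist cell scissoring; they are modeled as weak linear
  # springs along both diagonals of every diamond cell, with stiffness at
  # the bending scale gamma ~ (w/L)^2 relative to the axial springs.
  m2 <- max(mesh$strand_id) / 2L
  succ_p <- integer(nrow(ref)); succ_m <- integer(nrow(ref))
  for (s in seq_len(max(mesh$strand_id))) {
    st <- mesh$struts[mesh$strand_id == s, , drop = FALSE]
    if (s <= m2) succ_p[st[, 1]] <- st[, 2] else succ_m[st[, 1]] <- st[, 2]
  }
  dg_i <- integer(0); dg_j <- integer(0)
  has_both <- which(succ_p > 0L & succ_m > 0L)
  for (nn in has_both) {
    b <- succ_p[nn]; cc2 <- succ_m[nn]
    d1 <- succ_m[b]
    if (d1 > 0L && succ_p[cc2] == d1) {
      dg_i <- c(dg_i, nn, b); dg_j <- c(dg_j, d1, cc2)
    }
  }
  gamma_il <- (w_m / (stats::median(L0) * 1e-3))^2
  diag_L0 <- row_norm(ref[dg_i, , drop = FALSE] - ref[dg_j, , drop = FALSE])
  k_diag <- torsion_scale / 400 * gamma_il * stiffness_scale * pi * r_m^2 /
    (diag_L0 * 1e-3)

  # per-node stiffness normalization for the damped pseudo-dynamic steps:
  # scaled to the bending stiffness, since axial stretch is handled by
  # constraint projection (inextensible-wire limit, EA >> EI/L^2)
  kt_eff <- stats::median(k_tor) / (Lbar^2) * 1e-3
  knorm <- numeric(nrow(ref))
  for (cc in 1:3) {
    tb <- tabulate(trip[, cc], nbins = nrow(ref))
    knorm <- knorm + tb * kt_eff
  }
  if (length(dg_i)) {
    tb <- tabulate(dg_i, nbins = nrow(ref)) + tabulate(dg_j, nbins = nrow(ref))
    knorm <- knorm + tb * stats::median(k_diag) * 1e-3
  }
  knorm <- knorm + 1e-3 * kt_eff

  structure(list(nodes = mesh$nodes, ref_nodes = ref,
                 lin = list(i = mesh$struts[, 1], j = mesh$struts[, 2],
                            k = k_lin, L0 = L0),
                 tor = list(a = trip[, 1], b = trip[, 2], c = trip[, 3],
                            k = k_tor, theta0 = ang0),
                 diag = list(i = dg_i, j = dg_j, k = k_diag, L0 = diag_L0),
                 knorm = knorm, wire_radius_mm = mesh$wire_diameter / 2000,
                 mesh = mesh), class = "spring_network")
}

# Angles at node triples (a-b-c), radians.
triple_angles <- function(P, trip) {
  e1 <- P[trip[, 1], , drop = FALSE] - P[trip[, 2], , drop = FALSE]
  e2 <- P[trip[, 3], , drop = FALSE] - P[trip[, 2], , drop = FALSE]
  n1 <- row_norm(e1); n2 <- row_norm(e2)
  cosang <- rowSums(e1 * e2) / pmax(n1 * n2, 1e-30)
  acos(pmin(pmax(cosang, -1), 1))
}

# Total spring energy (linear + torsional), per unit modulus.
spring_energy <- function(net, P = net$nodes) {
  d <- P[net$lin$i, , drop = FALSE] - P[net$lin$j, , drop = FALSE]
  L <- row_norm(d)
  e_lin <- 0.5 * sum(net$lin$k * ((L - net$lin$L0) * 1e-3)^2)
  th <- triple_angles(P, cbind(net$tor$a, net$tor$b, net$tor$c))
  e_tor <- 0.5 * sum(net$tor$k * (th - net$tor$theta0)^2)
  e_diag <- 0
  if (length(net$diag$i)) {
    Ld <- row_norm(P[net$diag$i, , drop = FALSE] - P[net$diag$j, , drop = FALSE])
    e_diag <- 0.5 * sum(net$diag$k * ((Ld - net$diag$L0) * 1e-3)^2)
  }
  e_lin + e_tor + e_diag
}

# Nodal forces of all springs (rows = nodes). Displacements are mm; the
# absolute force scale is arbitrary (relaxation normalizes by stiffness).
spring_forces <- function(net, P = net$nodes) {
  F <- matrix(0, nrow(P), 3L)
  d <- P[net$lin$j, , drop = FALSE] - P[net$lin$i, , drop = FALSE]
  L <- row_norm(d)
  dirs <- d / pmax(L, 1e-12)
  fmag <- net$lin$k * (L - net$lin$L0) * 1e-3       # pull positive
  fv <- dirs * fmag
  F <- accumulate_rows(F, net$lin$i, fv)
  F <- accumulate_rows(F, net$lin$j, -fv)

  a <- net$tor$a; b <- net$tor$b; cc <- net$tor$c
  e1 <- P[a, , drop = FALSE] - P[b, , drop = FALSE]
  e2 <- P[cc, , drop = FALSE] - P[b, , drop = FALSE]
  n1 <- pmax(row_norm(e1), 1e-12); n2 <- pmax(row_norm(e2), 1e-12)
  u1 <- e1 / n1; u2 <- e2 / n2
  cosang <- rowSums(u1 * u2)
  cosang <- pmin(pmax(cosang, -1), 1)
  th <- acos(cosang)
  sinth <- pmax(sqrt(1 - cosang^2), 1e-6)
  mom <- net$tor$k * (th - net$tor$theta0)          # restoring moment
  # grad_a theta = -(u2 - cos*u1) / (|e1| sin); grad_c symmetric
  ga <- -(u2 - cosang * u1) / (n1 * sinth * 1e-3)
  gc <- -(u1 - cosang * u2) / (n2 * sinth * 1e-3)
  Fa <- -mom * ga
  Fc <- -mom * gc
  F <- accumulate_rows(F, a, Fa)
  F <- accumulate_rows(F, cc, Fc)
  F <- accumulate_rows(F, b, -(Fa + Fc))

  if (length(net$diag$i)) {
    dd <- P[net$diag$j, , drop = FALSE] - P[net$diag$i, , drop = FALSE]
    Ld <- pmax(row_norm(dd), 1e-12)
    fd <- (net$diag$k * (Ld - net$diag$L0) * 1e-3) * (dd / Ld)
    F <- accumulate_rows(F, net$diag$i, fd)
    F <- accumulate_rows(F, net$diag$j, -fd)
  }
  F
}

# Scatter-add rows of `vals` into `F` at (possibly repeated) indices.
accumulate_rows <- function(F, idx, vals) {
  s <- rowsum(vals, group = idx)
  rows <- as.integer(rownames(s))
  F[rows, ] <- F[rows, , drop = FALSE] + s
  F
}
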