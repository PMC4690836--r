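#' Generate a braided flow-diverter mesh
#'
#' Builds the strut-centerline graph of a braided stent on its cylindrical
#' reference surface. The braid consists of two counter-wound helical strand
#' families (`n_strands / 2` strands each); each strand is discretized into
#' straight struts between successive crossing points with the opposite
#' family, giving the characteristic rhomboid (diamond) cells. Struts are
#' planar centerlines with no explicit thickness; the wire diameter is
#' carried as metadata for porosity/pore measurement and strut sweeping.
#'
#' If `spec$strand_turns` is `NULL` the braid angle is solved so that the
#' closed-form lattice porosity matches `spec$target_porosity` (bisection;
#' see [diamond_lattice_coverage()]).
#'
#' @param spec A [device_spec()].
#' @return An object of class `device_mesh` with fields `nodes` (n x 3, mm),
#'   `struts` (s x 2 node indices), `strand_id` (per strut), `wire_diameter`
#'   (micrometres), `reference_diameter`, `reference_length`,
#'   `current_diameter`, `current_length`, `strand_turns`, `n_strands`,
#'   `node_z` and `node_theta` (cylindrical coordinates of each node, with
#'   theta unwrapped along the positive-family strand).
#' @export
generate_device <- function(spec) {
  stopifnot(inherits(spec, "device_spec"))
  turns <- spec$strand_turns %||% solve_strand_turns(spec)
  if (turns <= 0) stop("strand_turns must be positive")
  m <- spec$n_strands / 2L
  L <- spec$length
  R <- spec$nominal_diameter / 2

  # Crossing of +strand j (phase j/m + turns*z/L) with -strand k
  # (phase k/m - turns*z/L):  2*turns*z/L = (k - j)/m (mod 1).
  jk <- expand.grid(j = 0:(m - 1L), k = 0:(m - 1L))
  frac <- ((jk$k - jk$j) %% m) / m
  qmax <- floor(2 * turns - frac)            # q = 0..qmax keeps z in [0, L]
  keep <- qmax >= 0
  jk <- jk[keep, , drop = FALSE]; frac <- frac[keep]; qmax <- qmax[keep]
  nrep <- qmax + 1
  j <- rep(jk$j, nrep); k <- rep(jk$k, nrep)
  q <- sequence(nrep) - 1
  z <- L * (rep(frac, nrep) + q) / (2 * turns)
  theta <- 2 * pi * (j / m + turns * z / L)   # unwrapped along +strand

  cross_id <- seq_along(z)
  n_cross <- length(z)

  # Terminal nodes: each strand is cut at z = 0 and z = L.
  term_j <- 0:(m - 1L)
  plus_t0 <- 2 * pi * term_j / m
  plus_tL <- 2 * pi * (term_j / m + turns)
  minus_t0 <- 2 * pi * term_j / m
  minus_tL <- 2 * pi * (term_j / m - turns)
  term_theta <- c(plus_t0, plus_tL, minus_t0, minus_tL)
  term_z <- rep(c(0, L, 0, L), each = m)
  term_family <- rep(c("p", "p", "m", "m"), each = m)
  term_strand <- rep(term_j, 4)

  node_z <- c(z, term_z)
  node_theta <- c(theta, term_theta)
  n_nodes <- length(node_z)
  nodes <- cbind(R * cos(node_theta), R * sin(node_theta), node_z)
  dimnames(nodes) <- NULL

  # Struts: consecutive crossings along each strand, plus strand terminals.
  # A terminal is only added when no crossing already sits at that device end
  # (j == k pairs cross exactly at z = 0), avoiding zero-length struts.
  eps <- 1e-9 * L
  strut_list <- vector("list", 2L * m)
  for (jj in 0:(m - 1L)) {
    idx <- cross_id[j == jj]
    idx <- idx[order(z[idx])]
    chain <- c(if (z[idx[1L]] > eps) n_cross + jj + 1L,
               idx,
               if (z[idx[length(idx)]] < L - eps) n_cross + m + jj + 1L)
    strut_list[[jj + 1L]] <- cbind(chain[-length(chain)], chain[-1L])
  }
  for (kk in 0:(m - 1L)) {
    idx <- cross_id[k == kk]
    idx <- idx[order(z[idx])]
    chain <- c(if (z[idx[1L]] > eps) n_cross + 2L * m + kk + 1L,
               idx,
               if (z[idx[length(idx)]] < L - eps) n_cross + 3L * m + kk + 1L)
    strut_list[[m + kk + 1L]] <- cbind(chain[-length(chain)], chain[-1L])
  }
  struts <- do.call(rbind, strut_list)
  strand_id <- rep(seq_len(2L * m), vapply(strut_list, nrow, 1L))

  # Drop terminal nodes that were never referenced.
  used <- sort(unique(as.vector(struts)))
  remap <- integer(n_nodes); remap[used] <- seq_along(used)
  struts <- matrix(remap[struts], ncol = 2L)
  nodes <- nodes[used, , drop = FALSE]
  node_z <- node_z[used]; node_theta <- node_theta[used]

  mesh <- structure(list(
    nodes = nodes, struts = struts, strand_id = strand_id,
    wire_diameter = spec$wire_diameter,
    reference_diameter = spec$nominal_diameter,
    reference_length = spec$length,
    current_diameter = spec$nominal_diameter,
    current_length = spec$length,
    strand_turns = turns, n_strands = spec$n_strands,
    node_z = node_z, node_theta = node_theta,
    spec = spec), class = "device_mesh")
  mesh
}

#' @export
print.device_mesh <- function(x, ...) {
  cat(sprintf("<device_mesh> %d nodes, %d struts, %d strands, %.3f turns/strand\n",
              nrow(x$nodes), nrow(x$struts), x$n_strands, x$strand_turns))
  cat(sprintf("  diameter %.3f mm (reference %.2f), length %.2f mm, wire %.0f um\n",
              x$current_diameter, x$reference_diameter, x$current_length,
              x$wire_diameter))
  invisible(x)
}

# Per-strand summed chord length, in strand order (1..n_strands).
strand_lengths <- function(mesh, nodes = mesh$nodes) {
  d <- nodes[mesh$struts[, 1], , drop = FALSE] - nodes[mesh$struts[, 2], , drop = FALSE]
  len <- row_norm(d)
  as.vector(tapply(len, mesh$strand_id, sum))
}

# Degree of every node in the strut graph.
node_degrees <- function(mesh) {
  tabulate(c(mesh$struts[, 1], mesh$struts[, 2]), nbins = nrow(mesh$nodes))
}

#' Crimp a device into a delivery catheter
#'
#' Radially scales the braid to the catheter diameter, with the axial
#' elongation solved from conservation of strand arc length (inextensible
#' wire): each strand is a helix of arc length
#' \eqn{S = \sqrt{L^2 + (\pi D N_t)^2}}, so at the crimped diameter
#' \eqn{D'} the new length is \eqn{L' = \sqrt{S^2 - (\pi D' N_t)^2}}.
#' Turn count and per-node winding phase are preserved, so the crimped
#' configuration stores elastic (bending) energy relative to the reference
#' braid, mimicking a device compressed in its delivery catheter.
#'
#' @param mesh A `device_mesh` at reference diameter.
#' @param catheter_diameter Inner diameter of the delivery catheter, mm.
#' @return A list with elements `mesh` (the crimped `device_mesh`, which
#'   retains the reference configuration in `ref_nodes`) and `report`
#'   (class `crimp_report`: `crimped_diameter`, `crimped_length`,
#'   `strand_length_error`).
#' @export
crimp_device <- function(mesh, catheter_diameter) {
  stopifnot(inherits(mesh, "device_mesh"))
  if (catheter_diameter <= 2 * mesh$wire_diameter / 1000)
    stop("catheter_diameter leaves no lumen (<= 2 wire diameters)")
  if (catheter_diameter > mesh$current_diameter)
    stop("catheter_diameter exceeds the device diameter")
  D0 <- mesh$reference_diameter; L0 <- mesh$reference_length
  Nt <- mesh$strand_turns
  S <- sqrt(L0^2 + (pi * D0 * Nt)^2)
  helix_term <- pi * catheter_diameter * Nt
  if (helix_term >= S) stop("crimp infeasible: helix arc length exhausted")
  Lc <- sqrt(S^2 - helix_term^2)

  ref_nodes <- mesh$ref_nodes %||% mesh$nodes
  ref_len <- strand_lengths(mesh, ref_nodes)

  r <- catheter_diameter / 2
  zc <- mesh$node_z * (Lc / L0)
  new_nodes <- cbind(r * cos(mesh$node_theta), r * sin(mesh$node_theta), zc)
  dimnames(new_nodes) <- NULL

  out <- mesh
  out$nodes <- new_nodes
  out$ref_nodes <- ref_nodes
  out$current_diameter <- catheter_diameter
  out$current_length <- Lc
  out$node_z <- zc

  new_len <- strand_lengths(out)
  err <- max(abs(new_len - ref_len) / ref_len)
  report <- structure(list(crimped_diameter = catheter_diameter,
                           crimped_length = Lc,
                           strand_length_error = err),
                      class = "crimp_report")
  list(mesh = out, report = report)
}

#' @export
print.crimp_report <- function(x, ...) {
  cat(sprintf("<crimp_report> diameter %.3f mm, length %.3f mm, strand length error %.3g\n",
              x$crimped_diameter, x$crimped_length, x$strand_length_error))
  invisible(x)
}
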