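# Row-wise Euclidean norm of an n x d matrix.
row_norm <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m, eps = 1e-12) {
  n <- row_norm(m)
  m / pmax(n, eps)
}

cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Vectorized distance from points (px,py) to segment (ax,ay)-(bx,by).
point_seg_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  if (L2 < 1e-30) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * dx + (py - ay) * dy) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# Distance from points (n x 3) to a 3D segment a-b.
point_seg_dist3 <- function(p, a, b) {
  d <- b - a
  L2 <- sum(d * d)
  if (L2 < 1e-30) return(sqrt(rowSums(sweep(p, 2, a)^2)))
  t <- (sweep(p, 2, a) %*% d) / L2
  t <- pmin(pmax(as.vector(t), 0), 1)
  foot <- outer(t, d) + rep(a, each = length(t))
  sqrt(rowSums((p - foot)^2))
}

# Distance from points (n x 2) to a polyline (m x 2); optionally signed radius
# offset is applied by callers.
point_polyline_dist2 <- function(px, py, poly) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(poly) - 1L)) {
    d <- pmin(d, point_seg_dist2(px, py, poly[i, 1], poly[i, 2],
                                 poly[i + 1, 1], poly[i + 1, 2]))
  }
  d
}

point_polyline_dist3 <- function(p, poly) {
  d <- rep(Inf, nrow(p))
  for (i in seq_len(nrow(poly) - 1L)) {
    d <- pmin(d, point_seg_dist3(p, poly[i, ], poly[i + 1, ]))
  }
  d
}

# Polynomial smooth minimum (metaball-style union of SDFs).
smooth_min <- function(a, b, k) {
  if (k <= 0) return(pmin(a, b))
  h <- pmin(pmax(0.5 + 0.5 * (b - a) / k, 0), 1)
  b * (1 - h) + a * h - k * h * (1 - h)
}

polyline_length <- function(poly) {
  if (nrow(poly) < 2L) return(0)
  sum(sqrt(rowSums((poly[-1, , drop = FALSE] - poly[-nrow(poly), , drop = FALSE])^2)))
}

# Resample a polyline at a given arc-length position; returns point and tangent.
polyline_point_at <- function(poly, s) {
  seg <- poly[-1, , drop = FALSE] - poly[-nrow(poly), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  cs <- c(0, cumsum(len))
  s <- pmin(pmax(s, 0), cs[length(cs)])
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(poly) - 1L)
  f <- (s - cs[i]) / pmax(len[i], 1e-12)
  pt <- poly[i, , drop = FALSE] + seg[i, , drop = FALSE] * f
  tg <- normalize_rows(seg[i, , drop = FALSE])
  list(point = pt, tangent = tg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
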