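#' Write a triangulated surface to STL
#'
#' @param x A `surface_mesh`, `vessel_geometry`, or anything with
#'   `vertices`/`faces` fields. Coordinates are millimetres.
#' @param path Output file path.
#' @param format "binary" (default) or "ascii".
#' @export
write_stl <- function(x, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  surf <- if (inherits(x, "vessel_geometry")) x$surface else x
  stopifnot(!is.null(surf$vertices), !is.null(surf$faces))
  v <- surf$vertices; f <- surf$faces
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  nrm <- normalize_rows(cross3(p2 - p1, p3 - p1))
  n <- nrow(f)
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid stentflow", con)
    block <- sprintf(paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
                            "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
                            "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
                     nrm[, 1], nrm[, 2], nrm[, 3],
                     p1[, 1], p1[, 2], p1[, 3], p2[, 1], p2[, 2], p2[, 3],
                     p3[, 1], p3[, 2], p3[, 3])
    writeLines(block, con)
    writeLines("endsolid stentflow", con)
  } else {
    dat <- t(cbind(nrm, p1, p2, p3))            # 12 floats per facet
    fr <- writeBin(as.vector(dat), raw(), size = 4, endian = "little")
    fr <- matrix(fr, nrow = 48L)
    attrb <- matrix(as.raw(0), nrow = 2L, ncol = n)
    body <- as.vector(rbind(fr, attrb))
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "stentflow binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    writeBin(body, con)
  }
  invisible(path)
}

#' Read an STL surface as a vessel geometry
#'
#' Accepts binary or ASCII STL in millimetre units. Vertices are welded and
#' the surface checked for watertightness; a non-watertight import emits a
#' warning with the boundary-edge count. Imported surfaces have no analytic
#' centerline, so a companion centerline file (CSV with columns
#' `branch,x,y,z`) is required before the geometry can be used for virtual
#' deployment; without one the geometry can still be rasterized for flow.
#'
#' @param path STL file path.
#' @param centerline_path Optional CSV polyline file.
#' @return A `vessel_geometry` with `source = "stl"`.
#' @export
read_stl <- function(path, centerline_path = NULL) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  is_binary <- length(ntri) == 1 && !is.na(ntri) && sz == 84 + 50 * ntri
  if (is_binary) {
    body <- readBin(con, "raw", 50 * ntri)
    close(con)
    bm <- matrix(body, nrow = 50L)
    floats <- readBin(as.vector(bm[1:48, ]), "numeric", 12L * ntri, size = 4,
                      endian = "little")
    fm <- matrix(floats, nrow = 12L)
    tris <- t(fm[4:12, , drop = FALSE])         # drop facet normals
  } else {
    close(con)
    lines <- readLines(path, warn = FALSE)
    vl <- grep("vertex", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("malformed ASCII STL: vertex count not a multiple of 3")
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(w) as.numeric(w[2:4])))
    ntri <- nrow(coords) / 3
    tris <- cbind(coords[seq(1, by = 3, length.out = ntri), , drop = FALSE],
                  coords[seq(2, by = 3, length.out = ntri), , drop = FALSE],
                  coords[seq(3, by = 3, length.out = ntri), , drop = FALSE])
  }
  allv <- rbind(tris[, 1:3], tris[, 4:6], tris[, 7:9])
  scale <- max(apply(allv, 2, function(cc) diff(range(cc))), 1e-9)
  tol <- 1e-6 * scale
  key <- paste(round(allv[, 1] / tol), round(allv[, 2] / tol),
               round(allv[, 3] / tol))
  uid <- match(key, key[!duplicated(key)])
  verts <- allv[!duplicated(key), , drop = FALSE]
  faces <- cbind(uid[seq_len(ntri)], uid[ntri + seq_len(ntri)],
                 uid[2L * ntri + seq_len(ntri)])
  surf <- structure(list(vertices = verts, faces = faces),
                    class = "surface_mesh")
  nb <- boundary_edges(surf)
  if (nb > 0)
    warning(sprintf("imported surface is not watertight: %d boundary edges", nb))
  centerlines <- NULL
  if (!is.null(centerline_path)) centerlines <- read_centerlines(centerline_path)
  bb <- rbind(apply(verts, 2, min), apply(verts, 2, max))
  structure(list(surface = surf, caps = list(), dome = NULL,
                 dome_label = integer(0), centerlines = centerlines,
                 branch_diameters = NULL, sdf3 = NULL, sdf2 = NULL,
                 bbox2 = bb[, 1:2], bbox3 = bb, cap_edges2 = NULL,
                 neck_segment2 = NULL, source = "stl"),
            class = "vessel_geometry")
}

#' Read / write centerline polylines
#'
#' CSV with columns `branch` (id or name), `x`, `y`, `z` in mm, one row per
#' polyline vertex in order.
#'
#' @param path CSV file path.
#' @return List of branches (`name`, `points`).
#' @export
read_centerlines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("branch", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("centerline CSV must have columns branch, x, y, z")
  lapply(split(df, df$branch), function(d)
    list(name = as.character(d$branch[1]),
         points = as.matrix(d[, c("x", "y", "z")])))
}

#' @rdname read_centerlines
#' @param centerlines List of branches as returned by `read_centerlines`,
#'   or the `centerlines` field of a `vessel_geometry`.
#' @export
write_centerlines <- function(centerlines, path) {
  rows <- do.call(rbind, lapply(centerlines, function(b) {
    data.frame(branch = b$name, x = b$points[, 1], y = b$points[, 2],
               z = b$points[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
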