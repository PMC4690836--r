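test_that("synthetic tubes are watertight with convergent volume", {
  tube <- make_straight_vessel(3, 30)
  expect_true(stentflow:::is_watertight(tube$surface))
  v <- mesh_volume(tube$surface)
  expect_gt(v, 0)
  expect_lt(abs(v / (pi * 1.5^2 * 30) - 1), 0.01)
  # refinement halves the error at least linearly (observed order >= 1)
  coarse <- make_straight_vessel(3, 30, cell = 0.5)
  fine <- make_straight_vessel(3, 30, cell = 0.25)
  e1 <- abs(mesh_volume(coarse$surface) / (pi * 1.5^2 * 30) - 1)
  e2 <- abs(mesh_volume(fine$surface) / (pi * 1.5^2 * 30) - 1)
  expect_lt(e2, e1 / 1.9)
  # curved tube: analytic arc centerline of the requested length
  curved <- make_straight_vessel(3, 30, curvature_radius = 15,
                                 build_surface = FALSE)
  expect_equal(stentflow:::polyline_length(curved$centerlines[[1]]$points),
               30, tolerance = 1e-3)
  expect_error(make_straight_vessel(3, 30, curvature_radius = 2),
               "curvature_radius")
})

test_that("bifurcation aneurysm geometry satisfies its construction contract", {
  geom <- make_bifurcation_aneurysm(bifurcation_spec())
  outlets <- vapply(geom$caps, function(cp) cp$type == "outlet", TRUE)
  expect_identical(sum(!outlets), 1L)       # exactly one inlet
  expect_identical(sum(outlets), 2L)
  expect_gt(length(geom$dome_label), 0)
  expect_true(stentflow:::is_watertight(geom$surface))
  expect_gt(mesh_volume(geom$surface), 0)
  # centerline points lie inside the lumen
  for (b in geom$centerlines) {
    mid <- stentflow:::polyline_point_at(
      b$points, 0.5 * stentflow:::polyline_length(b$points))$point
    expect_lt(geom$sdf3(mid), 0)
  }
  # four-daughter (basilar-like) variant exposes four outlets
  g4 <- make_bifurcation_aneurysm(bifurcation_spec(n_daughters = 4),
                                  build_surface = FALSE)
  expect_identical(sum(vapply(g4$caps, function(cp) cp$type == "outlet",
                              TRUE)), 4L)
  expect_error(bifurcation_spec(neck_diameter = 9, dome_diameter = 8),
               "neck_diameter")
  expect_error(make_bifurcation_aneurysm(
    bifurcation_spec(neck_diameter = 7, dome_diameter = 8,
                     parent_diameter = 4)), "footprint")
})

test_that("a dome equal to the neck forms a hemispherical blister", {
  spec <- bifurcation_spec(dome_diameter = 5, neck_diameter = 5)
  geom <- make_bifurcation_aneurysm(spec, build_surface = FALSE)
  v <- stentflow:::dome_volume(geom, cell = 0.08)
  expect_lt(abs(v / ((2 / 3) * pi * 2.5^3) - 1), 0.05)
})

test_that("the neck plane separates dome from parent lumen", {
  geom <- aneurysm_fixture()
  np <- define_neck_plane(geom, offset = 0)
  expect_equal(np$normal, geom$dome$axis)
  # boundary perimeter ~ pi * neck diameter
  per <- stentflow:::polyline_length(np$boundary)
  expect_lt(abs(per / (pi * 5) - 1), 0.03)
  expect_error(define_neck_plane(geom, offset = 50), "degenerate")
  expect_error(define_neck_plane(make_straight_vessel(3, 10,
                                                      build_surface = FALSE)),
               "dome")
  # device-proximity warning
  fake <- matrix(c(0, np$point[2] + 0.01, 0), 1)
  expect_warning(define_neck_plane(geom, 0, device = fake), "wire diameters")
})

test_that("STL round trips preserve geometry in both dialects", {
  tube <- make_straight_vessel(2, 10, cell = 0.4)
  fb <- tempfile(fileext = ".stl"); fa <- tempfile(fileext = ".stl")
  write_stl(tube$surface, fb, "binary")
  write_stl(tube$surface, fa, "ascii")
  gb <- read_stl(fb); ga <- read_stl(fa)
  expect_identical(nrow(gb$surface$faces), nrow(tube$surface$faces))
  expect_identical(nrow(ga$surface$faces), nrow(tube$surface$faces))
  # same geometry across dialects: compare sorted vertex coordinates
  sv <- function(g) {
    v <- g$surface$vertices
    v[order(v[, 1], v[, 2], v[, 3]), ]
  }
  expect_equal(sv(ga), sv(gb), tolerance = 1e-5)
  expect_equal(mesh_volume(gb$surface), mesh_volume(tube$surface),
               tolerance = 1e-5)
  # an uncapped (open) surface import warns about watertightness
  open_surf <- tube$surface
  open_surf$faces <- open_surf$faces[-seq_len(50), , drop = FALSE]
  fo <- tempfile(fileext = ".stl")
  write_stl(open_surf, fo)
  expect_warning(read_stl(fo), "not watertight")
})

test_that("centerline CSV files round trip", {
  geom <- aneurysm_fixture()
  f <- tempfile(fileext = ".csv")
  write_centerlines(geom$centerlines, f)
  back <- read_centerlines(f)
  expect_setequal(names(back),
                  vapply(geom$centerlines, `[[`, "", "name"))
  expect_equal(back[["parent"]]$points,
               unname(geom$centerlines[[1]]$points), tolerance = 1e-9,
               ignore_attr = TRUE)
})
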