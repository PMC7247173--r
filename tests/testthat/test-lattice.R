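test_that("lattice construction: coverage, snapping, caps", {
  s <- sphere(c(0, 0, 0), 1)
  lat <- build_lattice(s, 0.25)
  expect_true(all(lat$dims >= 10))                  # 2 A extent / 0.25
  ## origin snapped to resolution multiples
  expect_equal(lat$origin / 0.25, round(lat$origin / 0.25))
  ## one lattice covers far-apart solids
  lat2 <- build_lattice(list(s, sphere(c(20, 0, 0), 1)), 0.5)
  expect_gte(lat2$origin[1], -3)
  expect_gte(lat2$dims[1] * 0.5, 22)
  ## identical inputs give identical lattices
  lat3 <- build_lattice(list(s, sphere(c(20, 0, 0), 1)), 0.5)
  expect_identical(lat2, lat3)
  expect_error(build_lattice(s, -1), "positive")
  expect_error(build_lattice(s, 0.25, max_cubes = 10), "coarser")
})

test_that("floodfill equals the exhaustive lattice scan", {
  fixtures <- list(
    sphere(c(0.07, -0.13, 0.02), 1),
    csg_union(sphere(c(0, 0, 0), 1), sphere(c(3, 0.2, -0.1), 0.8)),
    spindle(c(0, 0, 0), c(0.2, 1, 0.1), 2, 1, -0.8, 0.8))
  for (s in fixtures) {
    lat <- build_lattice(s, 0.25)
    surf <- find_all_surface_cubes(s, NULL, lat)
    scan <- csgmol:::exhaustive_surface_scan(s, lat)
    expect_identical(unname(surf$cubes), unname(scan))
  }
})

test_that("disjoint union keeps both connected cube components complete", {
  u <- csg_union(sphere(c(0, 0, 0), 1), sphere(c(4, 0, 0), 0.7))
  lat <- build_lattice(u, 0.25)
  surf <- find_all_surface_cubes(u, NULL, lat)
  scan <- csgmol:::exhaustive_surface_scan(u, lat)
  expect_identical(unname(surf$cubes), unname(scan))
  ## cubes split into two spatial clusters
  expect_true(any(surf$cubes[, 1] * 0.25 + lat$origin[1] > 2.5) &&
              any(surf$cubes[, 1] * 0.25 + lat$origin[1] < 2.5))
})

test_that("corner classification evaluates each distinct corner once", {
  s <- sphere(c(0, 0, 0), 1)
  lat <- build_lattice(s, 0.25)
  surf <- find_all_surface_cubes(s, NULL, lat)
  cc <- classify_corners(surf$cubes, s, lat)
  n_distinct <- length(unique(as.vector(cc$id_matrix)))
  expect_equal(cc$n_evaluations, n_distinct)
  expect_lt(cc$n_evaluations, 8 * nrow(surf$cubes))
  ## classification matches direct containment
  coords <- csgmol:::lat_corner_coords(lat, csgmol:::lat_corner_unid(lat, cc$ids))
  expect_identical(cc$states, contains_point(s, coords))
})

test_that("edge intersections sit on their edges at the analytic crossing", {
  s <- sphere(c(0, 0, 0), 1)
  lat <- build_lattice(s, 0.25)
  surf <- find_all_surface_cubes(s, NULL, lat)
  em <- compute_edge_intersections(surf, s, lat)
  ## every point on the sphere surface (within tangency tolerance), and on
  ## an axis-aligned lattice edge
  r <- sqrt(rowSums(em$points^2))
  expect_lt(max(abs(r - 1)), 1e-9)
  frac <- em$points / lat$res
  on_grid <- abs(frac - round(frac)) < 1e-9
  expect_true(all(rowSums(on_grid) >= 2))
})

test_that("worker counts do not change the surface cube set or mesh", {
  u <- csg_union(sphere(c(0, 0, 0), 1), sphere(c(1.2, 0.3, 0), 0.8))
  lat <- build_lattice(u, 0.25)
  ref <- find_all_surface_cubes(u, NULL, lat, workers = 1)
  for (w in c(2, 4)) {
    alt <- find_all_surface_cubes(u, NULL, lat, workers = w)
    expect_identical(ref$cubes, alt$cubes)
    expect_identical(ref$states, alt$states)
  }
  m1 <- mesh_solid_boundary(u, 0.25, workers = 1)
  m2 <- mesh_solid_boundary(u, 0.25, workers = 2)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$triangles, m2$triangles)
})
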