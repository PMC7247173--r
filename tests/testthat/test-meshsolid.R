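test_that("preparation classifies nesting for a simple sphere mesh", {
  m <- mesh_solid_boundary(sphere(c(0, 0, 0), 1), 0.25)
  msd <- prepare_mesh_solid(m, 0.25)
  expect_equal(max(msd$ne_lab), 1)                 # one nonempty component
  expect_equal(length(msd$em_interior), 2)         # inside and outside
  expect_equal(sort(msd$em_interior), c(FALSE, TRUE))
  expect_true(contains_point(msd, c(0, 0, 0)))
  expect_false(contains_point(msd, c(2, 2, 2)))
  ## non-closed input is rejected with a validation error
  broken <- triangle_mesh(m$vertices, m$triangles[-1, ])
  expect_error(prepare_mesh_solid(broken, 0.25), "not closed")
})

test_that("hollow shell nesting: exterior / solid / interior void", {
  shell <- csg_difference(sphere(c(0, 0, 0), 2), sphere(c(0, 0, 0), 1.2))
  mm <- mesh_solid_boundary(shell, 0.2)
  expect_equal(length(mesh_shells(mm)), 2)
  msd <- prepare_mesh_solid(mm, 0.4)
  ## the central void is outside the solid; the wall is inside
  expect_false(contains_point(msd, c(0, 0, 0)))
  expect_true(contains_point(msd, c(1.6, 0.05, 0.03)))
  expect_false(contains_point(msd, c(3, 3, 3)))
})

test_that("thin-wall abnormality is resolved by segment parity", {
  ## wall (0.3 A) thinner than the preparation cube (0.5 A): void boundary
  ## and outer surface share cubes, so naive outside-in alternation would
  ## call the void interior
  thin <- csg_difference(sphere(c(0, 0, 0), 2), sphere(c(0, 0, 0), 1.7))
  mm <- mesh_solid_boundary(thin, 0.1)
  expect_equal(length(mesh_shells(mm)), 2)
  msd <- prepare_mesh_solid(mm, 0.5)
  expect_false(contains_point(msd, c(0, 0, 0)))          # void: outside
  expect_true(contains_point(msd, c(1.85, 0.07, 0.03)))  # wall: inside
})

test_that("voting containment matches the analytic sphere off-boundary", {
  m <- mesh_solid_boundary(sphere(c(0, 0, 0), 1), 0.25)
  msd <- prepare_mesh_solid(m, 0.25)
  set.seed(71)
  pts <- rand_points(2000, -1.4, 1.4)
  truth <- sqrt(rowSums(pts^2)) <= 1
  est <- contains_point(msd, pts)
  dis <- est != truth
  ## disagreements confined to a band of half a triangle size
  if (any(dis)) {
    expect_lt(max(abs(sqrt(rowSums(pts[dis, , drop = FALSE]^2)) - 1)), 0.125)
  }
  ## points far from the boundary are never misclassified
  far <- abs(sqrt(rowSums(pts^2)) - 1) > 0.3
  expect_identical(est[far], truth[far])
})

test_that("segment intervals: diameter chord, miss, midpoint consistency", {
  m <- mesh_solid_boundary(sphere(c(0, 0, 0), 1), 0.25)
  msd <- prepare_mesh_solid(m, 0.25)
  iv <- intersect_segment(msd, segment_from_to(c(-2, 0.01, 0.017),
                                               c(2, 0.01, 0.017)))
  expect_equal(nrow(iv), 1)
  expect_equal(iv_length(iv) * 4, 2, tolerance = 0.05)
  expect_equal(nrow(intersect_segment(
    msd, segment_from_to(c(3, 3, 3), c(4, 4, 4)))), 0)
  set.seed(72)
  for (i in 1:20) {
    seg <- rand_segment(-2, 2)
    iv <- intersect_segment(msd, seg)
    if (nrow(iv) > 0) {
      mids <- (iv[, 1] + iv[, 2]) / 2
      wide <- iv[, 2] - iv[, 1] > 0.02
      expect_true(all(contains_point(msd, seg_point(seg, mids[wide]))))
    }
  }
})

test_that("round trip: mesh -> solid -> mesh preserves enclosed volume", {
  m <- mesh_solid_boundary(sphere(c(0, 0, 0), 1), 0.25)
  msd <- prepare_mesh_solid(m, 0.25)
  m2 <- mesh_solid_boundary(msd, 0.25)
  expect_watertight(m2)
  expect_equal(surveyor_volume(m2), surveyor_volume(m), tolerance = 0.01)
})

test_that("starting cubes cover every mesh component, including at a finer lattice", {
  two <- csg_union(sphere(c(0, 0, 0), 1), sphere(c(3.5, 0, 0), 0.8))
  mm <- mesh_solid_boundary(two, 0.25)
  msd <- prepare_mesh_solid(mm, 0.25)
  expect_equal(max(msd$ne_lab), 2)
  lat <- build_lattice(msd, 0.125)
  sc <- find_starting_cubes(msd, lat)
  expect_cubes_mixed(msd, lat, sc)
  ctr <- csgmol:::lat_corner_coords(lat, sc) + lat$res / 2
  expect_true(any(ctr[, 1] < 2) && any(ctr[, 1] > 2))   # both blobs seeded
  ## floodfill from these seeds recovers the full surface of the solid
  surf <- find_all_surface_cubes(msd, NULL, lat)
  expect_gt(nrow(surf$cubes), 0)
  m3 <- mesh_solid_boundary(msd, 0.125)
  expect_equal(length(mesh_shells(m3)), 2)
})
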