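test_that("dual graph: pair adjacency and the overlong-edge rule", {
  ## radii 1.9, solvent 1.4: threshold 1.9 + 1.9 + 2.8 = 6.6
  two <- function(d) data.frame(x = c(0, d), y = 0, z = 0, radius = 1.9,
                                element = "C", serial = 1:2)
  d1 <- compute_power_dual(two(3.0), 1.4)
  expect_equal(nrow(d1$edges), 1)
  expect_false(d1$edges$overlong)
  d2 <- compute_power_dual(two(7.0), 1.4)
  expect_true(d2$edges$overlong)
  ## four atoms in general position: one tetra, 4 triangles, 6 edges
  d4 <- compute_power_dual(toy_molecule("tetra"), 1.4)
  expect_equal(nrow(d4$tetras), 1)
  expect_equal(nrow(d4$triangles), 4)
  expect_equal(nrow(d4$edges), 6)
  ## a cloud: every triangle of a tetra appears, membership counts consistent
  set.seed(61)
  atoms <- data.frame(x = runif(9, -3, 3), y = runif(9, -3, 3),
                      z = runif(9, -3, 3), radius = 1.7)
  dd <- compute_power_dual(atoms, 1.4)
  expect_gt(nrow(dd$tetras), 0)
  expect_true(all(dd$tri_tetra_count >= 1))
})

test_that("tangent probe placement: mirror pair, residuals, degenerate", {
  ctrs <- rbind(c(0, 0, 0), c(4, 0, 0), c(2, 2 * sqrt(3), 0))
  cand <- place_solvent_tangent_sphere(ctrs, rep(1.9, 3), 1.4)
  expect_equal(nrow(cand), 2)
  ## mirror symmetric about the atom plane (z = 0)
  expect_equal(cand[1, 3], -cand[2, 3], tolerance = 1e-9)
  for (k in 1:2) {
    d <- sqrt(colSums((t(ctrs) - cand[k, ])^2))
    expect_lt(max(abs(d - 3.3)), 1e-9)
  }
  ## colinear atoms are degenerate: no candidates
  col <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))
  expect_equal(suppressMessages(
    nrow(place_solvent_tangent_sphere(col, rep(1.9, 3), 1.4))), 0)
})

test_that("construction counts: single atom, dimer spindle, tetra cluster", {
  one <- data.frame(x = 0, y = 0, z = 0, radius = 1.9)
  m1 <- build_molecular_solid(one, 1.4)
  expect_length(m1$spindles, 0)
  pts <- rand_points(500, -3, 3)
  expect_identical(contains_point(m1, pts),
                   contains_point(sphere(c(0, 0, 0), 1.9), pts))

  dimer <- build_molecular_solid(toy_molecule("dimer"), 1.4)
  expect_length(dimer$spindles, 1)
  ## a waist point in the mid-plane: outside both vdW spheres yet
  ## solvent-excluded (inside the spindle); analytically, the probe-center
  ## circle has radius sqrt(3.3^2 - 1.5^2) ~ 2.939, so (0, 1.3, 0) is
  ## 1.639 > 1.4 away from the probe tube
  p <- c(0, 1.3, 0)
  expect_false(contains_point(sphere(c(-1.5, 0, 0), 1.9), p) ||
               contains_point(sphere(c(1.5, 0, 0), 1.9), p))
  expect_true(contains_point(dimer, p))

  tet <- build_molecular_solid(toy_molecule("tetra"), 1.4)
  expect_length(tet$spheres, 4)
  expect_length(tet$spindles, 6)
  expect_length(tet$tetras, 1)
  expect_length(tet$cups, 4)
  mesh <- mesh_solid_boundary(tet, 0.3)
  expect_watertight(mesh)
})

test_that("negsphere containment dominates inside cups", {
  tet <- build_molecular_solid(toy_molecule("tetra"), 1.4)
  cup <- tet$cups[[1]]
  ## a point just inside the negsphere on the way toward the atom triangle
  ## is inside the cup tetrahedron too, and must classify outside
  p <- cup$negsphere$center +
    0.35 * (colMeans(cup$tetra$corners[1:3, ]) - cup$negsphere$center)
  expect_true(contains_point(cup$negsphere, p))
  expect_true(contains_point(cup$tetra, p))
  expect_false(contains_point(tet, p))
})

test_that("hash-accelerated evaluation equals the exhaustive path", {
  for (kind in c("dimer", "tetra")) {
    ms <- build_molecular_solid(toy_molecule(kind), 1.4)
    pts <- rand_points(10000, -6, 6)
    expect_identical(contains_point(ms, pts),
                     csgmol:::mol_contains_exhaustive(ms, pts))
  }
})

test_that("segment intervals through molecules match containment sampling", {
  ms <- build_molecular_solid(toy_molecule("tetra"), 1.4)
  set.seed(62)
  for (i in 1:25) expect_intervals_match_sampling(ms, rand_segment(-5, 5))
  ## lone-atom chord
  one <- build_molecular_solid(data.frame(x = 0, y = 0, z = 0, radius = 1.9),
                               1.4)
  iv <- intersect_segment(one, segment_from_to(c(-3, 0, 0), c(3, 0, 0)))
  expect_equal(iv_length(iv) * 6, 3.8, tolerance = 1e-9)
})

test_that("starting cubes include tangency-point cubes and pass corner test", {
  tet <- build_molecular_solid(toy_molecule("tetra"), 1.4)
  expect_equal(nrow(tet$tangency), 12)       # 3 per cup, 4 cups
  lat <- build_lattice(tet, 0.3)
  sc <- find_starting_cubes(tet, lat)
  expect_gt(nrow(sc), 0)
  expect_cubes_mixed(tet, lat, sc)
  ## every mixed cube holding a tangency point is among the seeds
  tc <- csgmol:::lat_cube_of(lat, tet$tangency)
  tc <- unique(tc[csgmol:::cubes_mixed(tet, lat, tc), , drop = FALSE])
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(tc) %in% key(sc)))
})

test_that("solvent exclusion only adds volume, monotonically in the probe", {
  at <- toy_molecule("dimer")
  vdw <- csg_union(sphere(c(-1.5, 0, 0), 1.9), sphere(c(1.5, 0, 0), 1.9))
  v_vdw <- surveyor_volume(mesh_solid_boundary(vdw, 0.25))
  vols <- sapply(c(1.0, 1.4, 2.0), function(rs) {
    surveyor_volume(mesh_solid_boundary(build_molecular_solid(at, rs), 0.25))
  })
  expect_true(all(vols >= v_vdw))
  expect_true(all(diff(vols) > 0))
})

test_that("a bonded chain produces a watertight single-shell surface", {
  ch <- toy_molecule("chain", n = 12)
  ms <- build_molecular_solid(ch, 1.4)
  mesh <- mesh_solid_boundary(ms, 0.4)
  expect_watertight(mesh)
  expect_equal(length(mesh_shells(mesh)), 1)
})
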