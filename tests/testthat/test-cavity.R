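test_that("pocket cavity: bounded volume, steric monotonicity, empty cases", {
  rec <- toy_molecule("pocket")
  lig <- attr(rec, "ligand")
  cav <- build_binding_cavity(rec, lig, resolution = 0.5)
  expect_watertight(cav)
  v_open <- surveyor_volume(cav, signed = TRUE)
  expect_gt(v_open, 0)
  expect_lt(v_open, 4 * pi / 3 * 125)     # bounded by one ligand sphere
  ## a blocker atom in the pocket strictly reduces the cavity
  recB <- toy_molecule("pocket", blocker = TRUE)
  cavB <- build_binding_cavity(recB, lig, resolution = 0.5)
  expect_lt(surveyor_volume(cavB, signed = TRUE), v_open)
  ## ligand far from the receptor: the envelope excludes everything
  far <- lig; far$x <- far$x + 50
  expect_warning(cav0 <- build_binding_cavity(rec, far, resolution = 0.5),
                 "empty cavity")
  expect_equal(nrow(cav0$triangles), 0)
})

test_that("removing the receptor leaves ligand spheres clipped by the envelope", {
  rec <- toy_molecule("pocket")
  lig <- attr(rec, "ligand")
  spec <- cavity_spec()
  lig_u <- sphere(c(lig$x, lig$y, lig$z), spec$ligand_sphere_radius)
  env <- build_molecular_solid(rec, spec$probe_large)
  direct <- mesh_solid_boundary(csg_intersection(lig_u, env), 0.5)
  ## same construction with an empty receptor contribution: difference with
  ## a far-away dummy molecular solid
  dummy <- build_molecular_solid(
    data.frame(x = 500, y = 500, z = 500, radius = 1.9), spec$probe_small)
  viaCavity <- mesh_solid_boundary(
    csg_intersection(csg_difference(lig_u, dummy), env), 0.5,
    lattice = attr(direct, "lattice"))
  expect_equal(surveyor_volume(viaCavity, signed = TRUE),
               surveyor_volume(direct, signed = TRUE), tolerance = 1e-12)
})

test_that("fragments: counts, analytic volumes, void bookkeeping", {
  two <- csg_union(sphere(c(0, 0, 0), 1), sphere(c(3.4, 0, 0), 0.8))
  fr <- extract_fragments(mesh_solid_boundary(two, 0.2))
  expect_equal(nrow(fr), 2)
  expect_equal(fr$volume[1], 4 * pi / 3, tolerance = 0.03)
  expect_equal(fr$volume[2], 4 * pi / 3 * 0.8^3, tolerance = 0.03)
  expect_true(all(diff(fr$volume) <= 0))
  ## crescent: difference of offset spheres stays one positive fragment
  cres <- csg_difference(sphere(c(0, 0, 0), 1), sphere(c(0.7, 0, 0), 0.8))
  frc <- extract_fragments(mesh_solid_boundary(cres, 0.15))
  expect_equal(nrow(frc), 1)
  ## inclusion-exclusion for the lens of the two spheres
  d <- 0.7; r1 <- 1; r2 <- 0.8
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * r2 - 3 * r2^2 + 2 * d * r1 + 6 * r1 * r2 - 3 * r1^2) /
    (12 * d)
  expect_equal(frc$volume[1], 4 * pi / 3 - lens, tolerance = 0.03)
  ## hollow shell: the void is a negative contribution of the same fragment
  shell <- csg_difference(sphere(c(0, 0, 0), 1.5), sphere(c(0, 0, 0), 0.8))
  frs <- extract_fragments(mesh_solid_boundary(shell, 0.15))
  expect_equal(nrow(frs), 1)
  expect_equal(frs$volume[1], 4 * pi / 3 * (1.5^3 - 0.8^3), tolerance = 0.03)
})

test_that("fragment volumes sum to the whole-mesh signed volume", {
  prims <- random_primitives(12, seed = 9, bbox = c(-6, 6))
  m <- mesh_solid_boundary(csg_union_all(prims), 0.4)
  fr <- extract_fragments(m)
  expect_equal(sum(fr$volume), surveyor_volume(m, signed = TRUE),
               tolerance = 1e-9)
})

test_that("displacement distance: identity, offset spheres, asymmetry", {
  a <- mesh_solid_boundary(sphere(c(0, 0, 0), 1), 0.2)
  expect_equal(unname(displacement_distance(a, a)), c(0, 0, 0))
  b <- mesh_solid_boundary(sphere(c(0, 0, 0), 1.1), 0.2)
  da <- displacement_distance(a, b)
  expect_equal(unname(da["mean"]), 0.1, tolerance = 0.25)
  ## asymmetry is real: compare the two directions
  db <- displacement_distance(b, a)
  expect_false(isTRUE(all.equal(unname(da), unname(db))))
})
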