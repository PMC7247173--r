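test_that("single-inside-corner cubes emit one triangle", {
  tab <- csgmol:::mc_table()
  for (c in 0:7) {
    expect_length(tab[[bitwShiftL(1L, c) + 1]], 3)
    ## complement: one outside corner gives a single triangle too
    expect_length(tab[[255L - bitwShiftL(1L, c) + 1]], 3)
  }
  expect_length(tab[[1]], 0)
  expect_length(tab[[256]], 0)
})

test_that("meshes are watertight with spherical topology and no duplicates", {
  m <- mesh_solid_boundary(sphere(c(0.05, 0.02, -0.03), 1), 0.25)
  expect_watertight(m)
  expect_equal(mesh_euler_characteristic(m), 2L)    # genus 0
  expect_equal(nrow(m$vertices), length(unique(paste(
    m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]))))
})

test_that("surveyor volume converges to the analytic sphere volume", {
  va <- 4 * pi / 3 * 8
  errs <- sapply(c(0.5, 0.25, 0.125), function(res) {
    v <- surveyor_volume(mesh_solid_boundary(sphere(c(0, 0, 0), 2), res))
    abs(v - va) / va
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.005)
})

test_that("tetrahedron volume is recovered at fine resolution", {
  tt <- tetrahedron(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3)))
  v <- surveyor_volume(mesh_solid_boundary(tt, 0.1))
  expect_equal(v, 27 / 6, tolerance = 0.02)
})

test_that("surveyor volume: exact on a cube, translation invariant", {
  ## unit cube as 12 triangles
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  tris <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
                c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
                c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  cube <- triangle_mesh(v, tris)
  expect_equal(surveyor_volume(cube), 1.0, tolerance = 1e-12)
  shifted <- triangle_mesh(sweep(v, 2, c(10, -7, 3), "+"), tris)
  expect_equal(surveyor_volume(shifted), 1.0, tolerance = 1e-9)
  ## open mesh errors
  open_mesh <- triangle_mesh(v, tris[-1, ])
  expect_error(surveyor_volume(open_mesh), "closed")
})

test_that("random-primitive union meshes complete across resolutions", {
  prims <- random_primitives(30, seed = 5)
  u <- csg_union_all(prims)
  vols <- sapply(c(1.0, 0.5), function(res) {
    m <- mesh_solid_boundary(u, res)
    expect_watertight(m)
    surveyor_volume(m, signed = TRUE)
  })
  ## refinement changes the volume by a modest fraction only
  expect_lt(abs(vols[2] - vols[1]) / vols[2], 0.2)
})

test_that("no zero-area triangles survive vertex welding", {
  ## radius a multiple of the resolution puts lattice corners exactly on the
  ## surface -- the configuration that produces collapsed triangles
  m <- mesh_solid_boundary(sphere(c(0, 0, 0), 1), 0.25)
  expect_watertight(m)
  V <- m$vertices; Tr <- m$triangles
  u <- V[Tr[, 2], ] - V[Tr[, 1], ]; w <- V[Tr[, 3], ] - V[Tr[, 1], ]
  area2 <- rowSums(cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                         u[, 3] * w[, 1] - u[, 1] * w[, 3],
                         u[, 1] * w[, 2] - u[, 2] * w[, 1])^2)
  expect_equal(sum(area2 / 4 <= 1e-18), 0)
})
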