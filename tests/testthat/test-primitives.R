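test_that("sphere containment honors the boundary-inside rule", {
  s <- sphere(c(0, 0, 0), 1)
  expect_true(contains_point(s, c(0, 0, 0.5)))
  expect_true(contains_point(s, c(1, 0, 0)))      # exactly on the surface
  expect_false(contains_point(s, c(1.0000001, 0, 0)))
})

test_that("sphere segment intersection: chord, miss, tangency", {
  s <- sphere(c(0, 0, 0), 1)
  iv <- intersect_segment(s, segment_from_to(c(-2, 0, 0), c(2, 0, 0)))
  expect_equal(unname(iv), cbind(0.25, 0.75), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(nrow(intersect_segment(
    s, segment_from_to(c(0, 0, 5), c(1, 0, 5)))), 0)
  ## tangent at (0,0,1): a degenerate interval at a trivial separation
  tg <- intersect_segment(s, segment_from_to(c(-2, 0, 1), c(2, 0, 1)))
  expect_equal(nrow(tg), 1)
  expect_equal(mean(tg[1, ]), 0.5, tolerance = 1e-9)
  expect_lt(tg[1, 2] - tg[1, 1], 1e-8)
})

test_that("sphere chord lengths match the analytic value on random segments", {
  set.seed(21)
  s <- sphere(c(0.3, -0.2, 0.1), 1.3)
  for (i in 1:200) {
    seg <- rand_segment(-4, 4)
    iv <- intersect_segment(s, seg)
    ## analytic chord: line-sphere intersection clipped to the segment
    oc <- seg$origin - s$center
    a <- sum(seg$dir^2); b <- 2 * sum(oc * seg$dir); c0 <- sum(oc^2) - s$radius^2
    disc <- b^2 - 4 * a * c0
    chord <- if (disc <= 0) 0 else {
      t1 <- max((-b - sqrt(disc)) / (2 * a), 0)
      t2 <- min((-b + sqrt(disc)) / (2 * a), 1)
      max(t2 - t1, 0)
    }
    expect_equal(iv_length(iv), chord, tolerance = 1e-9)
  }
})

test_that("tetrahedron containment uses closed half-spaces", {
  tt <- tetrahedron(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_true(contains_point(tt, c(0.1, 0.1, 0.1)))
  expect_true(contains_point(tt, c(0, 0.2, 0.2)))   # on the x = 0 face
  expect_false(contains_point(tt, c(1, 1, 1)))
})

test_that("tetrahedron segment clipping: interior, edge overlap, miss", {
  tt <- tetrahedron(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  iv <- intersect_segment(tt, segment_from_to(c(-1, 0.2, 0.2), c(2, 0.2, 0.2)))
  ## inside where x in [0, 0.6] -> t in [1/3, 1.6/3]
  expect_equal(unname(iv), cbind(1 / 3, 1.6 / 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  ## segment along an edge: the overlap interval
  ed <- intersect_segment(tt, segment_from_to(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(unname(ed), cbind(0, 1), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(nrow(intersect_segment(
    tt, segment_from_to(c(2, 2, 2), c(3, 3, 3)))), 0)
})

test_that("midpoint classification of intervals agrees with containment", {
  set.seed(31)
  prims <- list(sphere(c(0.2, 0, -0.3), 1.4),
                tetrahedron(rand_points(4, -2, 2)),
                spindle(c(0, 0.1, 0), c(0.3, 1, 0.2), 2, 0.9, -0.7, 0.7),
                spindle(c(0.5, 0, 0), c(0, 0, 1), 0.5, 1, -0.95, 0.95))
  for (p in prims) {
    for (i in 1:60) {
      seg <- rand_segment(-4, 4)
      iv <- intersect_segment(p, seg)
      if (nrow(iv) > 0) {
        mids <- (iv[, 1] + iv[, 2]) / 2
        wide <- iv[, 2] - iv[, 1] > 1e-7   # skip degenerate tangency slivers
        if (any(wide))
          expect_true(all(contains_point(p, seg_point(seg, mids[wide]))))
      }
      if (nrow(iv) > 1) {
        gaps <- (iv[-1, 1] + iv[-nrow(iv), 2]) / 2
        expect_false(any(contains_point(p, seg_point(seg, gaps))))
      }
    }
  }
})

test_that("starting cubes pass the mixed-corner test and cover all six sides", {
  s <- sphere(c(0, 0, 0), 1)
  lat <- build_lattice(s, 0.25)
  sc <- find_starting_cubes(s, lat)
  expect_equal(nrow(sc), 6)
  expect_cubes_mixed(s, lat, sc)
  tt <- tetrahedron(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4)))
  latt <- build_lattice(tt, 0.1)
  sct <- find_starting_cubes(tt, latt)
  expect_gt(nrow(sct), 0)
  expect_cubes_mixed(tt, latt, sct)
  sp <- spindle(c(0, 0, 0), c(1, 0.2, 0), 2, 1, -0.8, 0.8)
  latsp <- build_lattice(sp, 0.2)
  scs <- find_starting_cubes(sp, latsp)
  expect_gt(nrow(scs), 0)
  expect_cubes_mixed(sp, latsp, scs)
})

test_that("degenerate solids yield no starting cubes", {
  ## sphere fully inside one cube straddling no corner
  s <- sphere(c(0.5, 0.5, 0.5) * 0.25 + c(1, 1, 1) * 0.25, 0.05)
  lat <- build_lattice(sphere(c(0.3, 0.3, 0.3), 2), 0.25)
  expect_equal(nrow(find_starting_cubes(s, lat)), 0)
})
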