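## Shared helpers and independent oracles for the suite.

## random point cloud in a box
rand_points <- function(n, lo = -4, hi = 4) {
  matrix(runif(3 * n, lo, hi), ncol = 3)
}

## random segment within a box
rand_segment <- function(lo = -4, hi = 4) {
  segment_from_to(runif(3, lo, hi), runif(3, lo, hi))
}

## dense-sampling interval oracle: classify n points along the segment and
## compare with the interval set (boundaries localized to within 1/n)
expect_intervals_match_sampling <- function(solid, seg, n = 2000, slack = 2) {
  iv <- intersect_segment(solid, seg)
  t <- seq(0, seg$t_max, length.out = n)
  truth <- contains_point(solid, seg_point(seg, t))
  est <- iv_covers(iv, t, tol = slack * seg$t_max / n)
  ## allow disagreement only within slack steps of a state flip
  flips <- which(diff(truth) != 0)
  near_flip <- rep(FALSE, n)
  for (f in flips) near_flip[max(1, f - slack):min(n, f + slack + 1)] <- TRUE
  expect_true(all(est[!near_flip] == truth[!near_flip]))
}

## boolean-formula oracle: leaf containment combined by plain logic
direct_boolean_eval <- function(node, pts) {
  if (!inherits(node, "csg_node")) return(contains_point(node, pts))
  a <- direct_boolean_eval(node$left, pts)
  b <- direct_boolean_eval(node$right, pts)
  if (node$op == "union") a | b
  else if (node$op == "intersection") a & b
  else a & !b
}

## mixed-corner oracle: every cube must have corners on both sides
expect_cubes_mixed <- function(solid, lat, cubes) {
  if (nrow(cubes) == 0) return(invisible(TRUE))
  st <- vapply(seq_len(nrow(cubes)), function(i) {
    off <- csgmol:::CORNER_OFFSETS
    pts <- csgmol:::lat_corner_coords(
      lat, sweep(matrix(rep(cubes[i, ], 8), 8, 3, byrow = TRUE), 2, 0) +
        off)
    s <- contains_point(solid, pts)
    any(s) && !all(s)
  }, logical(1))
  expect_true(all(st))
}

expect_watertight <- function(mesh) {
  expect_true(mesh_is_closed(mesh))
  expect_true(mesh_is_watertight(mesh))
}

## points deliberately away from a sphere boundary
off_boundary_points <- function(n, radius, eps = 1e-6, lo = -4, hi = 4) {
  p <- rand_points(n, lo, hi)
  d <- sqrt(rowSums(p^2))
  p[abs(d - radius) > eps, , drop = FALSE]
}
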