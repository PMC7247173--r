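## Synthetic fixtures: random primitive collections, toy molecules, and
## analytic point-charge potential grids.  All generators are
## seed-deterministic and need no network access.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random primitive collection
#'
#' A mixed bag of spheres, tetrahedra and spindles with characteristic radii
#' 0.5--3 Angstrom scattered in a bounding box; the stress-test workload for
#' CSG unions (thirty of these emulate a randomly generated primitive set).
#'
#' @param n number of primitives.
#' @param seed RNG seed; identical seeds give identical collections.
#' @param bbox length-2 numeric: primitives are centered in
#'   `[bbox[1], bbox[2]]^3`.
#' @return list of `n` solids.
#' @export
random_primitives <- function(n, seed = 1, bbox = c(-8, 8)) {
  stopifnot(n >= 1)
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      ctr <- stats::runif(3, bbox[1], bbox[2])
      kind <- sample(c("sphere", "tetra", "spindle"), 1)
      if (kind == "sphere") {
        sphere(ctr, stats::runif(1, 0.5, 3))
      } else if (kind == "tetra") {
        sc <- stats::runif(1, 0.5, 3)
        tetrahedron(matrix(ctr, 4, 3, byrow = TRUE) +
                    matrix(stats::rnorm(12), 4, 3) * sc)
      } else {
        R <- stats::runif(1, 1, 3)
        r <- stats::runif(1, 0.4, 0.9) * R
        axis <- stats::rnorm(3)
        cap <- stats::runif(1, 0.5, 0.95) * r
        spindle(ctr, axis, R, r, -cap, cap)
      }
    })
  })
}

#' Toy molecules
#'
#' Small deterministic atom sets used throughout the test suite in place of
#' downloaded structures:
#' * `"dimer"`: two 1.9 Angstrom atoms 3.0 Angstrom apart (one spindle).
#' * `"tetra"`: four 1.9 Angstrom atoms at tetrahedron corners, side 4.0.
#' * `"pocket"`: a ring of eight atoms forming a shallow pocket around the
#'   origin with a floor below it; `blocker = TRUE` drops an extra atom into
#'   the pocket.  The single-atom ligand sits at the pocket center; the
#'   receptor/ligand split is returned in the `ligand` attribute.
#' * `"chain"`: a helix-like chain of `n` bonded atoms.
#'
#' @param kind one of `"dimer"`, `"tetra"`, `"pocket"`, `"chain"`.
#' @param n chain length for `"chain"`.
#' @param blocker add the pocket-blocking atom (only for `"pocket"`).
#' @return data frame of atoms (`x`, `y`, `z`, `radius`, `element`,
#'   `serial`); for `"pocket"` with attribute `ligand` holding the ligand
#'   atom row.
#' @export
toy_molecule <- function(kind = c("dimer", "tetra", "pocket", "chain"),
                         n = 20, blocker = FALSE) {
  kind <- match.arg(kind)
  mk <- function(xyz, radius = 1.9, element = "C") {
    xyz <- matrix(xyz, ncol = 3)
    data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               radius = radius, element = element,
               serial = seq_len(nrow(xyz)))
  }
  if (kind == "dimer") {
    return(mk(rbind(c(-1.5, 0, 0), c(1.5, 0, 0))))
  }
  if (kind == "tetra") {
    s <- 4.0
    v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
         (s / (2 * sqrt(2)))
    return(mk(v))
  }
  if (kind == "pocket") {
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    ring <- cbind(4.0 * cos(ang), 4.0 * sin(ang), 0)
    floor1 <- cbind(2.0 * cos(ang + pi / 8), 2.0 * sin(ang + pi / 8), -2.6)
    pts <- rbind(ring, floor1, c(0, 0, -3.4))
    if (blocker) pts <- rbind(pts, c(1.6, 0, -0.4))
    atoms <- mk(pts)
    attr(atoms, "ligand") <- mk(c(0, 0, 0.5), radius = 1.7)
    return(atoms)
  }
  ## helix-like chain: ~1.8 Angstrom bond steps
  i <- seq_len(n)
  th <- i * 0.9
  pts <- cbind(2.3 * cos(th), 2.3 * sin(th), 0.9 * i)
  mk(pts)
}

#' Analytic point-charge potential grid
#'
#' Bare Coulomb potential `phi(x) = sum q_i / |x - c_i|` sampled on a regular
#' grid (units: charge in e, distances in Angstrom, potential in e/Angstrom).
#' A synthetic stand-in for a Poisson--Boltzmann solver's output grid;
#' screening effects are deliberately absent.
#'
#' @param charges data frame with columns `x`, `y`, `z`, `q`.
#' @param origin grid origin (corner), length-3.
#' @param delta grid spacing, scalar, Angstrom.
#' @param counts grid point counts per axis, length-3.
#' @return a `potential_grid` list: `origin`, `delta`, `counts`, `values`
#'   (array `counts[1] x counts[2] x counts[3]`).
#' @export
point_charge_grid <- function(charges, origin = c(-8, -8, -8), delta = 0.5,
                              counts = c(33, 33, 33)) {
  stopifnot(all(c("x", "y", "z", "q") %in% names(charges)))
  xs <- origin[1] + delta * (seq_len(counts[1]) - 1)
  ys <- origin[2] + delta * (seq_len(counts[2]) - 1)
  zs <- origin[3] + delta * (seq_len(counts[3]) - 1)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  phi <- numeric(nrow(g))
  for (i in seq_len(nrow(charges))) {
    d <- sqrt((g[, 1] - charges$x[i])^2 + (g[, 2] - charges$y[i])^2 +
              (g[, 3] - charges$z[i])^2)
    phi <- phi + charges$q[i] / pmax(d, 1e-6)
  }
  structure(list(origin = as.numeric(origin), delta = delta,
                 counts = as.integer(counts),
                 values = array(phi, dim = counts)),
            class = "potential_grid")
}
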