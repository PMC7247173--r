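## Regular (weighted Delaunay) triangulation and its dual graph.
##
## The solvent-excluded solid positions its primitives with the dual graph of
## the power diagram of the atoms, weighted by the solvent-expanded radii
## (w_i = (r_i + r_probe)^2): the power vertices of the expanded spheres are
## exactly the centers of probe spheres tangent to four atoms.  The
## triangulation is computed internally by the empty-orthosphere definition:
## a 4-subset of atoms belongs iff its orthosphere has nonnegative power
## distance to every other atom.  This is O(n^5) and intended for the small
## structures this package targets (tens of atoms); degenerate (coplanar)
## inputs are handled by a deterministic symbolic jitter that perturbs the
## combinatorics only, never the primitive geometry.

## deterministic sub-Angstrom jitter, reproducible across sessions
comb_jitter <- function(n, scale = 1e-6) {
  i <- rep(seq_len(n), 3); d <- rep(1:3, each = n)
  u <- ((i * 73856093 + d * 19349663) %% 20521) / 20521
  matrix((u - 0.5) * 2 * scale, n, 3)
}

#' Dual graph of the atoms' power diagram
#'
#' Computes the regular triangulation of the atom centers weighted by
#' `(radius + solvent_radius)^2` and extracts the dual graph: vertices at
#' atom centers, edges/triangles/tetrahedra from the triangulation.  Each
#' edge is flagged overlong iff it is longer than the sum of the endpoint
#' van der Waals radii and the solvent sphere's diameter (no probe can fit a
#' tangent position across a longer gap).
#'
#' @param atoms data frame with columns `x`, `y`, `z`, `radius` (one row per
#'   atom, coordinates and van der Waals radii in Angstrom).
#' @param solvent_radius probe radius, Angstrom (default 1.4).
#' @return list with `edges` (data frame `i`, `j`, `length`, `overlong`),
#'   `triangles` (m x 3 index matrix), `tri_tetra_count` (tetrahedra adjacent
#'   to each triangle), and `tetras` (k x 4 index matrix).
#' @export
compute_power_dual <- function(atoms, solvent_radius = 1.4) {
  stopifnot(nrow(atoms) >= 1, all(c("x", "y", "z", "radius") %in% names(atoms)),
            all(is.finite(as.matrix(atoms[, c("x", "y", "z", "radius")]))))
  n <- nrow(atoms)
  P <- as.matrix(atoms[, c("x", "y", "z")])
  edge_df <- function(E) {
    if (is.null(E) || nrow(E) == 0)
      return(data.frame(i = integer(0), j = integer(0), length = numeric(0),
                        overlong = logical(0)))
    E <- unique(t(apply(E, 1, sort)))
    len <- sqrt(rowSums((P[E[, 1], , drop = FALSE] - P[E[, 2], , drop = FALSE])^2))
    thr <- atoms$radius[E[, 1]] + atoms$radius[E[, 2]] + 2 * solvent_radius
    data.frame(i = E[, 1], j = E[, 2], length = len, overlong = len > thr)
  }
  if (n == 1)
    return(list(edges = edge_df(NULL), triangles = matrix(integer(0), 0, 3),
                tri_tetra_count = integer(0), tetras = matrix(integer(0), 0, 4)))
  if (n == 2)
    return(list(edges = edge_df(rbind(c(1L, 2L))),
                triangles = matrix(integer(0), 0, 3),
                tri_tetra_count = integer(0), tetras = matrix(integer(0), 0, 4)))
  if (n == 3)
    return(list(edges = edge_df(rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))),
                triangles = rbind(c(1L, 2L, 3L)), tri_tetra_count = 0L,
                tetras = matrix(integer(0), 0, 4)))
  if (n == 4) {
    tet <- rbind(1:4)
    tris <- t(utils::combn(4L, 3L))
    return(list(edges = edge_df(t(utils::combn(4L, 2L))), triangles = tris,
                tri_tetra_count = rep(1L, 4), tetras = tet))
  }

  Pj <- P + comb_jitter(n)
  w <- (atoms$radius + solvent_radius)^2
  lift <- rowSums(Pj^2) - w
  combs <- utils::combn(n, 4)
  tetras <- NULL
  for (k in seq_len(ncol(combs))) {
    id <- combs[, k]
    A <- 2 * (Pj[id[2:4], , drop = FALSE] -
              matrix(Pj[id[1], ], 3, 3, byrow = TRUE))
    b <- lift[id[2:4]] - lift[id[1]]
    detA <- det(A)
    if (abs(detA) < 1e-10) next      # (near-)coplanar after jitter: skip
    ctr <- solve(A, b)
    rho <- sum((ctr - Pj[id[1], ])^2) - w[id[1]]
    others <- setdiff(seq_len(n), id)
    pow <- rowSums(sweep(Pj[others, , drop = FALSE], 2, ctr)^2) - w[others]
    if (all(pow >= rho - 1e-9)) tetras <- rbind(tetras, id)
  }
  if (is.null(tetras)) {
    ## no valid tetrahedron survives (e.g. nearly degenerate cloud): fall
    ## back to the distance graph so downstream stages still see adjacency
    E <- t(utils::combn(n, 2L))
    return(list(edges = edge_df(E), triangles = matrix(integer(0), 0, 3),
                tri_tetra_count = integer(0), tetras = matrix(integer(0), 0, 4)))
  }
  E <- NULL; Tri <- NULL
  for (r in seq_len(nrow(tetras))) {
    id <- tetras[r, ]
    E <- rbind(E, t(utils::combn(id, 2L)))
    Tri <- rbind(Tri, t(utils::combn(id, 3L)))
  }
  Tri <- t(apply(Tri, 1, sort))
  key <- paste(Tri[, 1], Tri[, 2], Tri[, 3])
  cnt <- table(key)
  uq <- !duplicated(key)
  tri_u <- Tri[uq, , drop = FALSE]
  tri_cnt <- as.integer(cnt[paste(tri_u[, 1], tri_u[, 2], tri_u[, 3])])
  list(edges = edge_df(E), triangles = tri_u, tri_tetra_count = tri_cnt,
       tetras = tetras)
}

#' Probe sphere tangent to three atoms
#'
#' Trilateration: centers `c` with `|c - center_i| = radius_i +
#' solvent_radius` for each of the three atoms.  In general position there
#' are two mirror solutions across the atom plane, one, or none (the
#' expanded spheres admit no common point).  Colinear atoms are degenerate
#' and return no solution.
#'
#' @param centers 3 x 3 matrix of atom centers (rows).
#' @param radii length-3 van der Waals radii.
#' @param solvent_radius probe radius, Angstrom.
#' @return 0-, 1- or 2-row matrix of candidate probe centers.
#' @export
place_solvent_tangent_sphere <- function(centers, radii, solvent_radius) {
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == 3, ncol(centers) == 3)
  R <- radii + solvent_radius
  u <- centers[2, ] - centers[1, ]
  v <- centers[3, ] - centers[1, ]
  nrm <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  nn <- vnorm(nrm)
  if (nn < 1e-10 * max(vnorm(u), vnorm(v), 1)) {
    message("tangent probe placement skipped for (nearly) colinear atoms")
    return(matrix(numeric(0), 0, 3))
  }
  nrm <- nrm / nn
  ## in-plane point q = c1 + alpha u + beta v satisfying both tangency
  ## difference equations
  b1 <- (sum(u * u) + R[1]^2 - R[2]^2) / 2
  b2 <- (sum(v * v) + R[1]^2 - R[3]^2) / 2
  G <- rbind(c(sum(u * u), sum(u * v)), c(sum(u * v), sum(v * v)))
  ab <- solve(G, c(b1, b2))
  q <- centers[1, ] + ab[1] * u + ab[2] * v
  h2 <- R[1]^2 - sum((q - centers[1, ])^2)
  if (h2 < -1e-12) return(matrix(numeric(0), 0, 3))
  if (h2 < 0) h2 <- 0
  h <- sqrt(h2)
  if (h < 1e-12) return(matrix(q, 1, 3))
  rbind(q + h * nrm, q - h * nrm)
}
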