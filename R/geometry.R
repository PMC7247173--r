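## Shared geometric constants, segments, and the solid generic contract.

## separation of the two artificial points generated at a tangency (Angstrom)
EPS_TANGENT <- 1e-9
## absolute boundary tolerance for containment comparisons (Angstrom)
EPS_BOUNDARY <- 1e-12

#' Line segments
#'
#' A segment is parameterized as `point(t) = origin + t * direction` for
#' `t` in `[0, t_max]`.  `segment_from_to()` builds the segment between two
#' points with `t_max = 1`, so `t` is the fraction along the segment.
#'
#' @param origin numeric length-3 start point (Angstrom).
#' @param direction numeric length-3 direction vector (nonzero norm).
#' @param t_max upper end of the parameter range.
#' @return an object of class `"segment"`.
#' @export
segment <- function(origin, direction, t_max = 1) {
  origin <- as.numeric(origin); direction <- as.numeric(direction)
  stopifnot(length(origin) == 3, length(direction) == 3,
            all(is.finite(origin)), all(is.finite(direction)))
  n2 <- sum(direction^2)
  if (n2 == 0) stop("segment direction must have nonzero norm")
  structure(list(origin = origin, dir = direction, t_max = as.numeric(t_max),
                 len = sqrt(n2)),
            class = "segment")
}

#' @rdname segment
#' @param from,to numeric length-3 endpoints.
#' @export
segment_from_to <- function(from, to) segment(from, as.numeric(to) - as.numeric(from), 1)

#' @rdname segment
#' @param seg a segment.
#' @param t numeric vector of parameters.
#' @return `seg_point()`: a `length(t)` x 3 matrix of points.
#' @export
seg_point <- function(seg, t) {
  cbind(seg$origin[1] + t * seg$dir[1],
        seg$origin[2] + t * seg$dir[2],
        seg$origin[3] + t * seg$dir[3])
}

## tangency half-width in t units for a given segment
seg_eps_t <- function(seg) EPS_TANGENT / seg$len

#' The three basic solid functions
#'
#' Every solid in the package -- leaf primitives ([sphere()], [tetrahedron()],
#' [spindle()]), [molecular solids][build_molecular_solid], [mesh
#' solids][prepare_mesh_solid] and CSG nodes ([csg_union()] and friends) --
#' answers the same three questions:
#'
#' * `contains_point(s, p)`: is each point inside the solid?  A point exactly
#'   on the surface counts as inside.
#' * `intersect_segment(s, seg)`: the interval set of segment parameters where
#'   the segment is inside the solid.
#' * `find_starting_cubes(s, lat)`: a few lattice cubes straddling the solid's
#'   surface (at least one corner inside and one outside), used to seed the
#'   breadth-first surface search.
#'
#' @param s a solid.
#' @param p numeric length-3 point or an n x 3 matrix of points.
#' @param seg a [segment()].
#' @param lat a [build_lattice()] lattice enclosing the solid.
#' @return `contains_point()`: logical vector; `intersect_segment()`: interval
#'   set matrix; `find_starting_cubes()`: integer matrix of cube triples
#'   (0-based, one row per cube).
#' @export
contains_point <- function(s, p) UseMethod("contains_point")

#' @rdname contains_point
#' @export
intersect_segment <- function(s, seg) UseMethod("intersect_segment")

#' @rdname contains_point
#' @export
find_starting_cubes <- function(s, lat) UseMethod("find_starting_cubes")

#' @rdname contains_point
#' @export
solid_bbox <- function(s) UseMethod("solid_bbox")

## coerce a point argument to an n x 3 matrix
as_points <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    p
  } else {
    stopifnot(length(p) == 3)
    matrix(as.numeric(p), ncol = 3)
  }
}

vnorm <- function(v) sqrt(sum(v^2))

## deterministic orthonormal completion of a unit axis: pivot on the axis
## component of largest magnitude so the frame is bit-reproducible
orthonormal_frame <- function(axis) {
  a <- axis / vnorm(axis)
  k <- which.max(abs(a))
  e <- c(0, 0, 0); e[if (k == 1L) 2L else 1L] <- 1
  u <- e - sum(e * a) * a
  u <- u / vnorm(u)
  v <- c(a[2] * u[3] - a[3] * u[2],
         a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  list(a = a, u = u, v = v)
}
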