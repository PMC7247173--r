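## Exact leaf solids: spheres and tetrahedra.
##
## Both follow the global boundary rule: a point exactly on the surface is
## inside the solid.  Containment comparisons use an absolute tolerance of
## EPS_BOUNDARY at the boundary.

#' Sphere solid
#'
#' A sphere defined by center and radius.  `negative = TRUE` marks a
#' "negsphere": a probe-sized sphere that carves solvent space out of a cup
#' inside a [molecular solid][build_molecular_solid].  As a standalone solid a
#' negsphere behaves like an ordinary sphere; its negativity is interpreted by
#' the molecular solid that owns it.
#'
#' @param center numeric length-3 center (Angstrom).
#' @param radius sphere radius, Angstrom, `> 0`.
#' @param negative logical negsphere flag.
#' @return a solid of class `"sphere"`.
#' @export
sphere <- function(center, radius, negative = FALSE) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3, is.finite(radius), radius > 0)
  structure(list(center = center, radius = as.numeric(radius),
                 negative = isTRUE(negative)),
            class = c("sphere", "csg_solid"))
}

#' @export
contains_point.sphere <- function(s, p) {
  p <- as_points(p)
  d2 <- (p[, 1] - s$center[1])^2 + (p[, 2] - s$center[2])^2 +
        (p[, 3] - s$center[3])^2
  d2 <= (s$radius + EPS_BOUNDARY)^2
}

#' @export
intersect_segment.sphere <- function(s, seg) {
  oc <- seg$origin - s$center
  a <- sum(seg$dir^2)
  b <- 2 * sum(oc * seg$dir)
  c0 <- sum(oc^2) - s$radius^2
  disc <- b * b - 4 * a * c0
  eps_t <- seg_eps_t(seg)
  if (disc <= 0) {
    ## possible tangency: closest approach within boundary tolerance of the
    ## radius generates two artificial intersection points at a trivial
    ## separation, i.e. a degenerate interval of width 2 * EPS_TANGENT
    tstar <- -b / (2 * a)
    pm <- seg$origin + tstar * seg$dir
    dmin <- vnorm(pm - s$center)
    if (abs(dmin - s$radius) <= 1e-9) {
      return(iv_clip(cbind(tstar - eps_t, tstar + eps_t), 0, seg$t_max))
    }
    return(iv_empty())
  }
  sq <- sqrt(disc)
  t1 <- (-b - sq) / (2 * a)
  t2 <- (-b + sq) / (2 * a)
  iv_clip(cbind(t1, t2), 0, seg$t_max)
}

#' @export
solid_bbox.sphere <- function(s) {
  rbind(s$center - s$radius, s$center + s$radius)
}

#' @export
find_starting_cubes.sphere <- function(s, lat) {
  ## cube containing the center, then step outwards in the six orthogonal
  ## directions until a surface cube is met in each
  c0 <- lat_cube_of(lat, s$center)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  found <- NULL
  for (d in seq_len(6)) {
    cube <- c0
    repeat {
      if (!lat_in_bounds(lat, cube)) break
      if (cubes_mixed(s, lat, matrix(cube, ncol = 3))) {
        found <- rbind(found, cube)
        break
      }
      cube <- cube + dirs[d, ]
    }
  }
  unique_cubes(found)
}

#' Tetrahedron solid
#'
#' A tetrahedron defined by four corners.  Containment tests the point against
#' the four face half-spaces (closed: face points are inside).
#'
#' @param corners 4 x 3 numeric matrix of corner coordinates (Angstrom).
#' @return a solid of class `"tetrahedron"`.
#' @export
tetrahedron <- function(corners) {
  corners <- as.matrix(corners)
  stopifnot(nrow(corners) == 4, ncol(corners) == 3, all(is.finite(corners)))
  ## face normals oriented inward (toward the opposite corner), unit length
  faces <- rbind(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 4, 2), c(2, 3, 4, 1))
  normals <- matrix(0, 4, 3); offs <- numeric(4)
  degenerate <- FALSE
  for (f in 1:4) {
    A <- corners[faces[f, 1], ]; B <- corners[faces[f, 2], ]
    C <- corners[faces[f, 3], ]; D <- corners[faces[f, 4], ]
    ab <- B - A; ac <- C - A
    n <- c(ab[2] * ac[3] - ab[3] * ac[2],
           ab[3] * ac[1] - ab[1] * ac[3],
           ab[1] * ac[2] - ab[2] * ac[1])
    nn <- vnorm(n)
    if (nn < 1e-14) { degenerate <- TRUE; n <- c(1, 0, 0); nn <- 1 }
    n <- n / nn
    if (sum(n * (D - A)) < 0) n <- -n
    normals[f, ] <- n
    offs[f] <- sum(n * A)
  }
  structure(list(corners = corners, normals = normals, offsets = offs,
                 degenerate = degenerate),
            class = c("tetrahedron", "csg_solid"))
}

#' @export
contains_point.tetrahedron <- function(s, p) {
  p <- as_points(p)
  inside <- rep(TRUE, nrow(p))
  for (f in 1:4) {
    d <- p %*% s$normals[f, ] - s$offsets[f]
    inside <- inside & (d >= -EPS_BOUNDARY)
  }
  as.vector(inside)
}

#' @export
intersect_segment.tetrahedron <- function(s, seg) {
  ## clip the parameter range against the four closed half-spaces; a segment
  ## colinear with an edge or face falls out naturally as the overlap interval
  lo <- 0; hi <- seg$t_max
  for (f in 1:4) {
    a <- sum(s$normals[f, ] * seg$dir)
    b <- sum(s$normals[f, ] * seg$origin) - s$offsets[f]
    if (abs(a) < 1e-14) {
      if (b < -EPS_BOUNDARY) return(iv_empty())
    } else if (a > 0) {
      lo <- max(lo, (-EPS_BOUNDARY - b) / a)
    } else {
      hi <- min(hi, (-EPS_BOUNDARY - b) / a)
    }
    if (lo > hi + 2 * seg_eps_t(seg)) return(iv_empty())
  }
  if (lo > hi) {
    ## tangency to an edge or corner: two artificial points at a trivial
    ## separation
    mid <- (lo + hi) / 2
    eps_t <- seg_eps_t(seg)
    return(iv_clip(cbind(mid - eps_t, mid + eps_t), 0, seg$t_max))
  }
  cbind(lo = lo, hi = hi)
}

#' @export
solid_bbox.tetrahedron <- function(s) {
  rbind(apply(s$corners, 2, min), apply(s$corners, 2, max))
}

#' @export
find_starting_cubes.tetrahedron <- function(s, lat) {
  ## per corner: the corner's cube if it is a surface cube, else walk along
  ## the corner -> opposite-face-center ray until a surface cube or ray end
  found <- NULL
  for (i in 1:4) {
    corner <- s$corners[i, ]
    opp <- colMeans(s$corners[-i, , drop = FALSE])
    hit <- walk_cubes_until_mixed(s, lat, corner, opp)
    if (!is.null(hit)) found <- rbind(found, hit)
  }
  unique_cubes(found)
}
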