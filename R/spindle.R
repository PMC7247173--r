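## Spindle solids and torus--segment intersection.
##
## A spindle is the solvent-excluded region between two nearby atoms: the
## volume inside a capped cylinder of radius R (the circle traced by the
## rolling probe center) minus the interior of the coaxial torus whose tube
## (minor radius r, the probe radius) is traced by the probe itself.  "Broken"
## spindles (R < r) arise when the probe's edge can pass beyond the
## centerline, opening a hole through the middle.

#' Spindle solid
#'
#' @param center length-3 center: the perpendicular projection of the probe
#'   center onto the interatomic axis.
#' @param axis length-3 perpendicular vector (need not be unit).
#' @param R torus major radius (probe-center circle radius), Angstrom.
#' @param r torus minor radius (probe radius), Angstrom, `> 0`.
#' @param cap_lo,cap_hi signed endcap offsets along the axis, `cap_lo <
#'   cap_hi`, each within `[-r, r]`.
#' @param broken logical; defaults to `R < r` (probe reaches past the
#'   centerline).
#' @return a solid of class `"spindle"`.
#' @export
spindle <- function(center, axis, R, r, cap_lo, cap_hi, broken = R < r) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3, r > 0, cap_lo < cap_hi, R >= 0)
  fr <- orthonormal_frame(as.numeric(axis))
  structure(list(center = center, axis = fr$a, u = fr$u, v = fr$v,
                 R = as.numeric(R), r = as.numeric(r),
                 cap_lo = as.numeric(cap_lo), cap_hi = as.numeric(cap_hi),
                 broken = isTRUE(broken)),
            class = c("spindle", "csg_solid"))
}

## canonical (axial, radial^2) coordinates of points, vectorized
spindle_canon <- function(s, p) {
  dx <- p[, 1] - s$center[1]; dy <- p[, 2] - s$center[2]; dz <- p[, 3] - s$center[3]
  a <- dx * s$axis[1] + dy * s$axis[2] + dz * s$axis[3]
  rho2 <- pmax(dx^2 + dy^2 + dz^2 - a^2, 0)
  list(a = a, rho = sqrt(rho2))
}

## cross-section membership in (axial, radial) coordinates: inside the
## rectangle of the cylinder and outside (or on) the circle of the torus tube
spindle_inside_ar <- function(s, a, rho) {
  tube <- sqrt(a^2 + (rho - s$R)^2)
  (a >= s$cap_lo - EPS_BOUNDARY) & (a <= s$cap_hi + EPS_BOUNDARY) &
    (rho <= s$R + EPS_BOUNDARY) & (tube >= s$r - EPS_BOUNDARY)
}

#' @export
contains_point.spindle <- function(s, p) {
  p <- as_points(p)
  cc <- spindle_canon(s, p)
  spindle_inside_ar(s, cc$a, cc$rho)
}

#' @export
solid_bbox.spindle <- function(s) {
  ## conservative per-axis extent: axial reach of the caps plus radial reach R
  ax <- abs(s$axis)
  ext <- ax * max(abs(s$cap_lo), abs(s$cap_hi)) + sqrt(pmax(1 - ax^2, 0)) * s$R
  rbind(s$center - ext, s$center + ext)
}

#' Real roots of the torus--segment quartic
#'
#' In the spindle's canonical frame (center at the origin, axis along x) the
#' torus is `(x^2+y^2+z^2+R^2-r^2)^2 - 4 R^2 (y^2+z^2) = 0`.  Substituting the
#' parameterized line `origin + t * dir` yields a quartic in `t`, solved as
#' the eigenvalues of its Frobenius companion matrix.  Complex eigenvalues
#' correspond to nonexistent intersection points; real ones (imaginary part
#' below `1e-8 * max(1, |Re|)`, since companion eigensolvers perturb real
#' roots into conjugate pairs near tangency) are returned sorted ascending.
#'
#' @param sp a [spindle()] supplying R and r.
#' @param origin,dir segment origin and direction, already transformed into
#'   the canonical frame.
#' @return sorted numeric vector of real roots (possibly empty).
#' @export
solve_torus_quartic <- function(sp, origin, dir) {
  R <- sp$R; r <- sp$r
  c2 <- sum(dir^2)
  c1 <- 2 * sum(origin * dir)
  c0 <- sum(origin^2) + R^2 - r^2
  b2 <- dir[2]^2 + dir[3]^2
  b1 <- 2 * (origin[2] * dir[2] + origin[3] * dir[3])
  b0 <- origin[2]^2 + origin[3]^2
  k4 <- c2^2
  k3 <- 2 * c1 * c2
  k2 <- c1^2 + 2 * c0 * c2 - 4 * R^2 * b2
  k1 <- 2 * c0 * c1 - 4 * R^2 * b1
  k0 <- c0^2 - 4 * R^2 * b0
  if (k4 < 1e-300) {
    ## degenerate direction; fall back to a cubic/quadratic solve
    return(sort(Re(polyroot(c(k0, k1, k2, k3))[
      abs(Im(polyroot(c(k0, k1, k2, k3)))) < 1e-8])))
  }
  a3 <- k3 / k4; a2 <- k2 / k4; a1 <- k1 / k4; a0 <- k0 / k4
  comp <- rbind(c(0, 0, 0, -a0),
                c(1, 0, 0, -a1),
                c(0, 1, 0, -a2),
                c(0, 0, 1, -a3))
  ev <- eigen(comp, only.values = TRUE)$values
  keep <- abs(Im(ev)) <= 1e-8 * pmax(1, abs(Re(ev)))
  sort(Re(ev[keep]))
}

#' @export
intersect_segment.spindle <- function(s, seg) {
  ## transform into the canonical frame
  o <- seg$origin - s$center
  oc <- c(sum(o * s$axis), sum(o * s$u), sum(o * s$v))
  dc <- c(sum(seg$dir * s$axis), sum(seg$dir * s$u), sum(seg$dir * s$v))
  tmax <- seg$t_max

  ## candidate boundary parameters: torus quartic roots, endcap plane
  ## crossings, cylinder (rho = R) crossings, and the segment ends
  cand <- c(0, tmax)
  cand <- c(cand, solve_torus_quartic(s, oc, dc))
  if (abs(dc[1]) > 1e-14) {
    cand <- c(cand, (s$cap_lo - oc[1]) / dc[1], (s$cap_hi - oc[1]) / dc[1])
  }
  qa <- dc[2]^2 + dc[3]^2
  qb <- 2 * (oc[2] * dc[2] + oc[3] * dc[3])
  qc <- oc[2]^2 + oc[3]^2 - s$R^2
  if (qa > 1e-14) {
    disc <- qb^2 - 4 * qa * qc
    if (disc > 0) cand <- c(cand, (-qb + c(-1, 1) * sqrt(disc)) / (2 * qa))
  }
  cand <- sort(unique(pmin(pmax(cand, 0), tmax)))
  if (length(cand) < 2) return(iv_empty())

  ## classify span midpoints with the cross-section rule so that intervals are
  ## consistent with contains_point by construction
  mids <- (cand[-1] + cand[-length(cand)]) / 2
  av <- oc[1] + mids * dc[1]
  rho <- sqrt((oc[2] + mids * dc[2])^2 + (oc[3] + mids * dc[3])^2)
  ins <- spindle_inside_ar(s, av, rho)
  m <- if (any(ins)) cbind(cand[-length(cand)][ins], cand[-1][ins])
       else iv_empty()
  ## isolated boundary touches (tangencies, e.g. grazing the torus or a cap
  ## rim) are not covered by any inside span; emit the two artificial points
  ## at a trivial separation as a degenerate interval
  eps_t <- seg_eps_t(seg)
  ac <- oc[1] + cand * dc[1]
  rc <- sqrt((oc[2] + cand * dc[2])^2 + (oc[3] + cand * dc[3])^2)
  touch <- spindle_inside_ar(s, ac, rc)
  spanned <- c(ins, FALSE) | c(FALSE, ins)
  iso <- touch & !spanned
  if (any(iso))
    m <- rbind(m, cbind(cand[iso] - eps_t, cand[iso] + eps_t))
  if (nrow(m) == 0) return(iv_empty())
  iv_clip(iv_normalize(m, gap = eps_t), 0, tmax)
}

#' @export
find_starting_cubes.spindle <- function(s, lat) {
  capA <- s$center + s$cap_lo * s$axis
  capB <- s$center + s$cap_hi * s$axis
  walks <- if (s$broken) {
    ## probe reaches past the centerline: walk from each endcap centroid
    ## toward the center so both lobes are seeded
    list(c_from = list(capA, capB), c_to = list(s$center, s$center))
  } else {
    list(c_from = list(capA), c_to = list(capB))
  }
  found <- NULL
  for (i in seq_along(walks$c_from)) {
    hit <- walk_cubes_until_mixed(s, lat, walks$c_from[[i]], walks$c_to[[i]])
    if (!is.null(hit)) found <- rbind(found, hit)
  }
  unique_cubes(found)
}
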