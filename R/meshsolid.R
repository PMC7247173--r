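## Closed triangle meshes interpreted as exact solids.
##
## Preparation classifies an internal lattice: cubes containing triangles are
## nonempty, the rest are empty; empty cubes are grouped into face-adjacent
## connected components and labeled interior or exterior by ray parity
## against the mesh (lattice-edge components are exterior by definition, and
## the parity test resolves thin-wall abnormalities where a void boundary
## and the outer surface share a cube).  Containment inside nonempty cubes
## is decided by majority vote over five segments cast to nearby empty-cube
## centers.

## flood-fill connected components on a logical array (6-adjacency);
## returns an integer array of labels (0 where mask is FALSE)
array_components <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nextlab <- 0L
  idx <- which(mask & lab == 0L)
  while (length(idx) > 0) {
    nextlab <- nextlab + 1L
    seedv <- idx[1]
    frontier <- arrayInd(seedv, dims)
    lab[seedv] <- nextlab
    while (nrow(frontier) > 0) {
      nb <- do.call(rbind, lapply(1:6, function(d)
        sweep(frontier, 2, FACE_NEIGHBORS[d, ], "+")))
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0) break
      lin <- nb[, 1] + dims[1] * (nb[, 2] - 1) + dims[1] * dims[2] * (nb[, 3] - 1)
      keep <- !duplicated(lin) & mask[cbind(nb[, 1], nb[, 2], nb[, 3])] &
              lab[cbind(nb[, 1], nb[, 2], nb[, 3])] == 0L
      nb <- nb[keep, , drop = FALSE]
      if (nrow(nb) == 0) break
      lab[cbind(nb[, 1], nb[, 2], nb[, 3])] <- nextlab
      frontier <- nb
    }
    idx <- which(mask & lab == 0L)
  }
  lab
}

#' Interpret a closed triangle mesh as a solid
#'
#' @param mesh a closed [triangle_mesh()] (every edge shared by exactly two
#'   triangles); violations raise a validation error reporting the number of
#'   boundary edges.
#' @param resolution internal lattice cube size, Angstrom; defaults should
#'   match the resolution requested from the downstream mesher.
#' @return a solid of class `"mesh_solid"`.
#' @examples
#' m <- mesh_solid_boundary(sphere(c(0, 0, 0), 1), 0.25)
#' msd <- prepare_mesh_solid(m, 0.25)
#' contains_point(msd, c(0, 0, 0))
#' @export
prepare_mesh_solid <- function(mesh, resolution) {
  stopifnot(inherits(mesh, "triangle_mesh"), resolution > 0)
  degen <- mesh$triangles[, 1] == mesh$triangles[, 2] |
           mesh$triangles[, 2] == mesh$triangles[, 3] |
           mesh$triangles[, 1] == mesh$triangles[, 3]
  if (any(degen)) {
    warning(sprintf("dropping %d degenerate triangles", sum(degen)))
    mesh <- triangle_mesh(mesh$vertices, mesh$triangles[!degen, , drop = FALSE])
  }
  tab <- table(mesh_edge_keys(mesh))
  if (any(tab != 2L))
    stop(sprintf("mesh is not closed: %d boundary/non-manifold edges",
                 sum(tab != 2L)))
  V <- mesh$vertices; Tr <- mesh$triangles
  lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  lo_i <- floor(lo / resolution) - 1; hi_i <- ceiling(hi / resolution) + 1
  lat <- structure(list(origin = lo_i * resolution, res = resolution,
                        dims = as.integer(hi_i - lo_i)),
                   class = "lattice")
  ## conservative triangle registration over triangle bounding boxes
  hash <- new.env(hash = TRUE, size = 4096L)
  nonempty <- array(FALSE, lat$dims)
  ta <- V[Tr[, 1], , drop = FALSE]; tb <- V[Tr[, 2], , drop = FALSE]
  tc <- V[Tr[, 3], , drop = FALSE]
  tlo <- lat_cube_of(lat, pmin(ta, pmin(tb, tc)))
  thi <- lat_cube_of(lat, pmax(ta, pmax(tb, tc)))
  for (t in seq_len(nrow(Tr))) {
    for (ix in tlo[t, 1]:thi[t, 1]) for (iy in tlo[t, 2]:thi[t, 2])
      for (iz in tlo[t, 3]:thi[t, 3]) {
        key <- as.character(ix + lat$dims[1] * (iy + lat$dims[2] * iz))
        hash[[key]] <- c(hash[[key]], t)
        nonempty[ix + 1, iy + 1, iz + 1] <- TRUE
      }
  }
  ne_lab <- array_components(nonempty)
  em_lab <- array_components(!nonempty)
  n_em <- max(em_lab)
  ## empty components touching the lattice boundary are exterior by
  ## definition; the rest are labeled by ray parity from a representative
  boundary_labs <- unique(c(em_lab[1, , ], em_lab[lat$dims[1], , ],
                            em_lab[, 1, ], em_lab[, lat$dims[2], ],
                            em_lab[, , 1], em_lab[, , lat$dims[3]]))
  interior <- rep(NA, n_em)
  interior[setdiff(boundary_labs, 0L)] <- FALSE
  out_pt <- lat$origin - c(1.7, 2.3, 3.1) * lat$res
  for (l in seq_len(n_em)) {
    if (!is.na(interior[l])) next
    rep_cube <- arrayInd(which(em_lab == l)[1], lat$dims) - 1L
    ctr <- lat$origin + (rep_cube + 0.5) * lat$res
    vote <- NA
    for (att in 1:5) {
      tgt <- out_pt + (att - 1) * c(0.31, -0.17, 0.23) * lat$res
      hits <- segment_triangle_hits(ctr, tgt, V, Tr)
      if (!is.na(hits)) { vote <- hits %% 2 == 1; break }
    }
    interior[l] <- isTRUE(vote)
  }
  ## one representative cube per nonempty component (for starting cubes)
  reps <- lapply(seq_len(max(ne_lab)), function(l)
    which(ne_lab == l))
  structure(list(mesh = mesh, lat = lat, hash = hash,
                 nonempty = nonempty, ne_lab = ne_lab, em_lab = em_lab,
                 em_interior = interior, ne_members = reps),
            class = c("mesh_solid", "csg_solid"))
}

meshsolid_tris_along <- function(s, p0, p1) {
  path <- voxel_traverse(s$lat, p0, p1)
  if (nrow(path) == 0) return(integer(0))
  keys <- as.character(path[, 1] + s$lat$dims[1] *
                       (path[, 2] + s$lat$dims[2] * path[, 3]))
  sort(unique(unlist(lapply(keys, function(k) s$hash[[k]]))))
}

## the five nearest empty-cube centers to p (expanding ring search)
nearby_empty_centers <- function(s, cube, p, want = 5L) {
  dims <- s$lat$dims
  found <- NULL
  ring <- 1L
  while (ring <= max(dims)) {
    lo <- pmax(cube - ring, 0L); hi <- pmin(cube + ring, dims - 1L)
    sl <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
    shell <- as.matrix(sl[pmax(abs(sl$i - cube[1]), pmax(abs(sl$j - cube[2]),
                                abs(sl$k - cube[3]))) == ring, , drop = FALSE])
    if (nrow(shell) > 0) {
      emp <- !s$nonempty[cbind(shell[, 1] + 1, shell[, 2] + 1, shell[, 3] + 1)]
      found <- rbind(found, shell[emp, , drop = FALSE])
    }
    ## one extra ring after enough hits so true nearest centers are included
    if (!is.null(found) && nrow(found) >= want && ring >= 2L) break
    ring <- ring + 1L
  }
  if (is.null(found) || nrow(found) == 0) return(NULL)
  ctrs <- sweep((found + 0.5) * s$lat$res, 2, s$lat$origin, "+")
  d <- sqrt(rowSums(sweep(ctrs, 2, p)^2))
  ord <- order(d)
  list(cubes = found[ord, , drop = FALSE][seq_len(min(want, nrow(found))), ,
                                          drop = FALSE],
       centers = ctrs[ord, , drop = FALSE][seq_len(min(want, nrow(found))), ,
                                           drop = FALSE])
}

meshsolid_contains_one <- function(s, p) {
  cube <- lat_cube_of(s$lat, p)[1, ]
  if (!all(cube >= 0L) || !all(cube < s$lat$dims)) return(FALSE)
  ci <- cube + 1L
  if (!s$nonempty[ci[1], ci[2], ci[3]]) {
    l <- s$em_lab[ci[1], ci[2], ci[3]]
    return(s$em_interior[l])
  }
  ## voting: five segments to nearby empty-cube centers
  nb <- nearby_empty_centers(s, cube, p)
  if (is.null(nb)) return(FALSE)
  votes <- 0L; cast <- 0L
  V <- s$mesh$vertices; Tr <- s$mesh$triangles
  for (i in seq_len(nrow(nb$centers))) {
    tgt <- nb$centers[i, ]
    tl <- s$em_lab[nb$cubes[i, 1] + 1, nb$cubes[i, 2] + 1, nb$cubes[i, 3] + 1]
    tgt_in <- s$em_interior[tl]
    hits <- NA
    for (att in 1:4) {
      tj <- tgt + (att - 1) * c(0.11, -0.07, 0.05) * s$lat$res * 0.5
      tris <- meshsolid_tris_along(s, p, tj)
      hits <- if (length(tris) == 0) 0L else
        segment_triangle_hits(p, tj, V, Tr[tris, , drop = FALSE])
      if (!is.na(hits)) break
    }
    if (is.na(hits)) next
    even <- hits %% 2 == 0
    p_interior <- if (tgt_in) even else !even
    votes <- votes + if (p_interior) 1L else -1L
    cast <- cast + 1L
  }
  votes > 0L
}

#' @export
contains_point.mesh_solid <- function(s, p) {
  p <- as_points(p)
  vapply(seq_len(nrow(p)), function(i) meshsolid_contains_one(s, p[i, ]),
         logical(1))
}

#' @export
intersect_segment.mesh_solid <- function(s, seg) {
  p0 <- seg$origin; p1 <- seg$origin + seg$t_max * seg$dir
  V <- s$mesh$vertices; Tr <- s$mesh$triangles
  s0 <- meshsolid_contains_one(s, p0)
  s1 <- meshsolid_contains_one(s, p1)
  perp <- orthonormal_frame(seg$dir)
  for (att in 0:4) {
    ## deterministic jitter of the segment when a crossing is degenerate or
    ## the crossing parity disagrees with the endpoint states
    off <- if (att == 0) c(0, 0, 0) else
      1e-7 * att * (perp$u * cos(att) + perp$v * sin(att))
    tris <- meshsolid_tris_along(s, p0 + off, p1 + off)
    ts <- if (length(tris) == 0) numeric(0) else
      segment_triangle_ts(p0 + off, p1 + off, V, Tr[tris, , drop = FALSE])
    if (anyNA(ts)) next
    ts <- sort(ts)
    if ((length(ts) %% 2 == 0) != (s0 == s1)) next
    bnds <- c(0, ts * seg$t_max, seg$t_max)
    states <- rep(c(s0, !s0), length.out = length(bnds) - 1)
    ins <- which(states)
    if (length(ins) == 0) return(iv_empty())
    return(iv_normalize(cbind(bnds[ins], bnds[ins + 1]),
                        gap = seg_eps_t(seg)))
  }
  ## all casts degenerate: fall back to midpoint classification on spans
  ts <- sort(stats::na.omit(segment_triangle_ts(p0, p1, V, Tr, strict = FALSE)))
  bnds <- unique(c(0, ts * seg$t_max, seg$t_max))
  mids <- (bnds[-1] + bnds[-length(bnds)]) / 2
  ins <- contains_point(s, seg_point(seg, mids))
  if (!any(ins)) return(iv_empty())
  iv_normalize(cbind(bnds[-length(bnds)][ins], bnds[-1][ins]),
               gap = seg_eps_t(seg))
}

## parameters of segment-triangle crossings; NA marks a degenerate hit
segment_triangle_ts <- function(p0, p1, V, Tr, eps = 1e-9, strict = TRUE) {
  d <- p1 - p0
  a <- V[Tr[, 1], , drop = FALSE]
  e1 <- V[Tr[, 2], , drop = FALSE] - a
  e2 <- V[Tr[, 3], , drop = FALSE] - a
  h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
             d[3] * e2[, 1] - d[1] * e2[, 3],
             d[1] * e2[, 2] - d[2] * e2[, 1])
  det <- rowSums(e1 * h)
  sv <- matrix(p0, nrow(a), 3, byrow = TRUE) - a
  q <- cbind(sv[, 2] * e1[, 3] - sv[, 3] * e1[, 2],
             sv[, 3] * e1[, 1] - sv[, 1] * e1[, 3],
             sv[, 1] * e1[, 2] - sv[, 2] * e1[, 1])
  keep <- abs(det) > 1e-14
  u <- ifelse(keep, rowSums(sv * h) / det, Inf)
  v <- ifelse(keep, (q[, 1] * d[1] + q[, 2] * d[2] + q[, 3] * d[3]) / det, Inf)
  t <- ifelse(keep, rowSums(e2 * q) / det, Inf)
  inside <- u >= eps & v >= eps & (u + v) <= 1 - eps & t > eps & t < 1 - eps
  near <- is.finite(u) &
    ((u > -eps & u < eps) | (v > -eps & v < eps) |
     (u + v > 1 - eps & u + v < 1 + eps)) & t > -eps & t < 1 + eps
  if (strict && any(near & !inside)) return(NA_real_)
  t[inside]
}

#' @export
solid_bbox.mesh_solid <- function(s) {
  rbind(apply(s$mesh$vertices, 2, min), apply(s$mesh$vertices, 2, max))
}

#' @export
find_starting_cubes.mesh_solid <- function(s, lat) {
  out <- NULL
  for (comp in s$ne_members) {
    found <- FALSE
    for (lin in comp) {
      cube_m <- arrayInd(lin, s$lat$dims) - 1L
      lo <- s$lat$origin + cube_m * s$lat$res
      hi <- lo + s$lat$res
      clo <- lat_cube_of(lat, lo)[1, ]; chi <- lat_cube_of(lat, hi)[1, ]
      cand <- as.matrix(expand.grid(clo[1]:chi[1], clo[2]:chi[2],
                                    clo[3]:chi[3]))
      cand <- cand[lat_in_bounds(lat, cand), , drop = FALSE]
      if (nrow(cand) == 0) next
      mx <- cubes_mixed(s, lat, cand)
      if (any(mx)) {
        out <- rbind(out, cand[mx, , drop = FALSE])
        found <- TRUE
        break
      }
    }
    ## a component too thin to straddle any corner of l yields nothing
    if (!found) next
  }
  unique_cubes(out)
}
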