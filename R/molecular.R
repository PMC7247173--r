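## Solvent-excluded molecular solids.
##
## A molecular solid is the region a spherical solvent probe cannot reach:
## the union of atom spheres, toroidal spindles along dual-graph edges,
## tetrahedra spanning dual tetrahedra, and concave "cups" (a tetrahedron
## reaching to a tangent probe center, minus that probe's negsphere).  The
## primitives are indexed by a 2 Angstrom spatial hash so the three basic
## functions touch only nearby primitives.

#' Build the solvent-excluded molecular solid
#'
#' Positions primitives with the [power-diagram dual graph][compute_power_dual]:
#' one sphere per atom; one spindle per non-overlong dual edge where the
#' probe-center circle exists; one tetrahedron per dual tetra lacking an
#' overlong edge; and, for each dual triangle not between two tetrahedra, a
#' cup for every tangent probe placement that collides with no other atom.
#' All primitives are registered in a 2 Angstrom spatial hash.
#'
#' @param atoms data frame with columns `x`, `y`, `z`, `radius` (Angstrom);
#'   as returned by [read_pdb_atoms()] or [toy_molecule()].
#' @param solvent_radius probe radius, Angstrom (default 1.4, a water probe).
#' @return a solid of class `"molecular_solid"`; counts are available via
#'   `summary()` and the fields `spheres`, `spindles`, `tetras`, `cups`.
#' @examples
#' dimer <- toy_molecule("dimer")
#' ms <- build_molecular_solid(dimer, 1.4)
#' contains_point(ms, colMeans(as.matrix(dimer[, c("x", "y", "z")])))
#' @export
build_molecular_solid <- function(atoms, solvent_radius = 1.4) {
  stopifnot(nrow(atoms) >= 1, solvent_radius > 0)
  rs <- solvent_radius
  P <- as.matrix(atoms[, c("x", "y", "z")])
  dual <- compute_power_dual(atoms, rs)

  spheres <- lapply(seq_len(nrow(atoms)),
                    function(i) sphere(P[i, ], atoms$radius[i]))

  spindles <- list()
  spindle_edges <- NULL
  E <- dual$edges[!dual$edges$overlong, , drop = FALSE]
  for (k in seq_len(nrow(E))) {
    i <- E$i[k]; j <- E$j[k]
    d <- E$length[k]
    R1 <- atoms$radius[i] + rs; R2 <- atoms$radius[j] + rs
    a1 <- (d^2 + R1^2 - R2^2) / (2 * d)
    Rmaj2 <- R1^2 - a1^2
    if (Rmaj2 <= 1e-12) next            # expanded spheres barely touch
    a2 <- d - a1
    if (a1 <= 0 || a2 <= 0) next        # one atom engulfs the contact zone
    u <- (P[j, ] - P[i, ]) / d
    cap_lo <- -a1 * rs / R1
    cap_hi <-  a2 * rs / R2
    if (cap_lo >= cap_hi) next
    spindles[[length(spindles) + 1]] <-
      spindle(P[i, ] + a1 * u, u, sqrt(Rmaj2), rs, cap_lo, cap_hi)
    spindle_edges <- rbind(spindle_edges, c(i, j))
  }

  overlong_pair <- paste(E$i, E$j)   # non-overlong pairs (sorted i < j)
  has_all_edges <- function(id) {
    prs <- t(utils::combn(sort(id), 2L))
    all(paste(prs[, 1], prs[, 2]) %in% overlong_pair)
  }
  tetras <- list()
  for (r in seq_len(nrow(dual$tetras))) {
    id <- dual$tetras[r, ]
    if (has_all_edges(id)) {
      tetras[[length(tetras) + 1]] <- tetrahedron(P[id, ])
    }
  }

  cups <- list()
  tangency <- NULL
  tri <- dual$triangles
  for (r in seq_len(nrow(tri))) {
    if (nrow(tri) == 0) break
    if (length(dual$tri_tetra_count) >= r && dual$tri_tetra_count[r] >= 2) next
    id <- tri[r, ]
    if (!has_all_edges(id)) next
    cand <- place_solvent_tangent_sphere(P[id, ], atoms$radius[id], rs)
    for (cc in seq_len(nrow(cand))) {
      ctr <- cand[cc, ]
      others <- setdiff(seq_len(nrow(atoms)), id)
      if (length(others) > 0) {
        dd <- sqrt(rowSums(sweep(P[others, , drop = FALSE], 2, ctr)^2))
        if (any(dd < atoms$radius[others] + rs - 1e-9)) next
      }
      neg <- sphere(ctr, rs, negative = TRUE)
      tet <- tetrahedron(rbind(P[id, ], ctr))
      cups[[length(cups) + 1]] <- list(negsphere = neg, tetra = tet,
                                       atoms = id)
      tangency <- rbind(tangency, t(vapply(seq_len(3), function(m) {
        a <- id[m]
        P[a, ] + atoms$radius[a] / (atoms$radius[a] + rs) * (ctr - P[a, ])
      }, numeric(3))))
    }
  }

  ## positive primitives followed by negspheres, deterministic order
  positives <- c(spheres, spindles, tetras,
                 lapply(cups, function(cp) cp$tetra))
  negs <- lapply(cups, function(cp) cp$negsphere)
  prims <- c(positives, negs)
  is_neg <- c(rep(FALSE, length(positives)), rep(TRUE, length(negs)))

  ## 2 Angstrom spatial hash over primitive bounding boxes
  hash_lat <- build_lattice(prims, 2, pad = 1)
  hash <- new.env(hash = TRUE, size = 1024L)
  for (pi in seq_along(prims)) {
    bb <- solid_bbox(prims[[pi]])
    lo <- lat_cube_of(hash_lat, bb[1, ])[1, ]
    hi <- lat_cube_of(hash_lat, bb[2, ])[1, ]
    lo <- pmax(lo, 0L); hi <- pmin(hi, hash_lat$dims - 1L)
    for (ix in lo[1]:hi[1]) for (iy in lo[2]:hi[2]) for (iz in lo[3]:hi[3]) {
      key <- as.character(ix + hash_lat$dims[1] * (iy + hash_lat$dims[2] * iz))
      hash[[key]] <- c(hash[[key]], pi)
    }
  }

  deg <- integer(nrow(atoms))
  if (!is.null(spindle_edges))
    for (r in seq_len(nrow(spindle_edges)))
      deg[spindle_edges[r, ]] <- deg[spindle_edges[r, ]] + 1L

  structure(list(atoms = atoms, solvent_radius = rs,
                 spheres = spheres, spindles = spindles, tetras = tetras,
                 cups = cups, prims = prims, is_neg = is_neg,
                 hash = hash, hash_lat = hash_lat,
                 tangency = if (is.null(tangency)) matrix(numeric(0), 0, 3)
                            else tangency,
                 isolated = which(deg == 0L)),
            class = c("molecular_solid", "csg_solid"))
}

#' @export
summary.molecular_solid <- function(object, ...) {
  cat(sprintf(paste0("molecular_solid: %d atoms, probe %.2f A\n",
                     "  %d spheres, %d spindles, %d tetrahedra, %d cups\n"),
              nrow(object$atoms), object$solvent_radius,
              length(object$spheres), length(object$spindles),
              length(object$tetras), length(object$cups)))
  invisible(object)
}

hash_key_of <- function(s, cubes) {
  as.character(cubes[, 1] + s$hash_lat$dims[1] *
               (cubes[, 2] + s$hash_lat$dims[2] * cubes[, 3]))
}

## evaluate points against a fixed set of primitive indices: inside a
## negsphere dominates (outside); otherwise inside any positive primitive
mol_eval_prims <- function(s, idx, pts) {
  if (length(idx) == 0) return(rep(FALSE, nrow(pts)))
  pos <- rep(FALSE, nrow(pts)); neg <- rep(FALSE, nrow(pts))
  for (pi in idx) {
    hit <- contains_point(s$prims[[pi]], pts)
    if (s$is_neg[pi]) neg <- neg | hit else pos <- pos | hit
  }
  pos & !neg
}

#' @export
contains_point.molecular_solid <- function(s, p) {
  p <- as_points(p)
  out <- rep(FALSE, nrow(p))
  cubes <- lat_cube_of(s$hash_lat, p)
  inb <- lat_in_bounds(s$hash_lat, cubes)
  if (!any(inb)) return(out)
  keys <- hash_key_of(s, cubes[inb, , drop = FALSE])
  grp <- split(which(inb), keys)
  for (key in names(grp)) {
    idx <- s$hash[[key]]
    rows <- grp[[key]]
    out[rows] <- mol_eval_prims(s, idx, p[rows, , drop = FALSE])
  }
  out
}

## hash-free reference path (oracle for tests)
mol_contains_exhaustive <- function(s, p) {
  mol_eval_prims(s, seq_along(s$prims), as_points(p))
}

#' @export
intersect_segment.molecular_solid <- function(s, seg) {
  p0 <- seg$origin; p1 <- seg$origin + seg$t_max * seg$dir
  path <- voxel_traverse(s$hash_lat, p0, p1)
  if (nrow(path) == 0) return(iv_empty())
  idx <- unique(unlist(lapply(hash_key_of(s, path), function(k) s$hash[[k]])))
  if (length(idx) == 0) return(iv_empty())
  pos <- iv_empty(); neg <- iv_empty()
  for (pi in idx) {
    iv <- intersect_segment(s$prims[[pi]], seg)
    if (nrow(iv) == 0) next
    if (s$is_neg[pi]) neg <- iv_union(neg, iv) else pos <- iv_union(pos, iv)
  }
  iv_diff(pos, neg)
}

#' @export
solid_bbox.molecular_solid <- function(s) {
  bb <- sapply(s$prims, solid_bbox)
  rbind(apply(matrix(bb[c(1, 3, 5), ], nrow = 3), 1, min),
        apply(matrix(bb[c(2, 4, 6), ], nrow = 3), 1, max))
}

#' @export
find_starting_cubes.molecular_solid <- function(s, lat) {
  seeds <- NULL
  ## cubes holding negsphere-atom tangency points
  if (nrow(s$tangency) > 0) {
    tc <- lat_cube_of(lat, s$tangency)
    seeds <- rbind(seeds, tc[lat_in_bounds(lat, tc), , drop = FALSE])
  }
  ## spindle starting cubes, and isolated atom spheres
  for (sp in s$spindles) seeds <- rbind(seeds, find_starting_cubes(sp, lat))
  for (i in s$isolated)
    seeds <- rbind(seeds, find_starting_cubes(s$spheres[[i]], lat))
  if (length(s$spindles) == 0 && length(s$isolated) == 0 &&
      length(s$spheres) > 0)
    seeds <- rbind(seeds, find_starting_cubes(s$spheres[[1]], lat))
  seeds <- unique_cubes(seeds)
  ## keep only cubes straddling the molecular surface itself
  if (nrow(seeds) > 0)
    seeds <- seeds[cubes_mixed(s, lat, seeds), , drop = FALSE]
  if (nrow(seeds) == 0) {
    ## small molecules without cups can leave every spindle-axis cube buried
    ## inside the solid: walk outward from each atom center instead, testing
    ## against the whole molecular solid
    dirs <- FACE_NEIGHBORS * max(1, ceiling(diff(range(solid_bbox(s))) /
                                            lat$res))
    P <- as.matrix(s$atoms[, c("x", "y", "z")])
    for (i in seq_len(nrow(P))) {
      for (d in 1:6) {
        hit <- walk_cubes_until_mixed(s, lat, P[i, ],
                                      P[i, ] + dirs[d, ] * lat$res)
        if (!is.null(hit)) seeds <- rbind(seeds, hit)
      }
    }
    seeds <- unique_cubes(seeds)
  }
  seeds
}
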