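## Cubic lattice management: indexing, corner classification, voxel
## traversal, and the breadth-first surface-cube search.
##
## Cubes are indexed by 0-based integer triples (i, j, k); cube (i,j,k) spans
## origin + (i,j,k)*res .. origin + (i+1,j+1,k+1)*res.  Corner grid points are
## indexed on the (dims + 1) grid.

## corner c in 0..7 has offsets (c&1, (c>>1)&1, (c>>2)&1)
CORNER_OFFSETS <- local({
  m <- matrix(0L, 8, 3)
  for (c in 0:7) m[c + 1, ] <- c(bitwAnd(c, 1L),
                                 bitwAnd(bitwShiftR(c, 1L), 1L),
                                 bitwAnd(bitwShiftR(c, 2L), 1L))
  m
})

FACE_NEIGHBORS <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

#' Build a cubic lattice around solids
#'
#' The lattice covers the union of the operands' bounding boxes with at least
#' one cube of padding on every side, at the requested resolution.  The
#' origin is snapped to integer multiples of the resolution so that identical
#' inputs always produce identical lattices.
#'
#' @param solids a single solid or a list of solids.
#' @param resolution cube side, Angstrom, `> 0`.
#' @param pad padding in cubes around the joint bounding box.
#' @param max_cubes hard cap on the cube count (default 2e8).
#' @return an object of class `"lattice"` with fields `origin`, `res`,
#'   `dims` (cube counts per axis).
#' @export
build_lattice <- function(solids, resolution, pad = 1, max_cubes = 2e8) {
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("resolution must be a single positive number (Angstrom)")
  if (inherits(solids, "csg_solid")) solids <- list(solids)
  if (length(solids) == 0) stop("need at least one solid")
  bb <- sapply(solids, function(s) solid_bbox(s))   # flattened 2x3, column-major
  lo <- apply(matrix(bb[c(1, 3, 5), ], nrow = 3), 1, min)
  hi <- apply(matrix(bb[c(2, 4, 6), ], nrow = 3), 1, max)
  lo_i <- floor(lo / resolution) - pad
  hi_i <- ceiling(hi / resolution) + pad
  dims <- as.integer(hi_i - lo_i)
  if (prod(dims) > max_cubes)
    stop(sprintf(paste0("lattice would hold %.3g cubes (cap %.3g); ",
                        "use a coarser resolution"), prod(dims), max_cubes))
  structure(list(origin = lo_i * resolution, res = resolution, dims = dims),
            class = "lattice")
}

lat_ncubes <- function(lat) prod(lat$dims)

## cube triple containing each point (rows of p)
lat_cube_of <- function(lat, p) {
  p <- as_points(p)
  m <- floor(sweep(sweep(p, 2, lat$origin), 2, rep(lat$res, 3), "/"))
  storage.mode(m) <- "integer"
  m
}

lat_in_bounds <- function(lat, cubes) {
  cubes <- matrix(cubes, ncol = 3)
  cubes[, 1] >= 0L & cubes[, 1] < lat$dims[1] &
  cubes[, 2] >= 0L & cubes[, 2] < lat$dims[2] &
  cubes[, 3] >= 0L & cubes[, 3] < lat$dims[3]
}

## linear cube id (double-valued; exact for < 2^53 cubes)
lat_cube_id <- function(lat, cubes) {
  cubes <- matrix(cubes, ncol = 3)
  cubes[, 1] + lat$dims[1] * (cubes[, 2] + lat$dims[2] * cubes[, 3])
}

## linear id on the (dims+1) corner grid
lat_corner_id <- function(lat, idx) {
  idx <- matrix(idx, ncol = 3)
  nx <- lat$dims[1] + 1; ny <- lat$dims[2] + 1
  idx[, 1] + nx * (idx[, 2] + ny * idx[, 3])
}

lat_corner_coords <- function(lat, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(idx * lat$res, 2, lat$origin, "+")
}

## invert a corner id back to its grid triple
lat_corner_unid <- function(lat, id) {
  nx <- lat$dims[1] + 1; ny <- lat$dims[2] + 1
  i <- id %% nx
  j <- (id %/% nx) %% ny
  k <- id %/% (nx * ny)
  cbind(i, j, k)
}

unique_cubes <- function(cubes) {
  if (is.null(cubes) || nrow(cubes) == 0)
    return(matrix(integer(0), ncol = 3))
  cubes <- matrix(as.integer(cubes), ncol = 3)
  unname(cubes[!duplicated(cubes), , drop = FALSE])
}

## chunked, optionally forked containment evaluation
contains_batch <- function(solid, pts, workers = 1L) {
  n <- nrow(pts)
  if (n == 0) return(logical(0))
  if (workers <= 1L || n < 4096L) return(contains_point(solid, pts))
  idx <- parallel::splitIndices(n, workers)
  out <- parallel::mclapply(idx, function(ii)
    contains_point(solid, pts[ii, , drop = FALSE]), mc.cores = workers)
  unlist(out, use.names = FALSE)
}

## per-cube corner states: returns n x 8 logical matrix, plus the distinct
## corner ids and their states (each distinct corner evaluated exactly once)
corner_states <- function(solid, lat, cubes, workers = 1L) {
  cubes <- matrix(cubes, ncol = 3)
  n <- nrow(cubes)
  if (n == 0)
    return(list(per_cube = matrix(logical(0), 0, 8),
                ids = numeric(0), states = logical(0),
                id_matrix = matrix(numeric(0), 0, 8)))
  idm <- matrix(0, n, 8)
  for (c in 1:8) {
    idm[, c] <- lat_corner_id(lat, sweep(cubes, 2, CORNER_OFFSETS[c, ], "+"))
  }
  ids <- unique(as.vector(idm))
  coords <- lat_corner_coords(lat, lat_corner_unid(lat, ids))
  st <- contains_batch(solid, coords, workers)
  per <- matrix(st[match(as.vector(idm), ids)], n, 8)
  list(per_cube = per, ids = ids, states = st, id_matrix = idm)
}

## mixed-corner (surface cube) test: at least one corner inside and one out
cubes_mixed <- function(solid, lat, cubes, workers = 1L) {
  cs <- corner_states(solid, lat, cubes, workers)
  if (nrow(cs$per_cube) == 0) return(logical(0))
  rowSums(cs$per_cube) %in% 1:7
}

## Amanatides-Woo voxel traversal of the segment p0 -> p1 (clipped to the
## lattice box); returns visited cube triples in order
voxel_traverse <- function(lat, p0, p1) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  box_lo <- lat$origin; box_hi <- lat$origin + lat$dims * lat$res
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-300) {
      if (p0[ax] < box_lo[ax] || p0[ax] > box_hi[ax])
        return(matrix(integer(0), ncol = 3))
    } else {
      ta <- (box_lo[ax] - p0[ax]) / d[ax]
      tb <- (box_hi[ax] - p0[ax]) / d[ax]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 > t1) return(matrix(integer(0), ncol = 3))
  a <- p0 + (t0 + 1e-12) * d
  cube <- pmin(pmax(lat_cube_of(lat, a)[1, ], 0L), lat$dims - 1L)
  step <- ifelse(d > 0, 1L, ifelse(d < 0, -1L, 0L))
  tmaxv <- rep(Inf, 3); tdelta <- rep(Inf, 3)
  for (ax in 1:3) {
    if (step[ax] != 0) {
      bound <- lat$origin[ax] + (cube[ax] + (step[ax] > 0)) * lat$res
      tmaxv[ax] <- (bound - p0[ax]) / d[ax]
      tdelta[ax] <- lat$res / abs(d[ax])
    }
  }
  out <- matrix(cube, 1, 3)
  max_steps <- sum(lat$dims) + 3L
  for (i in seq_len(max_steps)) {
    ax <- which.min(tmaxv)
    if (tmaxv[ax] > t1) break
    cube[ax] <- cube[ax] + step[ax]
    if (cube[ax] < 0L || cube[ax] >= lat$dims[ax]) break
    tmaxv[ax] <- tmaxv[ax] + tdelta[ax]
    out <- rbind(out, cube)
  }
  storage.mode(out) <- "integer"
  unname(out)
}

## walk cube-to-cube along from -> to, returning the first surface cube of
## `solid` met on the way (or NULL)
walk_cubes_until_mixed <- function(solid, lat, from, to) {
  path <- voxel_traverse(lat, from, to)
  if (nrow(path) == 0) return(NULL)
  mixed <- cubes_mixed(solid, lat, path)
  hit <- which(mixed)
  if (length(hit) == 0) NULL else path[hit[1], , drop = FALSE]
}

## exhaustive scan of the whole lattice for surface cubes of `solid`
## (brute-force oracle, and the driver's fallback for pathological thin
## solids that floodfill seeding misses)
exhaustive_surface_scan <- function(solid, lat, workers = 1L) {
  nx <- lat$dims[1] + 1L; ny <- lat$dims[2] + 1L; nz <- lat$dims[3] + 1L
  grid <- as.matrix(expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L),
                                k = 0:(nz - 1L)))
  st <- contains_batch(solid, lat_corner_coords(lat, grid), workers)
  A <- array(st, dim = c(nx, ny, nz))
  cnt <- array(0L, dim = lat$dims)
  for (c in 1:8) {
    off <- CORNER_OFFSETS[c, ]
    cnt <- cnt + A[(1 + off[1]):(lat$dims[1] + off[1]),
                   (1 + off[2]):(lat$dims[2] + off[2]),
                   (1 + off[3]):(lat$dims[3] + off[3])]
  }
  w <- which(cnt >= 1L & cnt <= 7L, arr.ind = TRUE)
  m <- unname(as.matrix(w)) - 1L
  storage.mode(m) <- "integer"
  m[order(lat_cube_id(lat, m)), , drop = FALSE]
}

#' Find all surface cubes by parallel breadth-first floodfill
#'
#' Runs a level-synchronous floodfill over face-adjacent cubes from each leaf
#' solid's starting cubes: a cube joins a leaf's set iff the mixed-corner test
#' passes against the discovering leaf.  The per-leaf sets are merged and the
#' union is then filtered to cubes with at least one corner inside and one
#' outside the root solid.  The result is independent of the worker count and
#' is returned sorted by cube id.
#'
#' If every leaf yields no starting cube but the root occupies the lattice
#' (pathological thin solids), the driver falls back to an exhaustive
#' bounding-box corner scan with a warning.
#'
#' @param root the root solid (a CSG node or any leaf).
#' @param starts optional extra seed cubes (integer triples) merged with the
#'   per-leaf starting cubes.
#' @param lat the lattice.
#' @param workers forked workers for corner classification batches.
#' @return list with `cubes` (n x 3 integer matrix), per-cube corner `states`
#'   (n x 8 logical, root solid) and corner `ids` (n x 8).
#' @export
find_all_surface_cubes <- function(root, starts = NULL, lat, workers = 1L) {
  leaves <- csg_leaves(root)
  ncub <- lat_ncubes(lat)
  candidates <- NULL
  for (leaf in leaves) {
    seeds <- find_starting_cubes(leaf, lat)
    if (nrow(seeds) == 0) next
    visited <- new.env(hash = TRUE, size = 4096L)
    accepted <- seeds
    frontier <- seeds
    for (id in lat_cube_id(lat, seeds)) assign(as.character(id), TRUE, visited)
    while (nrow(frontier) > 0) {
      nb <- do.call(rbind, lapply(1:6, function(d)
        sweep(frontier, 2, FACE_NEIGHBORS[d, ], "+")))
      nb <- nb[lat_in_bounds(lat, nb), , drop = FALSE]
      if (nrow(nb) == 0) break
      idn <- lat_cube_id(lat, nb)
      keep <- !duplicated(idn)
      nb <- nb[keep, , drop = FALSE]; idn <- idn[keep]
      seen <- vapply(as.character(idn), exists, logical(1), envir = visited,
                     inherits = FALSE)
      nb <- nb[!seen, , drop = FALSE]; idn <- idn[!seen]
      if (nrow(nb) == 0) break
      for (id in idn) assign(as.character(id), TRUE, visited)
      mixed <- cubes_mixed(leaf, lat, nb, workers)
      frontier <- nb[mixed, , drop = FALSE]
      if (nrow(frontier) > 0) accepted <- rbind(accepted, frontier)
    }
    candidates <- rbind(candidates, accepted)
  }
  if (!is.null(starts) && nrow(starts) > 0) candidates <- rbind(candidates, starts)
  if (is.null(candidates) || nrow(candidates) == 0) {
    if (ncub <= 2e6) {
      warning("no starting cubes found; falling back to bounding-box corner scan")
      candidates <- exhaustive_surface_scan(root, lat, workers)
    } else {
      candidates <- matrix(integer(0), ncol = 3)
    }
  }
  candidates <- unique_cubes(candidates)
  if (nrow(candidates) > 0)
    candidates <- candidates[order(lat_cube_id(lat, candidates)), , drop = FALSE]
  ## filter by root-solid corner classification
  cs <- corner_states(root, lat, candidates, workers)
  mixed <- rowSums(cs$per_cube) %in% 1:7
  list(cubes = candidates[mixed, , drop = FALSE],
       states = cs$per_cube[mixed, , drop = FALSE],
       ids = cs$id_matrix[mixed, , drop = FALSE])
}

#' Classify surface-cube corners against the root solid
#'
#' Maps every distinct lattice corner of the given cubes to its
#' interior/exterior state with respect to the root solid.  Shared corners are
#' evaluated exactly once; the number of containment evaluations equals the
#' number of distinct corners.
#'
#' @inheritParams find_all_surface_cubes
#' @param cubes n x 3 integer matrix of surface cubes.
#' @return list with `ids` (distinct corner ids), `states` (their
#'   classifications), and `per_cube` (n x 8 logical matrix).
#' @export
classify_corners <- function(cubes, root, lat, workers = 1L) {
  cs <- corner_states(root, lat, cubes, workers)
  list(ids = cs$ids, states = cs$states, per_cube = cs$per_cube,
       id_matrix = cs$id_matrix, n_evaluations = length(cs$ids))
}
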